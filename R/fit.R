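#' MCMC configuration
#'
#' Chain-length and tuning constants for [amh_fit()]. Defaults follow the
#' reference study settings: `L = 55000` iterations, burn-in `B = 5000`,
#' thinning `J = 10` (so `S = 5000` kept draws), random-walk proposal
#' variance `sigma2 = 1` for the shapes, slice step width `lambda = 0.01`,
#' and a phi proposal grid of width 0.1.
#'
#' @param L Total iterations.
#' @param B Burn-in (`0 <= B < L`).
#' @param J Thinning stride (`>= 1`); kept iterations are `B + J, B + 2J,
#'   ..., <= L`.
#' @param sigma2 Random-walk proposal variance for the shape updates
#'   (algorithm A2).
#' @param lambda Slice-sampler stepping increment (algorithm A3).
#' @param slice_mode `"shrink"` (default; rejected bracket draws shrink the
#'   bracket until the draw lies inside the slice, which leaves the target
#'   exactly invariant) or `"paper"` (a single uniform draw on the
#'   stepped-out bracket).
#' @return A list of class `"amh_control"`.
#' @export
amh_control <- function(L = 55000, B = 5000, J = 10, sigma2 = 1,
                        lambda = 0.01, slice_mode = c("shrink", "paper")) {
  slice_mode <- match.arg(slice_mode)
  stopifnot(B >= 0, B < L, J >= 1, sigma2 > 0, lambda > 0)
  if ((L - B) %/% J < 1) stop("no draws would be kept", call. = FALSE)
  structure(list(L = as.integer(L), B = as.integer(B), J = as.integer(J),
                 sigma2 = sigma2, lambda = lambda, slice_mode = slice_mode),
            class = "amh_control")
}

default_init <- function(data) {
  d <- as_surv_data(data)
  b1 <- sum(d$status1) / sum(d$time1)
  b2 <- sum(d$status2) / sum(d$time2)
  amh_params(1, if (b1 > 0) b1 else 1, 1, if (b2 > 0) b2 else 1, 0)
}

# overdispersed starting points for chains beyond the first
overdisperse_init <- function(init, chain) {
  if (chain == 1) return(init)
  f <- c(0.5, 2, 0.75)[((chain - 2) %% 3) + 1]
  ph <- c(-0.5, 0.5, 0.25)[((chain - 2) %% 3) + 1]
  amh_params(init[["alpha1"]] * f, init[["beta1"]] * f,
             init[["alpha2"]] * f, init[["beta2"]] * f, ph)
}

#' Fit the AMH-Weibull survival model by MCMC
#'
#' Posterior simulation for the five model parameters. Per iteration the
#' blocks are updated in the order `alpha1, beta1, alpha2, beta2, phi`,
#' each scale update using the same iteration's fresh shape. The scales are
#' always updated by Metropolis-Hastings with a natural
#' Gamma(`b1 + r_j`, `b2 + sum t^alpha_j`) candidate (an exact Gibbs draw
#' when `phi = 0`), and `phi` by a grid-based independence sampler whose
#' proposal mixes uniforms over the 0.1-wide intervals adjacent to the
#' current one. The three algorithms differ only in the shape updates:
#'
#' * `"A1"` — independence Metropolis-Hastings, proposing from the prior;
#' * `"A2"` — random-walk Metropolis with Normal(0, `sigma2`) steps;
#' * `"A3"` — slice sampling on the conditional kernel [amh_log_kappa()].
#'
#' @param data Bivariate survival table (see [bivariate_survival()]).
#' @param algorithm `"A1"`, `"A2"` or `"A3"`.
#' @param hyper [amh_hyperparams()].
#' @param control [amh_control()].
#' @param init `"auto"` (shape 1, scale matched to an exponential fit,
#'   `phi = 0`), or an [amh_params()] starting point.
#' @param n_chains Number of chains; chains beyond the first start from
#'   overdispersed initial values (parameters scaled by 0.5/2, `phi`
#'   shifted) so that the Gelman-Rubin diagnostic is meaningful.
#' @param seed Optional integer seed (one RNG stream; chains are run
#'   sequentially from it).
#' @return An object of class `"amh_fit"`: list with `draws` (tibble:
#'   `chain`, `iter`, the five parameters), `estimates` (posterior means),
#'   `intervals`, `acceptance`, `algorithm`, `control`, `data`, `seed`.
#' @examples
#' d <- amh_simulate(40, "D1")
#' f <- amh_fit(d, algorithm = "A2",
#'              control = amh_control(L = 1100, B = 100, J = 10), seed = 1)
#' tidy(f)
#' @export
amh_fit <- function(data, algorithm = c("A2", "A1", "A3"),
                    hyper = amh_hyperparams(), control = amh_control(),
                    init = "auto", n_chains = 1, seed = NULL) {
  algorithm <- match.arg(algorithm)
  d <- as_surv_data(data)
  v <- surv_vectors(d)
  if (attr(d, "n") < 2 || (attr(d, "r1") + attr(d, "r2")) < 1) {
    stop("need n >= 2 subjects with at least one observed event", call. = FALSE)
  }
  if (!inherits(control, "amh_control")) stop("control must come from amh_control()", call. = FALSE)
  base_init <- if (identical(init, "auto")) default_init(d) else as_params(init)
  if (!is.null(seed)) set.seed(seed)
  alg_code <- match(algorithm, c("A1", "A2", "A3"))
  draws_list <- vector("list", n_chains)
  acc <- matrix(0, n_chains, 5,
                dimnames = list(NULL, c("alpha1", "beta1", "alpha2", "beta2", "phi")))
  for (ch in seq_len(n_chains)) {
    ini <- overdisperse_init(base_init, ch)
    res <- run_chain_cpp(v$t1, v$d1, v$t2, v$d2, hyper_vec(hyper),
                         as.numeric(unclass(ini)),
                         control$L, control$B, control$J, alg_code,
                         control$sigma2, control$lambda,
                         control$slice_mode == "shrink")
    dm <- res$draws
    colnames(dm) <- c("alpha1", "beta1", "alpha2", "beta2", "phi")
    draws_list[[ch]] <- tibble::as_tibble(as.data.frame(dm)) |>
      dplyr::mutate(chain = ch,
                    iter = control$B + control$J * dplyr::row_number(),
                    .before = 1)
    acc[ch, ] <- res$accept / control$L
  }
  draws <- dplyr::bind_rows(draws_list)
  est <- colMeans(draws[c("alpha1", "beta1", "alpha2", "beta2", "phi")])
  out <- structure(list(
    draws = draws,
    estimates = est,
    intervals = apply(draws[names(est)], 2, quantile, probs = c(0.025, 0.975)),
    acceptance = colMeans(acc),
    algorithm = algorithm,
    control = control,
    hyper = as_hyper(hyper),
    n = attr(d, "n"),
    n_chains = n_chains,
    seed = seed,
    data = d
  ), class = "amh_fit")
  out
}

#' Posterior summary of a fitted chain
#'
#' Posterior means (the ergodic average of the thinned, post-burn-in draws)
#' and equal-tailed 95% credible intervals per parameter.
#'
#' @param fit An [amh_fit()] object.
#' @param conf_level Credible level for the equal-tailed interval.
#' @return A tibble with columns `term`, `estimate`, `std.error` (Monte
#'   Carlo standard error, autocorrelation-adjusted), `conf.low`,
#'   `conf.high`.
#' @export
posterior_summary <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "amh_fit"))
  a <- (1 - conf_level) / 2
  terms <- c("alpha1", "beta1", "alpha2", "beta2", "phi")
  purrr::map_dfr(terms, function(tm) {
    x <- fit$draws[[tm]]
    tibble::tibble(
      term = tm,
      estimate = mean(x),
      std.error = sd(x) * sqrt(max(mcmc_iat(x), 1e-6) / length(x)),
      conf.low = quantile(x, a, names = FALSE),
      conf.high = quantile(x, 1 - a, names = FALSE)
    )
  })
}

#' @rdname posterior_summary
#' @param x An `amh_fit` object.
#' @param ... Passed on to `posterior_summary()`.
#' @method tidy amh_fit
#' @export
tidy.amh_fit <- function(x, ...) posterior_summary(x, ...)

#' One-row summary of a fitted chain
#'
#' @param x An [amh_fit()] object.
#' @param ... Unused.
#' @return Tibble with sample size, algorithm, kept draws, minimum
#'   effective sample size across parameters, log-likelihood at the
#'   posterior mean, and (for multi-chain fits) the largest Gelman-Rubin
#'   factor.
#' @method glance amh_fit
#' @export
glance.amh_fit <- function(x, ...) {
  pars <- c("alpha1", "beta1", "alpha2", "beta2", "phi")
  ess <- vapply(pars, function(tm) mcmc_ess(x$draws[[tm]]), numeric(1))
  psrf <- if (x$n_chains >= 2) {
    max(vapply(pars, function(tm) {
      gelman_rubin(split(x$draws[[tm]], x$draws$chain))
    }, numeric(1)))
  } else NA_real_
  tibble::tibble(
    n = x$n, algorithm = x$algorithm,
    n_draws = nrow(x$draws), n_chains = x$n_chains,
    min_ess = min(ess), max_psrf = psrf,
    loglik = amh_loglik(x$data, as_params(x$estimates))
  )
}

#' @export
print.amh_fit <- function(x, ...) {
  cat(sprintf("AMH-Weibull MCMC fit (algorithm %s), n = %d subjects, %d kept draws\n",
              x$algorithm, x$n, nrow(x$draws)))
  print(posterior_summary(x), ...)
  cat("Acceptance rates:\n")
  print(round(x$acceptance, 3))
  invisible(x)
}

#' Trace plots of an MCMC fit
#'
#' @param object An [amh_fit()] object.
#' @param ... Unused.
#' @return A ggplot: one facet per parameter, thinned draws against kept
#'   iteration, coloured by chain.
#' @method autoplot amh_fit
#' @export
autoplot.amh_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$draws,
                              cols = c("alpha1", "beta1", "alpha2", "beta2", "phi"),
                              names_to = "term", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iter, y = .data$value,
                                     colour = factor(.data$chain))) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL, colour = "chain")
}

#' Ergodic (running) means of the kept draws
#'
#' @param fit An [amh_fit()] object.
#' @return Tibble with `chain`, `iter`, `term`, `running_mean`.
#' @export
ergodic_means <- function(fit) {
  stopifnot(inherits(fit, "amh_fit"))
  fit$draws |>
    tidyr::pivot_longer(cols = c("alpha1", "beta1", "alpha2", "beta2", "phi"),
                        names_to = "term", values_to = "value") |>
    dplyr::group_by(.data$chain, .data$term) |>
    dplyr::arrange(.data$iter, .by_group = TRUE) |>
    dplyr::mutate(running_mean = cumsum(.data$value) / dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("chain", "iter", "term", "running_mean")
}
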