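#' Conditional inverse of the AMH copula
#'
#' Given `u1` and a target conditional probability `u2`, solves
#' \deqn{u_2 = \frac{w[1 - \phi(1 - w)]}{[1 - \phi(1 - u_1)(1 - w)]^2}}
#' for `w` in (0, 1). The right-hand side is the conditional distribution
#' \eqn{\partial C_\phi(u_1, w)/\partial u_1} of the copula on the survival
#' scale, monotone increasing in `w`, so the root is unique; it is found by
#' bracketed root finding on `(1e-12, 1 - 1e-12)` to tolerance `1e-12`.
#' At `phi = 0` the equation reduces to `w = u2` exactly.
#'
#' @param u1,u2 Uniform(0, 1) values (vectorized, equal length).
#' @param phi AMH dependence parameter in `[-1, 1)`.
#' @return The solution(s) `w` in (0, 1).
#' @examples
#' conditional_inverse_w(0.3, 0.7, 0.5)
#' @export
conditional_inverse_w <- function(u1, u2, phi) {
  if (phi < -1 || phi >= 1) stop("phi must lie in [-1, 1)", call. = FALSE)
  stopifnot(length(u1) == length(u2), all(u1 > 0 & u1 < 1), all(u2 > 0 & u2 < 1))
  if (phi == 0) return(u2)
  eps <- 1e-12
  vapply(seq_along(u1), function(i) {
    a <- u1[[i]]; b <- u2[[i]]
    g <- function(w) w * (1 - phi * (1 - w)) / (1 - phi * (1 - a) * (1 - w))^2 - b
    uniroot(g, lower = eps, upper = 1 - eps, tol = 1e-12,
            f.lower = -b, check.conv = TRUE)$root
  }, numeric(1))
}

#' Calibrate the censoring upper bound for a target censoring percentage
#'
#' Censoring times are drawn from U(0, `tau`); a lifetime is censored when
#' the censoring time falls below it, so the expected censoring fraction is
#' \deqn{P(C < T) = \frac{1}{\tau}\int_0^\tau S_j(c)\,dc,}
#' a decreasing function of `tau`. This solves that identity for `tau` by
#' 1-D quadrature and root finding. A target of 0 returns `Inf` (no
#' censoring).
#'
#' @param params [amh_params()]; only the requested margin's Weibull
#'   parameters are used.
#' @param censor_pct Target percentage of censored observations, in
#'   `[0, 100)`.
#' @param margin Margin to calibrate (1 or 2).
#' @return The censoring bound `tau` (time units), or `Inf`.
#' @examples
#' # exponential margin: tau solves (1 - exp(-tau))/tau = 0.30
#' calibrate_censoring_bound(amh_params(1, 1, 1, 1, 0), 30, margin = 1)
#' @export
calibrate_censoring_bound <- function(params, censor_pct, margin = 1) {
  if (!margin %in% c(1, 2)) stop("margin must be 1 or 2", call. = FALSE)
  if (censor_pct < 0 || censor_pct >= 100) {
    stop("censor_pct must lie in [0, 100)", call. = FALSE)
  }
  if (censor_pct == 0) return(Inf)
  p <- as_params(params)
  alpha <- if (margin == 1) p[["alpha1"]] else p[["alpha2"]]
  beta <- if (margin == 1) p[["beta1"]] else p[["beta2"]]
  target <- censor_pct / 100
  pr_cens <- function(tau) {
    integrate(function(c) exp(-beta * c^alpha), 0, tau,
              rel.tol = 1e-10)$value / tau
  }
  # pr_cens decreases from 1 (tau -> 0) to 0 (tau -> Inf); bracket by doubling
  hi <- 1
  while (pr_cens(hi) > target) {
    hi <- hi * 2
    if (hi > 1e12) stop("censoring target unattainable", call. = FALSE)
  }
  lo <- hi / 2
  while (pr_cens(lo) < target) {
    lo <- lo / 2
    if (lo < 1e-12) stop("censoring target unattainable", call. = FALSE)
  }
  uniroot(function(tau) pr_cens(tau) - target, lower = lo, upper = hi,
          tol = 1e-10)$root
}

#' Simulate bivariate right-censored AMH-Weibull data
#'
#' Conditional-inversion sampler. Per subject: draw `u1, u2 ~ U(0,1)`
#' independently; solve the conditional copula equation for `w`
#' ([conditional_inverse_w()]); transform `u1` and `w` through the inverse
#' marginal survival functions,
#' \eqn{T_1 = (-\log u_1/\beta_1)^{1/\alpha_1}},
#' \eqn{T_2 = (-\log w/\beta_2)^{1/\alpha_2}}; draw censoring times
#' `C_j ~ U(0, tau_j)` independently of the lifetimes; record
#' `time_j = min(T_j, C_j)` and `status_j = 1{T_j <= C_j}`.
#'
#' Censoring bounds are calibrated per margin from `censor_pct` via
#' [calibrate_censoring_bound()] unless supplied directly through `tau`.
#'
#' @param n Sample size.
#' @param params True parameters ([amh_params()] or a design name
#'   `"D1"`-`"D4"`).
#' @param censor_pct Target censoring percentage applied to both margins
#'   (scalar) or per margin (length 2). Ignored when `tau` is given.
#' @param tau Optional censoring bounds, length 2 (use `Inf` for none).
#' @param latent If `TRUE`, also return the latent lifetimes `T1`, `T2` and
#'   uniforms as extra columns (useful for checking the copula itself).
#' @return A [bivariate_survival()] tibble with attributes `true_params`
#'   and `tau`.
#' @examples
#' d <- amh_simulate(50, "D1", censor_pct = 10)
#' attr(d, "tau")
#' @export
amh_simulate <- function(n, params, censor_pct = 0, tau = NULL, latent = FALSE) {
  p <- if (is.character(params)) amh_design(params) else as_params(params)
  stopifnot(n >= 1)
  if (is.null(tau)) {
    censor_pct <- rep_len(censor_pct, 2L)
    tau <- c(calibrate_censoring_bound(p, censor_pct[[1L]], 1),
             calibrate_censoring_bound(p, censor_pct[[2L]], 2))
  }
  stopifnot(length(tau) == 2L, all(tau > 0))
  u1 <- runif(n)
  u2 <- runif(n)
  w <- conditional_inverse_w(u1, u2, p[["phi"]])
  T1 <- (-log(u1) / p[["beta1"]])^(1 / p[["alpha1"]])
  T2 <- (-log(w) / p[["beta2"]])^(1 / p[["alpha2"]])
  C1 <- if (is.finite(tau[[1L]])) runif(n, 0, tau[[1L]]) else rep(Inf, n)
  C2 <- if (is.finite(tau[[2L]])) runif(n, 0, tau[[2L]]) else rep(Inf, n)
  out <- tibble::tibble(
    time1 = pmin(T1, C1), status1 = as.integer(T1 <= C1),
    time2 = pmin(T2, C2), status2 = as.integer(T2 <= C2)
  )
  if (latent) {
    out$T1 <- T1
    out$T2 <- T2
    out$u1 <- u1
    out$w <- w
  }
  out <- bivariate_survival(out)
  attr(out, "true_params") <- p
  attr(out, "tau") <- tau
  out
}
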