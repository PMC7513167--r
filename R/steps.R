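#' Single MCMC block updates
#'
#' One update of a single parameter block, exposed for inspection and
#' testing; [amh_fit()] runs the same compiled updates in its inner loop.
#' Each function draws from the R random number stream, so results are
#' reproducible under [set.seed()].
#'
#' * `update_alpha()` updates a Weibull shape by the chosen method:
#'   independence MH from the prior (`"imh"`), random-walk Metropolis
#'   (`"rwm"`), or slice sampling (`"slice"`, with `slice_mode` as in
#'   [amh_control()]).
#' * `update_beta()` updates a Weibull scale by MH with the natural
#'   Gamma(`b1 + r_j`, `b2 + sum t^alpha_j`) candidate; when `phi = 0` the
#'   acceptance ratio is identically 1 and the update is an exact Gibbs
#'   draw from that Gamma.
#' * `update_phi()` updates the dependence parameter by grid-based
#'   independence MH (mixture of uniforms over the 0.1-wide neighbouring
#'   intervals, with the exact Hastings correction 2/3, 1 or 3/2).
#'
#' @param data Bivariate survival table.
#' @param params Current [amh_params()] state.
#' @param margin Margin whose parameter is updated (1 or 2).
#' @param method Shape update method.
#' @param hyper [amh_hyperparams()].
#' @param sigma2 Random-walk proposal variance.
#' @param lambda Slice stepping increment.
#' @param slice_mode `"shrink"` or `"paper"`.
#' @return A list with `value` (the new parameter value) and `accepted`
#'   (logical; slice moves always count as accepted).
#' @name mcmc_steps
NULL

#' @rdname mcmc_steps
#' @export
update_alpha <- function(data, params, margin, method = c("imh", "rwm", "slice"),
                         hyper = amh_hyperparams(), sigma2 = 1, lambda = 0.01,
                         slice_mode = c("shrink", "paper")) {
  method <- match.arg(method)
  slice_mode <- match.arg(slice_mode)
  if (!margin %in% c(1, 2)) stop("margin must be 1 or 2", call. = FALSE)
  v <- surv_vectors(data)
  p <- as_params(params)
  code <- switch(method, imh = 0L, rwm = 1L,
                 slice = if (slice_mode == "shrink") 2L else 3L)
  step_alpha_cpp(v$t1, v$d1, v$t2, v$d2, hyper_vec(hyper),
                 as.numeric(unclass(p)), as.integer(margin), code, sigma2, lambda)
}

#' @rdname mcmc_steps
#' @export
update_beta <- function(data, params, margin, hyper = amh_hyperparams()) {
  if (!margin %in% c(1, 2)) stop("margin must be 1 or 2", call. = FALSE)
  v <- surv_vectors(data)
  p <- as_params(params)
  step_beta_cpp(v$t1, v$d1, v$t2, v$d2, hyper_vec(hyper),
                as.numeric(unclass(p)), as.integer(margin))
}

#' @rdname mcmc_steps
#' @export
update_phi <- function(data, params) {
  v <- surv_vectors(data)
  p <- as_params(params)
  step_phi_cpp(v$t1, v$d1, v$t2, v$d2, as.numeric(unclass(p)))
}
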