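#' Parameter vector of the AMH-Weibull bivariate survival model
#'
#' Bundles the five model parameters: the Weibull shape and scale of each
#' margin and the copula dependence parameter. The Weibull parameterization
#' is **rate-type**: the marginal survival function is
#' \eqn{S_j(t) = \exp(-\beta_j t^{\alpha_j})}. Many R functions (e.g.
#' [stats::pweibull()]) use instead a scale \eqn{\lambda_j = \beta_j^{-1/\alpha_j}};
#' convert before comparing.
#'
#' @param alpha1,beta1 Shape and rate-scale of margin 1 (both `> 0`).
#' @param alpha2,beta2 Shape and rate-scale of margin 2 (both `> 0`).
#' @param phi AMH dependence parameter, in `[-1, 1)`. `phi = 0` gives
#'   independent margins; positive (negative) values give weak positive
#'   (negative) dependence.
#'
#' @return An object of class `"amh_params"`: a named numeric vector
#'   `c(alpha1, beta1, alpha2, beta2, phi)`.
#' @seealso [amh_design()] for the four benchmark presets.
#' @examples
#' p <- amh_params(2, 1, 3, 1, 0.5)
#' amh_survival(0.5, 0.5, p)
#' @export
amh_params <- function(alpha1, beta1, alpha2, beta2, phi) {
  x <- c(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2, beta2 = beta2, phi = phi)
  validate_params(x)
  structure(x, class = "amh_params")
}

validate_params <- function(x) {
  if (length(x) != 5L || anyNA(x) || !is.numeric(x)) {
    stop("params must be five finite numbers (alpha1, beta1, alpha2, beta2, phi)",
         call. = FALSE)
  }
  for (nm in c("alpha1", "beta1", "alpha2", "beta2")) {
    if (x[[nm]] <= 0) stop(sprintf("%s must be > 0 (got %g)", nm, x[[nm]]), call. = FALSE)
  }
  if (x[[5L]] < -1 || x[[5L]] >= 1) {
    stop(sprintf("phi must lie in [-1, 1) (got %g)", x[[5L]]), call. = FALSE)
  }
  invisible(x)
}

as_params <- function(x) {
  if (inherits(x, "amh_params")) return(x)
  if (is.numeric(x) && length(x) == 5L) {
    return(amh_params(x[[1L]], x[[2L]], x[[3L]], x[[4L]], x[[5L]]))
  }
  if (is.list(x) || is.data.frame(x)) {
    return(amh_params(x$alpha1, x$beta1, x$alpha2, x$beta2, x$phi))
  }
  stop("cannot interpret `params`; use amh_params() or a numeric vector of length 5",
       call. = FALSE)
}

#' @export
print.amh_params <- function(x, ...) {
  cat("AMH-Weibull parameters (S_j(t) = exp(-beta_j t^alpha_j)):\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Benchmark parameter designs D1-D4
#'
#' Four fixed parameter settings used throughout the simulation study:
#' increasing/constant/decreasing marginal hazards combined with positive,
#' negative, weak and strong dependence.
#'
#' @param design One of `"D1"`, `"D2"`, `"D3"`, `"D4"`.
#' @return [amh_params()] object for that design.
#' @examples
#' amh_design("D2")
#' design_presets()
#' @export
amh_design <- function(design = c("D1", "D2", "D3", "D4")) {
  design <- match.arg(design)
  row <- design_presets()[design_presets()$design == design, ]
  amh_params(row$alpha1, row$beta1, row$alpha2, row$beta2, row$phi)
}

#' @rdname amh_design
#' @return `design_presets()`: a tibble with one row per design.
#' @export
design_presets <- function() {
  tibble::tibble(
    design = c("D1", "D2", "D3", "D4"),
    alpha1 = c(2.00, 1.00, 0.75, 1.80),
    beta1  = c(1.00, 2.00, 1.50, 2.40),
    alpha2 = c(3.00, 2.00, 1.00, 2.20),
    beta2  = c(1.00, 0.50, 2.00, 1.20),
    phi    = c(0.50, -0.75, 0.05, 0.95)
  )
}

#' Gamma prior constants for the Weibull parameters
#'
#' Independent Gamma priors (shape/rate parameterization: mean `a1/a2`,
#' variance `a1/a2^2`) are placed on each Weibull shape and rate-scale; the
#' dependence parameter has a flat U(-1, 1) prior with no free constant.
#' The default `0.01` for every constant gives vague priors with mean 1 and
#' variance 100.
#'
#' @param a11,a12 Gamma shape/rate for `alpha1`.
#' @param a21,a22 Gamma shape/rate for `alpha2`.
#' @param b11,b12 Gamma shape/rate for `beta1`.
#' @param b21,b22 Gamma shape/rate for `beta2`.
#' @return Object of class `"amh_hyperparams"` (named numeric vector of 8).
#' @examples
#' amh_hyperparams()
#' @export
amh_hyperparams <- function(a11 = 0.01, a12 = 0.01, a21 = 0.01, a22 = 0.01,
                            b11 = 0.01, b12 = 0.01, b21 = 0.01, b22 = 0.01) {
  x <- c(a11 = a11, a12 = a12, a21 = a21, a22 = a22,
         b11 = b11, b12 = b12, b21 = b21, b22 = b22)
  if (anyNA(x) || any(x <= 0)) stop("all hyperparameters must be positive", call. = FALSE)
  structure(x, class = "amh_hyperparams")
}

as_hyper <- function(x) {
  if (is.null(x)) return(amh_hyperparams())
  if (inherits(x, "amh_hyperparams")) return(x)
  if (is.numeric(x) && length(x) == 8L) return(do.call(amh_hyperparams, as.list(x)))
  stop("cannot interpret `hyper`; use amh_hyperparams()", call. = FALSE)
}

# hyper vector in the order the C++ layer expects
hyper_vec <- function(h) as.numeric(unclass(as_hyper(h)))
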