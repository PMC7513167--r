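#' Fitted marginal survival curves against Kaplan-Meier estimates
#'
#' Overlays each margin's fitted Weibull survival function (at the
#' posterior-mean parameters) on the nonparametric Kaplan-Meier step
#' estimate.
#'
#' @param fit An [amh_fit()] object.
#' @return A ggplot faceted by margin.
#' @export
plot_survival_fit <- function(fit) {
  stopifnot(inherits(fit, "amh_fit"))
  d <- fit$data
  p <- as_params(fit$estimates)
  km <- dplyr::bind_rows(
    dplyr::mutate(km_curve(d$time1, d$status1), margin = "margin 1"),
    dplyr::mutate(km_curve(d$time2, d$status2), margin = "margin 2")
  )
  grid1 <- seq(0, max(d$time1), length.out = 200)
  grid2 <- seq(0, max(d$time2), length.out = 200)
  fitted <- dplyr::bind_rows(
    tibble::tibble(time = grid1, margin = "margin 1",
                   surv = exp(-p[["beta1"]] * grid1^p[["alpha1"]])),
    tibble::tibble(time = grid2, margin = "margin 2",
                   surv = exp(-p[["beta2"]] * grid2^p[["alpha2"]]))
  )
  ggplot2::ggplot() +
    ggplot2::geom_step(data = km, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_line(data = fitted,
                       ggplot2::aes(x = .data$time, y = .data$surv),
                       colour = "steelblue") +
    ggplot2::facet_wrap(~margin) +
    ggplot2::labs(x = "time", y = "survival probability")
}
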