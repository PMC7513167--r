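#' Validate a bivariate right-censored survival table
#'
#' The data format used throughout the package: one row per subject with
#' columns `time1`, `status1`, `time2`, `status2`. Status is 1 when the
#' event was observed (the recorded time is the lifetime) and 0 when the
#' observation is right-censored (the lifetime exceeds the recorded time).
#'
#' @param data A data frame with the four columns above.
#' @return The same data as a validated tibble, invisibly classed
#'   `"bivariate_survival"`; attributes `n`, `r1`, `r2` record the sample
#'   size and per-margin event counts.
#' @examples
#' d <- tibble::tibble(time1 = c(1, 2), status1 = c(1, 0),
#'                     time2 = c(0.5, 1.5), status2 = c(1, 0))
#' bivariate_survival(d)
#' @export
bivariate_survival <- function(data) {
  cols <- c("time1", "status1", "time2", "status2")
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  out <- out[c(cols, setdiff(names(out), cols))]
  if (nrow(out) < 1L) stop("need at least one subject", call. = FALSE)
  for (tc in c("time1", "time2")) {
    bad <- which(!is.finite(out[[tc]]) | out[[tc]] <= 0)
    if (length(bad) > 0) {
      stop(sprintf("nonpositive or missing %s at row %d", tc, bad[1L]), call. = FALSE)
    }
  }
  for (sc in c("status1", "status2")) {
    bad <- which(!(out[[sc]] %in% c(0, 1)))
    if (length(bad) > 0) {
      stop(sprintf("%s outside {0, 1} at row %d", sc, bad[1L]), call. = FALSE)
    }
  }
  structure(out,
            class = c("bivariate_survival", class(out)),
            n = nrow(out),
            r1 = sum(out$status1), r2 = sum(out$status2))
}

as_surv_data <- function(data) {
  if (inherits(data, "bivariate_survival")) data else bivariate_survival(data)
}

# list of plain vectors for the C++ layer
surv_vectors <- function(data) {
  d <- as_surv_data(data)
  list(t1 = as.numeric(d$time1), d1 = as.integer(d$status1),
       t2 = as.numeric(d$time2), d2 = as.integer(d$status2))
}
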