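#' Read and write bivariate survival tables
#'
#' The on-disk format is delimited text with header
#' `time1,status1,time2,status2`, one row per subject; status is 1 for an
#' observed event and 0 for a right-censored observation.
#'
#' @param path File path.
#' @return `read_survival_table()`: a validated [bivariate_survival()]
#'   tibble. `write_survival_table()`: the input, invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_survival_table(amh_simulate(5, "D1"), f)
#' read_survival_table(f)
#' @export
read_survival_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  bivariate_survival(raw)
}

#' @rdname read_survival_table
#' @param data Bivariate survival table.
#' @export
write_survival_table <- function(data, path) {
  d <- as_surv_data(data)
  readr::write_csv(d[c("time1", "status1", "time2", "status2")], path,
                   progress = FALSE)
  invisible(data)
}

#' Write and read chain output
#'
#' The kept draws go to a CSV with header
#' `iter,alpha1,beta1,alpha2,beta2,phi` (plus `chain` for multi-chain
#' fits); a JSON sidecar (`<path>.json`) records the configuration, seed,
#' acceptance rates, posterior means and 95% intervals needed to
#' regenerate and interpret the run.
#'
#' @param fit An [amh_fit()] object.
#' @param path CSV output path.
#' @return `write_chain()`: `path`, invisibly. `read_chain()`: a tibble of
#'   draws with the sidecar (if present) attached as attribute `"meta"`.
#' @export
write_chain <- function(fit, path) {
  stopifnot(inherits(fit, "amh_fit"))
  cols <- c(if (fit$n_chains > 1) "chain", "iter",
            "alpha1", "beta1", "alpha2", "beta2", "phi")
  readr::write_csv(fit$draws[cols], path, progress = FALSE)
  meta <- list(
    algorithm = fit$algorithm,
    control = unclass(fit$control),
    hyper = as.list(unclass(fit$hyper)),
    seed = fit$seed,
    n = fit$n,
    n_chains = fit$n_chains,
    acceptance = as.list(fit$acceptance),
    estimates = as.list(fit$estimates),
    conf_low = as.list(fit$intervals[1, ]),
    conf_high = as.list(fit$intervals[2, ])
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_chain
#' @export
read_chain <- function(path) {
  draws <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    attr(draws, "meta") <- jsonlite::read_json(side, simplifyVector = TRUE)
  }
  draws
}

#' Pair the diabetic retinopathy data into the bivariate format
#'
#' Converts the `diabetic` data shipped with the \pkg{survival} package
#' (197 juvenile and adult diabetes patients; laser photocoagulation
#' randomly assigned to one eye, the other eye a control; time to visual
#' loss, right-censored) into the four-column bivariate format. Margin 1
#' is the treated eye, margin 2 the untreated eye, paired within patient.
#'
#' @return A [bivariate_survival()] tibble with 197 rows.
#' @export
retinopathy_pairs <- function() {
  if (!requireNamespace("survival", quietly = TRUE)) {
    stop("the survival package is required for the retinopathy data", call. = FALSE)
  }
  env <- new.env()
  utils::data("diabetic", package = "survival", envir = env)
  db <- env$diabetic
  trt <- db[db$trt == 1, c("id", "time", "status")]
  ctl <- db[db$trt == 0, c("id", "time", "status")]
  merged <- merge(trt, ctl, by = "id", suffixes = c("1", "2"))
  bivariate_survival(tibble::tibble(
    time1 = merged$time1, status1 = merged$status1,
    time2 = merged$time2, status2 = merged$status2
  ))
}
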