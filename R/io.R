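#' Write a MIMS trace and its addition schedule to CSV
#'
#' The trace goes to `<prefix>_trace.csv` (`time_s,signal_counts`) and the
#' additions to `<prefix>_additions.csv`
#' (`time_s,kind,volume_ml,conc_nm`), the plain-text exchange format used
#' throughout the package.
#'
#' @param trace A `mims_trace`.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths written.
#' @export
write_mims_trace <- function(trace, prefix) {
  stopifnot(inherits(trace, "mims_trace"))
  trace_path <- paste0(prefix, "_trace.csv")
  adds_path <- paste0(prefix, "_additions.csv")
  readr::write_csv(
    tibble::tibble(
      time_s = trace$time_s, signal_counts = trace$signal_counts
    ),
    trace_path
  )
  adds <- attr(trace, "additions")
  readr::write_csv(
    adds[, intersect(c("time_s", "kind", "volume_ml", "conc_nm"), names(adds))],
    adds_path
  )
  invisible(c(trace = trace_path, additions = adds_path))
}

#' Read a MIMS trace from CSV
#'
#' @param trace_path CSV with columns `time_s`, `signal_counts`.
#' @param additions_path CSV with columns `time_s`, `kind`, `volume_ml` and
#'   optionally `conc_nm`.
#' @param biomass_mg Dry weight of cells in the chamber (mg).
#' @param chamber_volume Chamber liquid volume (L).
#' @return An uncalibrated `mims_trace`.
#' @export
read_mims_trace <- function(trace_path, additions_path, biomass_mg,
                            chamber_volume = 0.5) {
  dat <- readr::read_csv(trace_path, col_types = readr::cols(
    time_s = readr::col_double(), signal_counts = readr::col_double()
  ))
  adds <- readr::read_csv(additions_path, col_types = readr::cols())
  dts <- diff(dat$time_s)
  if (length(dts) == 0 || any(dts <= 0) ||
    max(dts) - min(dts) > 1e-6 * max(dts)) {
    stop("trace times must form a uniform, strictly increasing grid",
      call. = FALSE
    )
  }
  dt <- dts[1]
  adds <- validate_additions(adds, dt, max(dat$time_s) + dt)
  new_mims_trace(dat,
    additions = adds, chamber_volume = chamber_volume,
    biomass_mg = biomass_mg, dt = dt
  )
}

#' Write a chemostat record as JSON
#'
#' @param record A `chemostat_record`.
#' @param path Output path.
#' @param keep_truth Include the generator ground truth (synthetic records
#'   only)?
#' @return Invisibly, `path`.
#' @export
write_chemostat_record <- function(record, path, keep_truth = FALSE) {
  stopifnot(inherits(record, "chemostat_record"))
  out <- unclass(record)
  if (!keep_truth) out$truth <- NULL
  out$truth$params <- NULL # sim params are not serializable observations
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a chemostat record from JSON
#'
#' @param path JSON written by [write_chemostat_record()] or assembled by
#'   hand with the same fields.
#' @return A `chemostat_record`.
#' @export
read_chemostat_record <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c(
    "volume", "dilution_rate", "gas_in", "gas_out", "dw_g_l",
    "toc_mm", "tn_mm", "molar_volume"
  )
  if (!all(needed %in% names(x))) {
    stop("record is missing fields: ",
      paste(setdiff(needed, names(x)), collapse = ", "),
      call. = FALSE
    )
  }
  x$gas_in <- tibble::as_tibble(x$gas_in)
  x$gas_out <- tibble::as_tibble(x$gas_out)
  structure(x[c(needed, intersect("truth", names(x)))],
    class = "chemostat_record"
  )
}

#' Read a feature table from CSV
#'
#' @param path CSV with `mz`, `rt` and `supernatant_*`/`blank_*` intensity
#'   columns; group statistics are recomputed if absent.
#' @return A tibble with group statistics.
#' @export
read_feature_table <- function(path) {
  ft <- readr::read_csv(path, col_types = readr::cols())
  stat_cols <- c("fold_change", "p_value", "max_intensity")
  if (!all(stat_cols %in% names(ft))) ft <- compute_feature_stats(ft)
  ft
}
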