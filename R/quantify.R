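#' Concentration from an external calibration curve
#'
#' Ordinary least-squares line (intercept included) through the standard
#' points, then inverse prediction of the measured response, multiplied by
#' any dilution factor applied to the sample before injection.
#'
#' @param standards A data frame with columns `concentration` and `response`
#'   (at least two points at distinct concentrations).
#' @param response Measured response(s) of the unknown.
#' @param dilution_factor Multiplier restoring the pre-dilution
#'   concentration (e.g. 30 for a 30-fold diluted supernatant).
#' @return Estimated concentration(s), in the units of the standards times
#'   `dilution_factor`.
#' @examples
#' std <- data.frame(concentration = c(1.25, 2.5), response = c(125, 250))
#' quantify_from_calibration(std, 176) # 1.76
#' @export
quantify_from_calibration <- function(standards, response,
                                      dilution_factor = 1) {
  standards <- as.data.frame(standards)
  if (!all(c("concentration", "response") %in% names(standards))) {
    names(standards)[1:2] <- c("concentration", "response")
  }
  if (nrow(standards) < 2 || length(unique(standards$concentration)) < 2) {
    stop("need at least two standards at distinct concentrations",
      call. = FALSE
    )
  }
  stopifnot(is.numeric(response), all(is.finite(response)),
    dilution_factor > 0
  )
  fit <- stats::lm(response ~ concentration, data = standards)
  slope <- stats::coef(fit)[["concentration"]]
  intercept <- stats::coef(fit)[["(Intercept)"]]
  span <- abs(slope) * diff(range(standards$concentration))
  if (!is.finite(slope) ||
    span <= 1e-8 * (stats::median(abs(standards$response)) + 1e-300)) {
    stop("calibration slope is zero; cannot invert", call. = FALSE)
  }
  lo <- min(standards$response)
  hi <- max(standards$response)
  if (any(response > 2 * hi | response < lo / 2)) {
    warning("response outside twice the calibration range; ",
      "extrapolated concentration is unreliable"
    )
  }
  (response - intercept) / slope * dilution_factor
}

#' Total carbon and nitrogen carried by a compound concentration table
#'
#' Multiplies each compound's concentration by its element counts from the
#' registry and sums, converting uM to mM. This is the compound-level side of
#' a carbon closure against bulk TOC.
#'
#' @param conc_table A data frame with columns `compound` and
#'   `concentration_um`.
#' @param registry A compound registry, see [load_compound_registry()].
#' @return A one-row tibble: `carbon_mm`, `nitrogen_mm`.
#' @examples
#' tab <- read_concentration_table()
#' carbon_total(tab) # 6.58 mM C for the packaged supernatant table
#' @export
carbon_total <- function(conc_table, registry = load_compound_registry()) {
  conc_table <- tibble::as_tibble(conc_table)
  stopifnot(all(c("compound", "concentration_um") %in% names(conc_table)))
  if (any(conc_table$concentration_um < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (nrow(conc_table) == 0) {
    return(tibble::tibble(carbon_mm = 0, nitrogen_mm = 0))
  }
  joined <- dplyr::left_join(conc_table, registry,
    by = c(compound = "name")
  )
  missing <- joined$compound[is.na(joined$n_carbon)]
  if (length(missing)) {
    stop("no element counts in the registry for: ",
      paste(unique(missing), collapse = ", "),
      call. = FALSE
    )
  }
  tibble::tibble(
    carbon_mm = sum(joined$concentration_um * joined$n_carbon) / 1000,
    nitrogen_mm = sum(joined$concentration_um * joined$n_nitrogen) / 1000
  )
}

#' Coverage of bulk TOC by identified compounds
#'
#' @param carbon_mm Summed carbon of the identified compounds (mM C), see
#'   [carbon_total()].
#' @param toc_mm Measured total organic carbon (mM C).
#' @return Percent coverage, `100 * carbon_mm / toc_mm`; values above 100
#'   indicate over-closure (quantification or TOC bias).
#' @export
toc_coverage <- function(carbon_mm, toc_mm) {
  if (!is.finite(toc_mm) || toc_mm <= 0) {
    stop("`toc_mm` must be positive", call. = FALSE)
  }
  if (carbon_mm < 0) stop("`carbon_mm` must be non-negative", call. = FALSE)
  100 * carbon_mm / toc_mm
}

#' Read a compound concentration table
#'
#' @param path CSV with columns `compound`, `concentration_um`, `method`;
#'   default is the packaged supernatant quantification table.
#' @return A tibble.
#' @export
read_concentration_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "excreted_compounds.csv",
      package = "knallgas", mustWork = TRUE
    )
  }
  readr::read_csv(path, col_types = readr::cols(
    compound = readr::col_character(),
    concentration_um = readr::col_double(),
    method = readr::col_character()
  ))
}
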