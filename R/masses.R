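# Monoisotopic atomic masses (CODATA/AME, Da) for the elements occurring in
# small metabolites; the electron mass is needed for adduct arithmetic.
ATOMIC_MASSES <- c(
  C = 12, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196,
  S = 31.97207100, P = 30.97376163, Na = 22.9897692809
)
ELECTRON_MASS <- 0.000548579909

#' Parse a molecular formula into element counts
#'
#' @param formula A Hill-style formula string such as `"C5H11NO2"`.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C5H11NO2")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("[A-Z][a-z]?\\d*", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(tokens)) != nchar(formula)) {
    stop("cannot parse formula: ", formula, call. = FALSE)
  }
  elements <- sub("\\d+$", "", tokens)
  counts <- as.integer(ifelse(grepl("\\d+$", tokens),
    sub("^[A-Za-z]+", "", tokens), "1"
  ))
  unknown <- setdiff(elements, names(ATOMIC_MASSES))
  if (length(unknown)) {
    stop("no monoisotopic mass for element(s): ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  tapply(counts, factor(elements, levels = unique(elements)), sum)
}

#' Monoisotopic mass of a neutral molecule
#'
#' Computed from tabulated monoisotopic atomic masses at call time, so
#' formula/mass consistency is checkable rather than hard-coded.
#'
#' @param formula Molecular formula string.
#' @return Monoisotopic mass (Da).
#' @examples
#' monoisotopic_mass("C5H11NO2") # valine, 117.0790
#' @export
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  sum(ATOMIC_MASSES[names(counts)] * counts)
}

#' Load a compound registry
#'
#' Reads a two-column TSV (`name`, `formula`) and derives carbon and nitrogen
#' counts and the monoisotopic mass from the formula. The packaged default
#' registry holds the 20 proteinogenic amino acids plus homoserine,
#' homoserine lactone and 2-aminobutyric acid (homoalanine), the compound
#' classes relevant to an amino-acid-dominated exometabolome.
#'
#' @param path Path to a registry TSV; default is the packaged registry.
#' @return A tibble: `name`, `formula`, `n_carbon`, `n_nitrogen`,
#'   `monoisotopic_mass`.
#' @export
load_compound_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "compound_registry.tsv",
      package = "knallgas", mustWork = TRUE
    )
  }
  reg <- readr::read_tsv(path, col_types = readr::cols(
    name = readr::col_character(), formula = readr::col_character()
  ))
  if (nrow(reg) == 0) stop("compound registry is empty", call. = FALSE)
  counts <- lapply(reg$formula, parse_formula)
  reg$n_carbon <- vapply(counts, function(x) sum(x[names(x) == "C"]), 1)
  reg$n_nitrogen <- vapply(counts, function(x) sum(x[names(x) == "N"]), 1)
  reg$monoisotopic_mass <- vapply(reg$formula, monoisotopic_mass, 1,
    USE.NAMES = FALSE
  )
  reg
}

ADDUCT_SHIFTS <- c(
  "M+H" = 1.00727646688, # proton
  "M+Na" = 22.9897692809 - 0.000548579909, # sodium cation
  "M-H" = -1.00727646688
)

#' Match an accurate mass against a compound registry
#'
#' Returns all registry compounds whose adduct ion mass lies within
#' `tol_ppm` of the observed m/z, ranked by absolute mass error. Compounds
#' with identical formulas (Ile/Leu, Thr/Hse) are indistinguishable by
#' accurate mass and are all returned.
#'
#' @param mz Observed m/z (Th).
#' @param adduct One of `"M+H"`, `"M+Na"`, `"M-H"`.
#' @param registry A compound registry, see [load_compound_registry()].
#' @param tol_ppm Mass tolerance (ppm).
#' @return A tibble of candidates with `mz_theoretical` and `delta_ppm`,
#'   sorted by `abs(delta_ppm)`; zero rows when nothing matches.
#' @examples
#' match_mass(118.0863, "M+H")
#' @export
match_mass <- function(mz, adduct = c("M+H", "M+Na", "M-H"),
                       registry = load_compound_registry(), tol_ppm = 10) {
  if (length(adduct) == 1L && !adduct %in% names(ADDUCT_SHIFTS)) {
    stop("unknown adduct: ", adduct, call. = FALSE)
  }
  adduct <- match.arg(adduct)
  stopifnot(is.numeric(mz), length(mz) == 1L, mz > 0, tol_ppm > 0)
  if (nrow(registry) == 0) stop("registry is empty", call. = FALSE)
  cand <- registry
  cand$mz_theoretical <- cand$monoisotopic_mass + ADDUCT_SHIFTS[[adduct]]
  cand$delta_ppm <- (mz - cand$mz_theoretical) / cand$mz_theoretical * 1e6
  cand <- cand[abs(cand$delta_ppm) <= tol_ppm, , drop = FALSE]
  cand$adduct <- rep(adduct, nrow(cand))
  dplyr::arrange(tibble::as_tibble(cand), abs(.data$delta_ppm))
}
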