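#' Group statistics for an LC-MS feature table
#'
#' Adds (or refreshes) the three statistics the abundance filter works on:
#' `fold_change` (mean supernatant / mean blank intensity), `p_value`
#' (two-sided Welch t-test on log10-transformed intensities, the usual
#' behaviour of online XCMS-style comparisons), and `max_intensity` (maximum
#' across all samples). A feature with fewer than two finite replicates in
#' either group gets `NA` statistics with a warning.
#'
#' @param features A tibble with per-sample intensity columns matching
#'   `sup_pattern` and `blank_pattern`.
#' @param sup_pattern,blank_pattern Regular expressions selecting the
#'   supernatant and blank intensity columns.
#' @return The table with `fold_change`, `p_value`, `max_intensity` columns.
#' @export
compute_feature_stats <- function(features, sup_pattern = "^supernatant_",
                                  blank_pattern = "^blank_") {
  features <- tibble::as_tibble(features)
  sup_cols <- grep(sup_pattern, names(features), value = TRUE)
  blk_cols <- grep(blank_pattern, names(features), value = TRUE)
  if (length(sup_cols) == 0 || length(blk_cols) == 0) {
    stop("feature table must contain supernatant and blank intensity columns",
      call. = FALSE
    )
  }
  n <- nrow(features)
  sup_m <- as.matrix(features[sup_cols])
  blk_m <- as.matrix(features[blk_cols])
  fc <- p <- mx <- rep(NA_real_, n)
  skipped <- 0L
  for (i in seq_len(n)) {
    sup <- sup_m[i, ]
    blk <- blk_m[i, ]
    sup <- sup[is.finite(sup)]
    blk <- blk[is.finite(blk)]
    if (length(sup) < 2 || length(blk) < 2) {
      skipped <- skipped + 1L
      next
    }
    mx[i] <- max(c(sup, blk))
    fc[i] <- if (mean(blk) > 0) mean(sup) / mean(blk) else Inf
    lsup <- log10(sup + 1)
    lblk <- log10(blk + 1)
    p[i] <- if (stats::var(lsup) + stats::var(lblk) == 0) {
      if (mean(lsup) == mean(lblk)) 1 else 0
    } else {
      stats::t.test(lsup, lblk, var.equal = FALSE)$p.value
    }
  }
  if (skipped > 0) {
    warning(skipped, " feature(s) lacked >=2 replicates in a group; ",
      "statistics set to NA"
    )
  }
  features$fold_change <- fc
  features$p_value <- p
  features$max_intensity <- mx
  features
}

#' Abundance filter for supernatant-versus-blank feature tables
#'
#' Keeps features more abundant in the culture supernatant than in blank
#' medium (`fold_change > fc_min` and `p_value < p_max`) and present at high
#' level (`max_intensity > intensity_min`). All three inequalities are
#' strict, matching the conventional reading of "fold-change > 5, p < 0.05,
#' max intensity > 1e6"; a feature sitting exactly on a threshold is removed.
#' Features with `NA` statistics (missing group) are dropped with a warning.
#' Row order is preserved, so the filter is idempotent.
#'
#' @param features A feature table; statistics are computed on the fly with
#'   [compute_feature_stats()] if absent.
#' @param fc_min Fold-change threshold.
#' @param p_max p-value threshold.
#' @param intensity_min Maximum-intensity threshold.
#' @return The kept rows, in their original order.
#' @examples
#' ft <- simulate_feature_table(feature_sim_params(seed = 1))
#' nrow(filter_features(ft))
#' @export
filter_features <- function(features, fc_min = 5, p_max = 0.05,
                            intensity_min = 1e6) {
  features <- tibble::as_tibble(features)
  stat_cols <- c("fold_change", "p_value", "max_intensity")
  if (!all(stat_cols %in% names(features))) {
    features <- compute_feature_stats(features)
  }
  incomplete <- !stats::complete.cases(features[stat_cols])
  if (any(incomplete)) {
    warning(sum(incomplete), " feature(s) skipped: missing group statistics")
  }
  dplyr::filter(
    features[!incomplete, , drop = FALSE],
    .data$fold_change > fc_min,
    .data$p_value < p_max,
    .data$max_intensity > intensity_min
  )
}

#' Flag isotope satellites and in-source fragments
#'
#' Annotates LC-MS artifacts that survive abundance filtering because they
#' track a genuine compound. A feature is flagged `flag_isotope` when a
#' co-eluting feature sits one isotope spacing below it in m/z with higher
#' intensity (a 13C satellite of that parent); it is flagged `flag_fragment`
#' when a co-eluting, higher-m/z, more intense feature exists whose
#' per-sample intensity pattern correlates with it (Pearson r >
#' `cor_min`), the signature of an in-source fragment. Flags are
#' annotations only; removing flagged rows is a separate, explicit step.
#'
#' @param features A feature table with `mz`, `rt` and per-sample intensity
#'   columns.
#' @param mz_tol_ppm m/z tolerance for the isotope spacing (ppm).
#' @param rt_tol_s Co-elution tolerance (s).
#' @param isotope_delta Isotope spacing (Th); default the 13C-12C mass
#'   difference.
#' @param cor_min Minimum intensity-pattern correlation for a fragment call.
#' @return The table with logical columns `flag_isotope` and `flag_fragment`.
#' @examples
#' ft <- simulate_feature_table(feature_sim_params(seed = 1))
#' kept <- filter_features(ft)
#' flagged <- flag_isotopes_and_fragments(kept)
#' sum(flagged$flag_isotope | flagged$flag_fragment)
#' @export
flag_isotopes_and_fragments <- function(features, mz_tol_ppm = 10,
                                        rt_tol_s = 5,
                                        isotope_delta = 1.00336,
                                        cor_min = 0.9) {
  features <- tibble::as_tibble(features)
  int_cols <- grep("^(supernatant|blank)_", names(features), value = TRUE)
  if (!all(c("mz", "rt") %in% names(features)) || length(int_cols) == 0) {
    stop("feature table must carry `mz`, `rt` and per-sample intensities",
      call. = FALSE
    )
  }
  n <- nrow(features)
  inten <- as.matrix(features[int_cols])
  level <- apply(inten, 1L, max)
  iso <- frag <- logical(n)
  for (i in seq_len(n)) {
    coelute <- abs(features$rt - features$rt[i]) <= rt_tol_s & seq_len(n) != i
    if (!any(coelute)) next
    tol_da <- mz_tol_ppm * 1e-6 * features$mz[i]
    parent_iso <- coelute &
      abs(features$mz[i] - features$mz - isotope_delta) <= tol_da &
      level > level[i]
    if (any(parent_iso)) {
      iso[i] <- TRUE
      next
    }
    cand <- which(coelute & features$mz > features$mz[i] & level > level[i])
    for (j in cand) {
      if (stats::sd(inten[i, ]) == 0 || stats::sd(inten[j, ]) == 0) next
      if (stats::cor(inten[i, ], inten[j, ]) > cor_min) {
        frag[i] <- TRUE
        break
      }
    }
  }
  features$flag_isotope <- iso
  features$flag_fragment <- frag
  features
}
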