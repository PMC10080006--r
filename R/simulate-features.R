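#' Parameters for the LC-MS feature-table generator
#'
#' Controls the composition of a synthetic untargeted-metabolomics peak
#' table: genuinely excreted compounds ("true signals"), medium components
#' present only in the blank, low-abundance features, 13C isotope satellites
#' co-eluting at +1.00336 Th of a parent, and in-source fragments co-eluting
#' at lower m/z with intensities correlated to their parent. Defaults
#' reproduce the bookkeeping of a supernatant-versus-blank comparison in
#' which 12 features pass the abundance filter, 5 of them are isotope or
#' fragment artifacts, and 1 of the remaining 7 is irreproducible, leaving 6
#' annotatable compounds.
#'
#' @param n_true_signals Number of genuine supernatant features (includes the
#'   `n_irreproducible` ones).
#' @param n_blank_only Features more abundant in the blank medium.
#' @param n_low_intensity Supernatant features below the intensity threshold.
#' @param n_isotope_satellites Isotope satellites planted on the first true
#'   signals.
#' @param n_insource_fragments In-source fragments planted on subsequent true
#'   signals.
#' @param n_irreproducible True signals labelled irreproducible (they pass
#'   every automatic filter; their removal is a separate explicit step).
#' @param replicates Replicate injections per group (supernatant, blank).
#' @param rt_range,mz_range Uniform sampling ranges for retention time (s)
#'   and m/z (Th).
#' @param isotope_delta Mass offset of an isotope satellite (Th).
#' @param seed Integer seed.
#' @return A validated list of class `feature_sim_params`.
#' @export
feature_sim_params <- function(n_true_signals = 7, n_blank_only = 20,
                               n_low_intensity = 15,
                               n_isotope_satellites = 3,
                               n_insource_fragments = 2,
                               n_irreproducible = 1, replicates = 3,
                               rt_range = c(60, 840), mz_range = c(80, 600),
                               isotope_delta = 1.00336, seed = NULL) {
  stopifnot(
    n_true_signals >= 0, n_blank_only >= 0, n_low_intensity >= 0,
    n_isotope_satellites >= 0, n_insource_fragments >= 0,
    n_irreproducible >= 0, replicates >= 2,
    length(rt_range) == 2, length(mz_range) == 2,
    rt_range[1] < rt_range[2], mz_range[1] < mz_range[2],
    isotope_delta > 0
  )
  if (n_isotope_satellites + n_insource_fragments > n_true_signals) {
    stop("satellites + fragments cannot outnumber their true-signal parents",
      call. = FALSE
    )
  }
  if (n_irreproducible > n_true_signals) {
    stop("`n_irreproducible` cannot exceed `n_true_signals`", call. = FALSE)
  }
  structure(
    list(
      n_true_signals = n_true_signals, n_blank_only = n_blank_only,
      n_low_intensity = n_low_intensity,
      n_isotope_satellites = n_isotope_satellites,
      n_insource_fragments = n_insource_fragments,
      n_irreproducible = n_irreproducible, replicates = replicates,
      rt_range = rt_range, mz_range = mz_range,
      isotope_delta = isotope_delta, seed = seed
    ),
    class = "feature_sim_params"
  )
}

#' Simulate an untargeted LC-MS feature table
#'
#' Generates a wide peak table with supernatant and blank replicate columns
#' and a ground-truth `class` label per feature. True signals pass the
#' standard abundance filter (fold change, Welch p, maximum intensity) by
#' construction; blank-only and low-intensity features fail it; isotope
#' satellites and in-source fragments pass it but co-elute with a more
#' intense parent and are meant to be caught by
#' [flag_isotopes_and_fragments()].
#'
#' @param params A [feature_sim_params()] object.
#' @return A tibble with columns `feature_id`, `mz`, `rt`, `class`,
#'   `parent_id` (NA except for satellites/fragments), the per-sample
#'   intensity columns `supernatant_*` and `blank_*`, and the group
#'   statistics `fold_change`, `p_value`, `max_intensity` (from
#'   [compute_feature_stats()]).
#' @examples
#' ft <- simulate_feature_table(feature_sim_params(seed = 1))
#' dplyr::count(ft, class)
#' @export
simulate_feature_table <- function(params = feature_sim_params()) {
  if (!inherits(params, "feature_sim_params")) {
    params <- do.call(feature_sim_params, params)
  }
  run <- function() simulate_feature_table_impl(params)
  if (is.null(params$seed)) run() else withr::with_seed(params$seed, run())
}

simulate_feature_table_impl <- function(p) {
  r <- p$replicates
  sup_cols <- paste0("supernatant_", seq_len(r))
  blk_cols <- paste0("blank_", seq_len(r))
  empty <- tibble::as_tibble(c(
    list(
      feature_id = character(), mz = numeric(), rt = numeric(),
      class = character(), parent_id = character()
    ),
    stats::setNames(rep(list(numeric()), 2 * r), c(sup_cols, blk_cols))
  ))
  rep_noise <- function(base, cv = 0.05) {
    pmax(0, base * stats::rnorm(r, mean = 1, sd = cv))
  }
  make_rows <- function(n, class, base_log10, fc, rts = NULL) {
    if (n == 0) {
      return(empty)
    }
    purrr::map_dfr(seq_len(n), function(i) {
      base <- 10^stats::runif(1, base_log10[1], base_log10[2])
      ratio <- stats::runif(1, fc[1], fc[2])
      sup <- rep_noise(base)
      blk <- rep_noise(base / ratio, cv = 0.2)
      tibble::as_tibble(c(
        list(
          feature_id = paste0(class, "_", i),
          mz = stats::runif(1, p$mz_range[1], p$mz_range[2]),
          rt = if (is.null(rts)) {
            stats::runif(1, p$rt_range[1], p$rt_range[2])
          } else {
            rts[i]
          },
          class = class, parent_id = NA_character_
        ),
        stats::setNames(as.list(c(sup, blk)), c(sup_cols, blk_cols))
      ))
    })
  }
  # distinct compounds elute at distinct times: draw true-signal retention
  # times from a 25-s grid so only planted satellites/fragments co-elute
  rt_slots <- seq(p$rt_range[1], p$rt_range[2], by = 25)
  if (p$n_true_signals > length(rt_slots)) {
    stop("rt_range too narrow for the requested number of true signals",
      call. = FALSE
    )
  }
  true_rts <- sample(rt_slots, p$n_true_signals)
  true_sig <- make_rows(p$n_true_signals, "true_signal",
    base_log10 = c(7.2, 8), fc = c(20, 100), rts = true_rts
  )
  if (p$n_irreproducible > 0 && nrow(true_sig) > 0) {
    idx <- utils::tail(seq_len(nrow(true_sig)), p$n_irreproducible)
    true_sig$class[idx] <- "irreproducible"
    true_sig$feature_id[idx] <- paste0("irreproducible_", seq_along(idx))
  }
  derived <- function(n, class, mz_shift, int_frac, offset) {
    if (n == 0) {
      return(empty)
    }
    purrr::map_dfr(seq_len(n), function(i) {
      parent <- true_sig[offset + i, ]
      frac <- stats::runif(1, int_frac[1], int_frac[2])
      row <- parent
      row$feature_id <- paste0(class, "_", i)
      row$mz <- mz_shift(parent$mz)
      row$rt <- parent$rt + stats::runif(1, -1, 1)
      row$class <- class
      row$parent_id <- parent$feature_id
      # same relative pattern as the parent, scaled down: correlated by
      # construction, as real satellites and in-source fragments are
      row[c(sup_cols, blk_cols)] <-
        as.list(frac * as.numeric(parent[1, c(sup_cols, blk_cols)]))
      row
    })
  }
  satellites <- derived(
    p$n_isotope_satellites, "isotope",
    mz_shift = function(mz) mz + p$isotope_delta,
    int_frac = c(0.08, 0.15), offset = 0
  )
  fragments <- derived(
    p$n_insource_fragments, "fragment",
    mz_shift = function(mz) pmax(p$mz_range[1] / 2, mz - stats::runif(1, 20, 60)),
    int_frac = c(0.2, 0.5), offset = p$n_isotope_satellites
  )
  blank_only <- make_rows(p$n_blank_only, "blank_only",
    base_log10 = c(4, 5.5), fc = c(20, 100)
  )
  if (nrow(blank_only)) { # swap groups: abundant in blank, weak in supernatant
    tmp <- blank_only[sup_cols]
    blank_only[sup_cols] <- blank_only[blk_cols] * 0.02
    blank_only[blk_cols] <- tmp * 50
  }
  low_int <- make_rows(p$n_low_intensity, "low_intensity",
    base_log10 = c(4.5, 5.7), fc = c(10, 50)
  )
  out <- dplyr::bind_rows(true_sig, satellites, fragments, blank_only, low_int)
  if (nrow(out) == 0) {
    return(compute_feature_stats(empty))
  }
  compute_feature_stats(out)
}
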