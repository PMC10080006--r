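two_group_row <- function(id, mz, rt, sup, blk) {
  tibble::tibble(
    feature_id = id, mz = mz, rt = rt,
    supernatant_1 = sup[1], supernatant_2 = sup[2], supernatant_3 = sup[3],
    blank_1 = blk[1], blank_2 = blk[2], blank_3 = blk[3]
  )
}

test_that("the abundance filter applies all three thresholds strictly", {
  ft <- tibble::tibble(
    feature_id = c("pass", "fc_at_edge", "p_at_edge", "dim", "all_fail"),
    mz = 100 + 1:5, rt = 100 + 10 * (1:5),
    fold_change = c(6, 5, 8, 9, 1),
    p_value = c(0.01, 0.01, 0.05, 0.001, 0.5),
    max_intensity = c(2e6, 2e6, 2e6, 1e6, 1e5)
  )
  kept <- filter_features(ft)
  expect_equal(kept$feature_id, "pass")
})

test_that("filtering is idempotent and preserves order", {
  ft <- simulate_feature_table(feature_sim_params(seed = 2))
  once <- filter_features(ft)
  twice <- filter_features(once)
  expect_identical(once, twice)
  expect_identical(once$feature_id, ft$feature_id[ft$feature_id %in% once$feature_id])
})

test_that("group statistics flag features lacking replicates", {
  ft <- two_group_row("a", 100, 100, c(2e6, 2.1e6, 1.9e6), c(1e4, NA, NA))
  expect_warning(out <- compute_feature_stats(ft), "replicates")
  expect_true(is.na(out$p_value))
  expect_warning(kept <- filter_features(out), "skipped")
  expect_equal(nrow(kept), 0)
})

test_that("a co-eluting +1.00336 satellite is flagged as an isotope", {
  parent <- two_group_row(
    "val", 118.0863, 240, c(2e7, 2.1e7, 1.9e7), c(1e5, 1.2e5, 0.9e5)
  )
  sat <- two_group_row(
    "val_13c", 119.0897, 240.5, c(2e6, 2.1e6, 1.9e6), c(1e4, 1.2e4, 0.9e4)
  )
  out <- flag_isotopes_and_fragments(dplyr::bind_rows(parent, sat))
  expect_equal(out$flag_isotope, c(FALSE, TRUE))
  expect_equal(out$flag_fragment, c(FALSE, FALSE))
})

test_that("co-elution is required for any artifact call", {
  parent <- two_group_row(
    "a", 118.0863, 240, c(2e7, 2.1e7, 1.9e7), c(1e5, 1.2e5, 0.9e5)
  )
  far <- two_group_row(
    "b", 119.0897, 290, c(2e6, 2.1e6, 1.9e6), c(1e4, 1.2e4, 0.9e4)
  )
  out <- flag_isotopes_and_fragments(dplyr::bind_rows(parent, far))
  expect_false(any(out$flag_isotope))
  expect_false(any(out$flag_fragment))
})

test_that("the 12 -> 5 flagged -> 7 -> 6 bookkeeping holds by construction", {
  ft <- simulate_feature_table(feature_sim_params(seed = 1))
  kept <- filter_features(ft)
  expect_equal(nrow(kept), 12)
  flagged <- flag_isotopes_and_fragments(kept)
  artifact <- flagged$flag_isotope | flagged$flag_fragment
  expect_equal(sum(artifact), 5)
  expect_setequal(flagged$class[artifact], c("isotope", "fragment"))
  remaining <- dplyr::filter(flagged, !artifact)
  expect_equal(nrow(remaining), 7)
  reproducible <- dplyr::filter(remaining, .data$class != "irreproducible")
  expect_equal(nrow(reproducible), 6)
})

test_that("the most intense feature of a co-eluting group is never flagged an isotope", {
  for (seed in 1:10) {
    ft <- simulate_feature_table(feature_sim_params(seed = 300 + seed))
    flagged <- flag_isotopes_and_fragments(ft)
    level <- apply(
      as.matrix(flagged[grep("^(supernatant|blank)_", names(flagged))]), 1, max
    )
    for (i in which(flagged$flag_isotope)) {
      peers <- abs(flagged$rt - flagged$rt[i]) <= 5
      expect_lt(level[i], max(level[peers]))
    }
  }
})

test_that("kept-minus-flagged equals the planted true signals across random tables", {
  for (seed in 1:25) {
    p <- feature_sim_params(seed = 400 + seed)
    ft <- simulate_feature_table(p)
    kept <- filter_features(ft)
    flagged <- flag_isotopes_and_fragments(kept)
    survivors <- dplyr::filter(
      flagged, !.data$flag_isotope & !.data$flag_fragment
    )
    expect_setequal(
      survivors$feature_id,
      ft$feature_id[ft$class %in% c("true_signal", "irreproducible")]
    )
  }
})

test_that("empty parameter sets give empty, well-formed tables", {
  p <- feature_sim_params(
    n_true_signals = 0, n_blank_only = 0, n_low_intensity = 0,
    n_isotope_satellites = 0, n_insource_fragments = 0,
    n_irreproducible = 0, seed = 1
  )
  ft <- simulate_feature_table(p)
  expect_equal(nrow(ft), 0)
  expect_true(all(c("mz", "rt", "fold_change", "p_value") %in% names(ft)))
})

test_that("feature tables are seed-reproducible", {
  a <- simulate_feature_table(feature_sim_params(seed = 9))
  b <- simulate_feature_table(feature_sim_params(seed = 9))
  expect_identical(a, b)
})
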