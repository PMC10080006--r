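test_that("without consumption the signal is a step to baseline + gain * dS", {
  adds <- tibble::tibble(
    time_s = 100, kind = "analyte", volume_ml = 1, conc_nm = 250000
  ) # 1 mL x 250 uM into 0.5 L = 500 nM
  tr <- noiseless_trace(
    vmax_specific = 0, additions = adds, duration = 400,
    baseline = 1000, signal_gain = 100
  )
  expect_equal(unique(tr$signal_counts[tr$time_s < 100]), 1000)
  expect_equal(unique(tr$signal_counts[tr$time_s >= 100]), 1000 + 100 * 500)
})

test_that("substrate mass is conserved at every step of a noiseless trace", {
  tr <- noiseless_trace()
  truth <- attr(tr, "truth")
  adds <- attr(tr, "additions")
  dt <- attr(tr, "dt")
  s <- tr$s_true_nm
  # re-walk the series: each step must equal the MM rate drawn down from the
  # previous state plus any injected substrate -- nothing else
  jump_at <- numeric(nrow(tr))
  step_idx <- ceiling(adds$time_s / dt) + 1L
  jump_at[step_idx] <- adds$delta_s_nm
  expected <- vapply(seq_len(nrow(tr) - 1L), function(i) {
    max(
      0,
      s[i] - truth$vmax_chamber * s[i] / (truth$ks + s[i]) * dt / 60
    ) + jump_at[i + 1L]
  }, numeric(1))
  expect_equal(s[-1L], expected, tolerance = 1e-12)
  # and the ledger closes: added = consumed + remaining
  consumed <- sum(s[-length(s)] - (s[-1] - jump_at[-1]))
  expect_equal(consumed + s[length(s)], sum(adds$delta_s_nm),
    tolerance = 1e-9
  )
})

test_that("each noiseless pulse follows the implicit closed-form solution", {
  tr <- noiseless_trace() |> calibrate_signal()
  truth <- attr(tr, "truth")
  segs <- segment_pulses(tr)
  expect_equal(nrow(segs), 8)
  for (k in seq_len(nrow(segs))) {
    d <- segs$data[[k]]
    t_min <- (d$time_s - d$time_s[1]) / 60
    cont <- mm_implicit_oracle(d$conc_nm[1], truth$vmax_chamber, truth$ks, t_min)
    expect_lt(max(abs(d$conc_nm - cont)) / d$conc_nm[1], 0.005)
  }
})

test_that("a fixed seed reproduces a Poisson-noise trace bitwise", {
  a <- simulate_mims_trace(mims_sim_params(seed = 11))
  b <- simulate_mims_trace(mims_sim_params(seed = 11))
  expect_identical(a$signal_counts, b$signal_counts)
  c <- simulate_mims_trace(mims_sim_params(seed = 12))
  expect_false(identical(a$signal_counts, c$signal_counts))
})

test_that("invalid addition schedules are rejected", {
  bad_overlap <- tibble::tibble(
    time_s = c(100, 100), kind = "analyte", volume_ml = 1, conc_nm = NA_real_
  )
  expect_error(mims_sim_params(additions = bad_overlap), "overlap")
  bad_volume <- tibble::tibble(
    time_s = 100, kind = "analyte", volume_ml = -1, conc_nm = NA_real_
  )
  expect_error(mims_sim_params(additions = bad_volume), "volume")
  bad_time <- tibble::tibble(
    time_s = 5000, kind = "analyte", volume_ml = 1, conc_nm = NA_real_
  )
  expect_error(
    mims_sim_params(additions = bad_time, duration = 2700), "duration"
  )
})
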