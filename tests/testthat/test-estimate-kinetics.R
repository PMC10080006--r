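test_that("noiseless traces give back the generating kinetics almost exactly", {
  fit <- noiseless_trace() |>
    calibrate_signal() |>
    estimate_kinetics()
  expect_equal(fit$vmax_app_mean, 953, tolerance = 0.005)
  expect_equal(fit$ks_app_mean, 353, tolerance = 0.005)
  expect_lt(fit$vmax_app_sd / fit$vmax_app_mean, 0.005)
  expect_equal(fit$n_vmax, 4)
  expect_equal(fit$n_ks, 4)
})

test_that("starvation lowers late-round Vmax but not the Ks estimate", {
  fit <- noiseless_trace(
    starved_vmax_factor = 0.7, starvation_onset_s = 1490
  ) |>
    calibrate_signal() |>
    estimate_kinetics()
  # first four rounds precede the starvation onset
  expect_equal(fit$vmax_app_mean, 953, tolerance = 0.01)
  # last four rounds run at the reduced Vmax, Ks untouched
  late <- fit$rounds[fit$rounds$pulse %in% fit$ks_pulses, ]
  expect_equal(mean(late$vmax_app), 0.7 * 953, tolerance = 0.02)
  expect_equal(fit$ks_app_mean, 353, tolerance = 0.02)
})

test_that("recovered Ks rises with the simulated Ks", {
  est <- purrr::map_dbl(c(150, 353, 700), function(ks_true) {
    adds <- tibble::tibble(
      time_s = c(60, 300), kind = c("calibration", "analyte"),
      volume_ml = c(0.64, 1), conc_nm = NA_real_
    )
    seg <- noiseless_trace(ks = ks_true, additions = adds, duration = 700) |>
      calibrate_signal() |>
      segment_pulses()
    fit_pulse(seg$data[[1]], dt = 1, biomass_mg = 0.5, chamber_volume = 0.5)$ks_app
  })
  expect_true(all(diff(est) > 0))
})

test_that("recovery from counting noise is nearly unbiased and tightens as noise shrinks", {
  fits <- purrr::map_dfr(1:25, function(i) {
    tr <- simulate_mims_trace(mims_sim_params(seed = 500 + i))
    glance(estimate_kinetics(calibrate_signal(tr)))
  })
  expect_lt(abs(mean(fits$vmax_app_mean) - 953) / 953, 0.05)
  expect_lt(abs(mean(fits$ks_app_mean) - 353) / 353, 0.05)
  spread <- function(noise_sd) {
    ks <- purrr::map_dbl(1:8, function(i) {
      tr <- simulate_mims_trace(mims_sim_params(
        noise = "gaussian", noise_sd = noise_sd, seed = 900 + i
      ))
      estimate_kinetics(calibrate_signal(tr))$ks_app_mean
    })
    sd(ks)
  }
  expect_lt(spread(20), spread(600))
})

test_that("aggregation needs enough converged rounds", {
  cal <- noiseless_trace(vmax_specific = 0) |> calibrate_signal()
  expect_error(
    suppressWarnings(estimate_kinetics(cal)),
    "converged"
  )
})

test_that("short pulse trains overlap the two aggregation sets with a warning", {
  adds <- mims_additions(n_pulses = 5)
  cal <- noiseless_trace(additions = adds, duration = 1800) |>
    calibrate_signal()
  expect_warning(fit <- estimate_kinetics(cal), "overlap")
  expect_equal(fit$n_vmax, 4)
  expect_equal(fit$n_ks, 4)
})

test_that("doubling times follow ln(2)/rate", {
  expect_equal(round(doubling_time(0.034)), 20)
  expect_equal(round(doubling_time(0.14), 1), 5.0)
  expect_equal(doubling_time(log(2)), 1)
  expect_error(doubling_time(0), "positive")
  expect_error(doubling_time(-0.1), "positive")
})

test_that("tidy and glance expose per-pulse and aggregate views", {
  fit <- noiseless_trace() |>
    calibrate_signal() |>
    estimate_kinetics()
  td <- tidy(fit)
  expect_equal(nrow(td), 8)
  expect_setequal(
    td$used_for[td$pulse %in% 1:4], "vmax"
  )
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_named(gl, c(
    "vmax_app_mean", "vmax_app_sd", "n_vmax",
    "ks_app_mean", "ks_app_sd", "n_ks", "n_pulses", "dt"
  ))
})
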