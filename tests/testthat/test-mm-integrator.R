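test_that("zero-rate and zero-Ks limits behave as closed forms", {
  # no consumption: constant series
  expect_equal(
    integrate_mm_depletion(500, 0, 353, dt = 1, duration = 60),
    rep(500, 61)
  )
  # zero-order limit: linear decrease of vmax per minute, clamped at zero
  s <- integrate_mm_depletion(1000, 100, 0, dt = 1, duration = 900)
  expect_equal(s[61], 900) # 100 nM consumed over the first 60 s
  expect_equal(s[601], 0) # budget exhausted at 10 min
  expect_true(all(s >= 0))
  expect_true(all(diff(s) <= 0))
})

test_that("non-finite or negative inputs are rejected", {
  expect_error(integrate_mm_depletion(NA, 1, 1, 1, 10), "finite")
  expect_error(integrate_mm_depletion(100, Inf, 1, 1, 10), "finite")
  expect_error(integrate_mm_depletion(-1, 1, 1, 1, 10), "non-negative")
  expect_error(integrate_mm_depletion(100, 1, 1, 0, 10), "positive")
})

test_that("discrete depletion tracks the implicit continuous solution", {
  # the continuous solution is asymptotic in S while the discrete one clamps,
  # so agreement is measured relative to the pulse size S0
  withr::with_seed(42, {
    params <- tibble::tibble(
      s0 = runif(22, 300, 3000),
      vmax = runif(22, 50, 1200),
      ks = runif(22, 20, 1500)
    )
  })
  for (i in seq_len(nrow(params))) {
    s0 <- params$s0[i]
    vmax <- params$vmax[i]
    ks <- params$ks[i]
    t_s <- 0:300
    disc <- integrate_mm_depletion(s0, vmax, ks, dt = 1, duration = 300)
    cont <- mm_implicit_oracle(s0, vmax, ks, t_s / 60)
    expect_lt(max(abs(disc - cont)) / s0, 0.005)
  }
})

test_that("dt = 1 s agrees with a dt = 1 ms reference trajectory", {
  withr::with_seed(7, {
    params <- tibble::tibble(
      s0 = runif(6, 300, 3000),
      vmax = runif(6, 50, 1200),
      ks = runif(6, 20, 1500)
    )
  })
  for (i in seq_len(nrow(params))) {
    s0 <- params$s0[i]
    coarse <- integrate_mm_depletion(s0, params$vmax[i], params$ks[i],
      dt = 1, duration = 240
    )
    fine <- integrate_mm_depletion(s0, params$vmax[i], params$ks[i],
      dt = 0.001, duration = 240
    )
    fine_on_grid <- fine[seq(1, length(fine), by = 1000)]
    expect_lt(max(abs(coarse - fine_on_grid)) / s0, 0.005)
  }
})

test_that("worked depletion example matches the bisection oracle", {
  disc <- integrate_mm_depletion(1000, 100, 353, dt = 1, duration = 300)
  s_300 <- mm_implicit_oracle(1000, 100, 353, 5)
  expect_equal(disc[301], s_300, tolerance = 0.005)
})
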