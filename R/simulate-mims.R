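#' Default addition schedule for a simulated MIMS experiment
#'
#' One calibration addition of H2-saturated water followed by a train of
#' analyte pulses, mirroring the bench procedure in which known amounts of
#' gas-saturated water are injected into a stirred, membrane-coupled chamber.
#'
#' @param n_pulses Number of analyte (substrate) additions.
#' @param start_s Time of the first analyte addition (s).
#' @param spacing_s Interval between analyte additions (s).
#' @param volume_ml Injected volume per analyte addition (mL).
#' @param calibration_times_s Times of calibration additions (s).
#' @param calibration_volume_ml Injected volume per calibration addition (mL).
#' @return A tibble with columns `time_s`, `kind`, `volume_ml`, `conc_nm`
#'   (`NA` means the injected liquid is at the saturation concentration).
#' @export
mims_additions <- function(n_pulses = 8, start_s = 300, spacing_s = 300,
                           volume_ml = 1, calibration_times_s = 60,
                           calibration_volume_ml = 0.64) {
  dplyr::bind_rows(
    tibble::tibble(
      time_s = as.numeric(calibration_times_s),
      kind = "calibration",
      volume_ml = calibration_volume_ml,
      conc_nm = NA_real_
    ),
    tibble::tibble(
      time_s = start_s + spacing_s * (seq_len(n_pulses) - 1),
      kind = "analyte",
      volume_ml = volume_ml,
      conc_nm = NA_real_
    )
  ) |>
    dplyr::arrange(.data$time_s)
}

#' Parameters for the MIMS trace simulator
#'
#' Bundles and validates the ground-truth kinetics, chamber geometry, addition
#' schedule and detector model used by [simulate_mims_trace()]. Defaults
#' describe a 0.5-L chamber holding 0.5 mg dry weight of cells with apparent
#' whole-cell kinetics Vmax = 953 nM/min/mg DW and Ks = 353 nM, probed with
#' one calibration addition and eight analyte pulses of H2-saturated water.
#'
#' @param chamber_volume Liquid volume of the incubation chamber (L).
#' @param biomass_mg Dry weight of cells in the chamber (mg).
#' @param vmax_specific True specific maximal uptake rate (nM/min/mg DW).
#' @param ks True half-saturation constant (nM).
#' @param starved_vmax_factor Multiplier in (0, 1] applied to Vmax from
#'   `starvation_onset_s` onward; models the reduced apparent Vmax of biomass
#'   that has been without substrate, with Ks unaffected.
#' @param starvation_onset_s Time (s) from which the starvation factor
#'   applies; `Inf` disables it.
#' @param additions Addition schedule, see [mims_additions()].
#' @param signal_gain Detector gain (ion counts per nM dissolved substrate).
#' @param noise Detector noise model: `"poisson"` (counting statistics of
#'   pulsed ion counting), `"gaussian"`, or `"none"`.
#' @param noise_sd Standard deviation (counts) for `noise = "gaussian"`.
#' @param baseline Constant baseline signal (counts).
#' @param baseline_drift Linear baseline drift (counts per s).
#' @param dt Sampling/integration step (s).
#' @param duration Trace length (s).
#' @param h2_saturation_nm Dissolved concentration of the gas-saturated
#'   injection liquid (nM); default 780 uM, H2-saturated water near 25 degC
#'   and 1 atm.
#' @param seed Integer seed; identical seeds give identical traces.
#' @return A validated list of class `mims_sim_params`.
#' @export
mims_sim_params <- function(chamber_volume = 0.5, biomass_mg = 0.5,
                            vmax_specific = 953, ks = 353,
                            starved_vmax_factor = 1, starvation_onset_s = Inf,
                            additions = mims_additions(),
                            signal_gain = 100,
                            noise = c("poisson", "gaussian", "none"),
                            noise_sd = 50, baseline = 2000,
                            baseline_drift = 0, dt = 1, duration = 2700,
                            h2_saturation_nm = 7.8e5, seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(
    chamber_volume > 0, biomass_mg > 0, vmax_specific >= 0, ks >= 0,
    dt > 0, duration > 0, signal_gain > 0, baseline >= 0, noise_sd >= 0,
    h2_saturation_nm > 0
  )
  if (!(starved_vmax_factor > 0 && starved_vmax_factor <= 1)) {
    stop("`starved_vmax_factor` must lie in (0, 1]", call. = FALSE)
  }
  additions <- validate_additions(additions, dt, duration)
  structure(
    list(
      chamber_volume = chamber_volume, biomass_mg = biomass_mg,
      vmax_specific = vmax_specific, ks = ks,
      starved_vmax_factor = starved_vmax_factor,
      starvation_onset_s = starvation_onset_s,
      additions = additions, signal_gain = signal_gain, noise = noise,
      noise_sd = noise_sd, baseline = baseline,
      baseline_drift = baseline_drift, dt = dt, duration = duration,
      h2_saturation_nm = h2_saturation_nm, seed = seed
    ),
    class = "mims_sim_params"
  )
}

validate_additions <- function(additions, dt, duration) {
  additions <- tibble::as_tibble(additions)
  needed <- c("time_s", "kind", "volume_ml")
  if (!all(needed %in% names(additions))) {
    stop("`additions` needs columns ", paste(needed, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"conc_nm" %in% names(additions)) additions$conc_nm <- NA_real_
  if (nrow(additions) > 0) {
    if (!all(additions$kind %in% c("analyte", "calibration"))) {
      stop("addition `kind` must be 'analyte' or 'calibration'", call. = FALSE)
    }
    if (any(additions$volume_ml <= 0)) {
      stop("addition volumes must be positive (volume bookkeeping)",
        call. = FALSE
      )
    }
    if (is.unsorted(additions$time_s, strictly = TRUE)) {
      stop("addition times must be strictly increasing (overlapping ",
        "additions are rejected)",
        call. = FALSE
      )
    }
    if (any(additions$time_s <= 0) || any(additions$time_s >= duration)) {
      stop("addition times must lie strictly inside (0, duration)",
        call. = FALSE
      )
    }
    if (any(diff(additions$time_s) < dt)) {
      stop("additions overlap within one sampling step", call. = FALSE)
    }
  }
  additions
}

#' Simulate a MIMS substrate-depletion trace
#'
#' Generates a calibrant-plus-pulse ion-count time series from ground-truth
#' Michaelis-Menten kinetics. Between additions the dissolved concentration
#' follows the explicit depletion update of [integrate_mm_depletion()]; each
#' addition raises it instantaneously by
#' `volume_ml * conc_nm / (1000 * chamber_volume)` nM. The detector reports
#' `baseline + drift * t + gain * S(t)` plus counting noise. The true
#' concentration series and parameters are kept alongside the trace so that
#' recovery by the fitting pipeline can be checked against ground truth.
#'
#' @param params A [mims_sim_params()] object.
#' @return A `mims_trace`: a tibble with columns `time_s`, `signal_counts`
#'   and `s_true_nm`, carrying the addition schedule, chamber geometry and
#'   simulation truth as attributes.
#' @examples
#' tr <- simulate_mims_trace(mims_sim_params(seed = 1))
#' tr
#' @export
simulate_mims_trace <- function(params) {
  if (!inherits(params, "mims_sim_params")) params <- do.call(mims_sim_params, params)
  run <- function() simulate_mims_trace_impl(params)
  if (is.null(params$seed)) run() else withr::with_seed(params$seed, run())
}

simulate_mims_trace_impl <- function(p) {
  n <- as.integer(round(p$duration / p$dt))
  time_s <- seq(0, by = p$dt, length.out = n + 1L)
  adds <- p$additions
  adds$delta_s_nm <- with(
    adds,
    volume_ml * ifelse(is.na(conc_nm), p$h2_saturation_nm, conc_nm) /
      (1000 * p$chamber_volume)
  )
  vmax_chamber <- p$vmax_specific * p$biomass_mg / p$chamber_volume
  s <- numeric(n + 1L)
  f <- p$dt / 60
  add_step <- if (nrow(adds)) ceiling(adds$time_s / p$dt) else integer(0)
  for (i in seq_len(n)) {
    si <- s[i]
    t_prev <- time_s[i]
    v <- vmax_chamber *
      if (t_prev >= p$starvation_onset_s) p$starved_vmax_factor else 1
    s_new <- if (si > 0) max(0, si - v * si / (p$ks + si) * f) else 0
    hit <- which(add_step == i)
    if (length(hit)) s_new <- s_new + sum(adds$delta_s_nm[hit])
    s[i + 1L] <- s_new
  }
  mu <- p$baseline + p$baseline_drift * time_s + p$signal_gain * s
  signal <- switch(p$noise,
    none = mu,
    poisson = as.numeric(stats::rpois(length(mu), lambda = mu)),
    gaussian = mu + stats::rnorm(length(mu), sd = p$noise_sd)
  )
  new_mims_trace(
    tibble::tibble(time_s = time_s, signal_counts = signal, s_true_nm = s),
    additions = adds,
    chamber_volume = p$chamber_volume,
    biomass_mg = p$biomass_mg,
    dt = p$dt,
    truth = list(
      vmax_specific = p$vmax_specific, ks = p$ks,
      vmax_chamber = vmax_chamber,
      starved_vmax_factor = p$starved_vmax_factor,
      starvation_onset_s = p$starvation_onset_s,
      signal_gain = p$signal_gain, baseline = p$baseline,
      params = p
    )
  )
}

new_mims_trace <- function(data, additions, chamber_volume, biomass_mg, dt,
                           gain = NA_real_, baseline = NA_real_,
                           truth = NULL) {
  structure(
    data,
    additions = tibble::as_tibble(additions),
    chamber_volume = chamber_volume,
    biomass_mg = biomass_mg,
    dt = dt,
    gain = gain,
    baseline = baseline,
    truth = truth,
    class = c("mims_trace", class(tibble::tibble()))
  )
}

#' @export
print.mims_trace <- function(x, ...) {
  adds <- attr(x, "additions")
  cat(sprintf(
    "<mims_trace> %d samples, dt = %g s, chamber %g L, biomass %g mg DW\n",
    nrow(x), attr(x, "dt"), attr(x, "chamber_volume"), attr(x, "biomass_mg")
  ))
  cat(sprintf(
    "  additions: %d analyte, %d calibration; gain: %s counts/nM\n",
    sum(adds$kind == "analyte"), sum(adds$kind == "calibration"),
    if (is.na(attr(x, "gain"))) "uncalibrated" else format(attr(x, "gain"))
  ))
  NextMethod()
}
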