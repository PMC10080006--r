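#' Calibrate a MIMS trace from its calibration additions
#'
#' Converts raw ion counts to dissolved concentration using the signal jumps
#' produced by injections of gas-saturated water. For each calibration
#' addition the expected concentration step is
#' `delta_S = volume_ml * solubility_nm / (1000 * chamber_volume)`; the
#' observed jump is estimated by short linear extrapolation of the samples on
#' either side of the addition to the addition time, which corrects for
#' ongoing consumption during the measurement windows. With one calibration
#' the gain is `jump / delta_S`; with several it is the least-squares slope
#' through the origin of the (delta_S, jump) pairs. The baseline is the
#' median signal before the first calibration addition.
#'
#' @param trace A `mims_trace` (see [simulate_mims_trace()] or
#'   [read_mims_trace()]).
#' @param solubility_nm Dissolved concentration of the saturated injection
#'   liquid (nM); used for calibration additions whose `conc_nm` is `NA`.
#' @param window Number of samples used on each side of an addition to
#'   estimate the jump.
#' @return The trace with attributes `gain` (counts/nM) and `baseline`
#'   (counts) set and a new column `conc_nm = (signal - baseline) / gain`.
#' @export
calibrate_signal <- function(trace, solubility_nm = 7.8e5, window = 5) {
  stopifnot(inherits(trace, "mims_trace"))
  adds <- attr(trace, "additions")
  cal <- adds[adds$kind == "calibration", , drop = FALSE]
  if (nrow(cal) == 0) {
    stop("trace has no calibration addition; cannot set the gain",
      call. = FALSE
    )
  }
  vol <- attr(trace, "chamber_volume")
  conc <- ifelse(is.na(cal$conc_nm), solubility_nm, cal$conc_nm)
  delta_s <- cal$volume_ml * conc / (1000 * vol)
  jumps <- vapply(
    seq_len(nrow(cal)),
    function(i) signal_jump(trace$time_s, trace$signal_counts, cal$time_s[i], window),
    numeric(1)
  )
  if (any(jumps <= 0)) {
    stop("non-positive signal jump at a calibration addition", call. = FALSE)
  }
  gain <- if (length(jumps) == 1L) {
    jumps / delta_s
  } else {
    sum(jumps * delta_s) / sum(delta_s^2) # through-origin least squares
  }
  pre <- trace$signal_counts[trace$time_s < min(cal$time_s)]
  baseline <- stats::median(pre)
  out <- trace
  out$conc_nm <- (out$signal_counts - baseline) / gain
  attr(out, "gain") <- gain
  attr(out, "baseline") <- baseline
  out
}

# Jump across an addition: linear fits over `window` samples on each side,
# both extrapolated to the addition time, so consumption within the windows
# does not bias the step estimate.
signal_jump <- function(time_s, signal, t_add, window = 5) {
  pre_idx <- which(time_s < t_add)
  post_idx <- which(time_s > t_add)
  if (length(pre_idx) < 2 || length(post_idx) < 2) {
    stop("too few samples around the addition at t = ", t_add, call. = FALSE)
  }
  pre_idx <- utils::tail(pre_idx, window)
  post_idx <- utils::head(post_idx, window)
  predict_at <- function(idx) {
    if (length(idx) == 2L || stats::var(time_s[idx]) == 0) {
      return(mean(signal[idx]))
    }
    fit <- stats::lm.fit(cbind(1, time_s[idx] - t_add), signal[idx])
    fit$coefficients[[1]]
  }
  predict_at(post_idx) - predict_at(pre_idx)
}

#' Segment a calibrated trace into substrate-depletion pulses
#'
#' Cuts the concentration series into one segment per analyte addition. A
#' segment starts at the first sample after the addition (the post-jump
#' sample) and ends at the next addition, at complete depletion (first sample
#' below `floor_nm`), or at the end of the trace, whichever comes first.
#'
#' @param trace A calibrated `mims_trace` (column `conc_nm` present).
#' @param floor_nm Depletion floor (nM) below which a pulse is considered
#'   fully consumed.
#' @return A tibble with one row per pulse: `pulse`, `t_start_s`, `t_end_s`,
#'   `n_points`, `s0_nm`, `depleted_fully`, and a list-column `data` holding
#'   the per-pulse tibble (`time_s`, `conc_nm`, clamped at zero).
#' @export
segment_pulses <- function(trace, floor_nm = 1) {
  stopifnot(inherits(trace, "mims_trace"))
  if (!"conc_nm" %in% names(trace)) {
    stop("trace is not calibrated; run calibrate_signal() first", call. = FALSE)
  }
  adds <- attr(trace, "additions")
  dt <- attr(trace, "dt")
  if (nrow(adds) > 1 && any(diff(adds$time_s) < 2 * dt)) {
    stop("additions closer than 2*dt cannot be segmented", call. = FALSE)
  }
  analyte <- adds[adds$kind == "analyte", , drop = FALSE]
  empty <- tibble::tibble(
    pulse = integer(), t_start_s = numeric(), t_end_s = numeric(),
    n_points = integer(), s0_nm = numeric(), depleted_fully = logical(),
    data = list()
  )
  if (nrow(analyte) == 0) {
    return(empty)
  }
  conc <- pmax(0, trace$conc_nm)
  purrr::map_dfr(seq_len(nrow(analyte)), function(k) {
    t_add <- analyte$time_s[k]
    later <- adds$time_s[adds$time_s > t_add]
    t_limit <- if (length(later)) min(later) else Inf
    idx <- which(trace$time_s > t_add & trace$time_s < t_limit)
    below <- idx[conc[idx] < floor_nm]
    depleted <- length(below) > 0
    if (depleted) idx <- idx[idx <= below[1L]]
    tibble::tibble(
      pulse = k,
      t_start_s = trace$time_s[idx[1L]],
      t_end_s = trace$time_s[idx[length(idx)]],
      n_points = length(idx),
      s0_nm = conc[idx[1L]],
      depleted_fully = depleted,
      data = list(tibble::tibble(
        time_s = trace$time_s[idx], conc_nm = conc[idx]
      ))
    )
  })
}

#' Fit Michaelis-Menten parameters to one depletion pulse
#'
#' Least-squares fit of the explicit depletion model
#' ([integrate_mm_depletion()]) to an observed concentration series, with the
#' initial concentration fixed at the first observed sample and both
#' `vmax_chamber` and `ks` free. The optimizer is deterministic: a coarse
#' log-spaced grid seeds a Nelder-Mead refinement on log-parameters with
#' fixed tolerances, so identical inputs always return identical estimates.
#'
#' @param segment A per-pulse tibble (`time_s`, `conc_nm`) as produced by
#'   [segment_pulses()], or a bare numeric concentration series at spacing
#'   `dt`.
#' @param dt Sampling step (s).
#' @param biomass_mg Dry weight of cells in the chamber (mg).
#' @param chamber_volume Chamber liquid volume (L); with `biomass_mg` it
#'   converts the fitted chamber rate (nM/min) to the specific rate
#'   (nM/min/mg DW).
#' @param min_depletion_frac Minimum fractional drop of the series below
#'   which the pulse is flagged non-converged (no measurable consumption).
#' @return A one-row tibble: `vmax_app` (nM/min/mg DW), `ks_app` (nM),
#'   `vmax_chamber` (nM/min), `s0_nm`, `sse`, `converged`, `message`.
#' @export
fit_pulse <- function(segment, dt = 1, biomass_mg, chamber_volume,
                      min_depletion_frac = 0.02) {
  conc <- if (is.data.frame(segment)) segment$conc_nm else as.numeric(segment)
  stopifnot(biomass_mg > 0, chamber_volume > 0, dt > 0)
  n <- length(conc)
  if (n < 10) stop("pulse has fewer than 10 points", call. = FALSE)
  s0 <- conc[1L]
  biomass_per_l <- biomass_mg / chamber_volume
  flagged <- function(msg) tibble::tibble(
    vmax_app = NA_real_, ks_app = NA_real_, vmax_chamber = NA_real_,
    s0_nm = s0, sse = NA_real_, converged = FALSE, message = msg
  )
  if (s0 <= 0) {
    return(flagged("non-positive starting concentration"))
  }
  drop_total <- s0 - min(conc)
  if (drop_total < min_depletion_frac * s0) {
    return(flagged("no measurable consumption"))
  }
  duration <- (n - 1L) * dt
  sse_of <- function(vmax, ks) {
    pred <- integrate_mm_depletion(s0, vmax, ks, dt, duration)
    sum((conc - pred)^2)
  }
  # crude initial-rate estimate over the first ~10 samples (nM/min)
  k0 <- min(n, 11L)
  v0 <- (s0 - conc[k0]) / ((k0 - 1L) * dt) * 60
  v0 <- max(v0, drop_total / (duration / 60) , 1e-6)
  vmax_grid <- exp(seq(log(v0 * 0.5), log(v0 * 20), length.out = 15))
  ks_grid <- exp(seq(log(max(s0 * 1e-3, 0.5)), log(s0 * 10), length.out = 15))
  grid <- expand.grid(vmax = vmax_grid, ks = ks_grid)
  grid_sse <- mapply(sse_of, grid$vmax, grid$ks)
  start <- grid[which.min(grid_sse), ]
  opt <- stats::optim(
    par = log(c(start$vmax, start$ks)),
    fn = function(p) sse_of(exp(p[1]), exp(p[2])),
    method = "Nelder-Mead",
    control = list(reltol = 1e-8, maxit = 500)
  )
  vmax_hat <- exp(opt$par[1])
  ks_hat <- exp(opt$par[2])
  tibble::tibble(
    vmax_app = vmax_hat / biomass_per_l,
    ks_app = ks_hat,
    vmax_chamber = vmax_hat,
    s0_nm = s0,
    sse = opt$value,
    converged = opt$convergence == 0 && vmax_hat > 0,
    message = if (opt$convergence == 0) "ok" else "optimizer did not converge"
  )
}

#' Two-phase progress-curve estimation of apparent Vmax and Ks
#'
#' Fits every analyte pulse of a calibrated trace independently with
#' [fit_pulse()], then aggregates the way repeated-pulse MIMS experiments are
#' analysed: the mean and sample standard deviation of the apparent Vmax over
#' the first `n_vmax_rounds` converged pulses (biomass not yet starved, high
#' starting substrate constrains Vmax) and of the apparent Ks over the last
#' `n_ks_rounds` converged pulses (depletion through the low-concentration
#' region constrains Ks).
#'
#' @param trace A calibrated `mims_trace`.
#' @param n_vmax_rounds,n_ks_rounds Number of early/late pulses aggregated.
#' @param floor_nm Depletion floor passed to [segment_pulses()].
#' @return A `kinetic_fit` object; see [tidy.kinetic_fit()] and
#'   [glance.kinetic_fit()].
#' @examples
#' \donttest{
#' tr <- simulate_mims_trace(mims_sim_params(seed = 7))
#' fit <- estimate_kinetics(calibrate_signal(tr))
#' fit
#' }
#' @export
estimate_kinetics <- function(trace, n_vmax_rounds = 4, n_ks_rounds = 4,
                              floor_nm = 1) {
  segs <- segment_pulses(trace, floor_nm = floor_nm)
  n_pulses <- nrow(segs)
  if (n_pulses < n_vmax_rounds + n_ks_rounds) {
    warning(
      "only ", n_pulses, " pulses for ", n_vmax_rounds, " + ", n_ks_rounds,
      " rounds; early and late sets overlap"
    )
  }
  dt <- attr(trace, "dt")
  biomass_mg <- attr(trace, "biomass_mg")
  chamber_volume <- attr(trace, "chamber_volume")
  rounds <- purrr::map_dfr(seq_len(n_pulses), function(k) {
    dplyr::bind_cols(
      tibble::tibble(pulse = segs$pulse[k]),
      fit_pulse(segs$data[[k]],
        dt = dt, biomass_mg = biomass_mg,
        chamber_volume = chamber_volume
      )
    ) |>
      dplyr::mutate(depleted_fully = segs$depleted_fully[k])
  })
  ok <- rounds[rounds$converged, , drop = FALSE]
  first_set <- utils::head(ok, n_vmax_rounds)
  last_set <- utils::tail(ok, n_ks_rounds)
  if (nrow(first_set) < 2 || nrow(last_set) < 2) {
    stop("fewer than 2 converged pulses in an aggregation set", call. = FALSE)
  }
  structure(
    list(
      rounds = rounds,
      vmax_app_mean = mean(first_set$vmax_app),
      vmax_app_sd = stats::sd(first_set$vmax_app),
      n_vmax = nrow(first_set),
      vmax_pulses = first_set$pulse,
      ks_app_mean = mean(last_set$ks_app),
      ks_app_sd = stats::sd(last_set$ks_app),
      n_ks = nrow(last_set),
      ks_pulses = last_set$pulse,
      dt = dt, biomass_mg = biomass_mg, chamber_volume = chamber_volume
    ),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("<kinetic_fit> progress-curve estimates from",
    nrow(x$rounds), "pulses\n"
  )
  cat(sprintf(
    "  Vmax(app): %.1f +/- %.1f nM/min/mg DW (n = %d, pulses %s)\n",
    x$vmax_app_mean, x$vmax_app_sd, x$n_vmax,
    paste(x$vmax_pulses, collapse = ",")
  ))
  cat(sprintf(
    "  Ks(app):   %.1f +/- %.1f nM (n = %d, pulses %s)\n",
    x$ks_app_mean, x$ks_app_sd, x$n_ks,
    paste(x$ks_pulses, collapse = ",")
  ))
  invisible(x)
}
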