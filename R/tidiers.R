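#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-pulse estimates of a kinetic fit
#'
#' @param x A `kinetic_fit` from [estimate_kinetics()].
#' @param ... Unused.
#' @return A tibble with one row per pulse: `pulse`, `vmax_app`, `ks_app`,
#'   `vmax_chamber`, `s0_nm`, `sse`, `converged`, `depleted_fully`, plus a
#'   `used_for` label saying which aggregate (if any) the pulse entered.
#' @export
tidy.kinetic_fit <- function(x, ...) {
  rounds <- x$rounds
  rounds$used_for <- dplyr::case_when(
    rounds$pulse %in% x$vmax_pulses & rounds$pulse %in% x$ks_pulses ~ "both",
    rounds$pulse %in% x$vmax_pulses ~ "vmax",
    rounds$pulse %in% x$ks_pulses ~ "ks",
    TRUE ~ "none"
  )
  rounds
}

#' One-row summary of a kinetic fit
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `vmax_app_mean`, `vmax_app_sd`, `n_vmax`,
#'   `ks_app_mean`, `ks_app_sd`, `n_ks`, `n_pulses`, `dt`.
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble::tibble(
    vmax_app_mean = x$vmax_app_mean, vmax_app_sd = x$vmax_app_sd,
    n_vmax = x$n_vmax,
    ks_app_mean = x$ks_app_mean, ks_app_sd = x$ks_app_sd, n_ks = x$n_ks,
    n_pulses = nrow(x$rounds), dt = x$dt
  )
}

#' Plot a MIMS trace with its addition events
#'
#' @param object A `mims_trace`.
#' @param ... Unused.
#' @return A ggplot: ion counts (or concentration, if calibrated) against
#'   time with additions marked.
#' @export
autoplot.mims_trace <- function(object, ...) {
  adds <- attr(object, "additions")
  calibrated <- "conc_nm" %in% names(object)
  y <- if (calibrated) "conc_nm" else "signal_counts"
  ggplot2::ggplot(
    object, ggplot2::aes(x = .data$time_s, y = .data[[y]])
  ) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(
      data = adds,
      ggplot2::aes(xintercept = .data$time_s, colour = .data$kind),
      linetype = "dashed", alpha = 0.6
    ) +
    ggplot2::labs(
      x = "time (s)",
      y = if (calibrated) "dissolved H2 (nM)" else "ion counts",
      colour = "addition"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-pulse kinetic estimates and the two-phase aggregates
#'
#' @param object A `kinetic_fit`.
#' @param ... Unused.
#' @return A ggplot of per-pulse apparent Vmax and Ks with the early-round
#'   Vmax mean and late-round Ks mean overlaid.
#' @export
autoplot.kinetic_fit <- function(object, ...) {
  long <- tidy(object) |>
    dplyr::filter(.data$converged) |>
    tidyr::pivot_longer(c("vmax_app", "ks_app"),
      names_to = "parameter", values_to = "estimate"
    )
  means <- tibble::tibble(
    parameter = c("vmax_app", "ks_app"),
    estimate = c(object$vmax_app_mean, object$ks_app_mean)
  )
  ggplot2::ggplot(
    long, ggplot2::aes(x = .data$pulse, y = .data$estimate)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(
      data = means, ggplot2::aes(yintercept = .data$estimate),
      linetype = "dotted"
    ) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "pulse", y = "estimate") +
    ggplot2::theme_minimal()
}

#' Plot a feature table in the m/z - retention time plane
#'
#' @param features A feature table with `mz`, `rt` and, if available,
#'   `max_intensity` and artifact flags.
#' @return A ggplot with point size following intensity and colour following
#'   the artifact flags when present.
#' @export
plot_feature_map <- function(features) {
  features <- tibble::as_tibble(features)
  has_flags <- all(c("flag_isotope", "flag_fragment") %in% names(features))
  if (has_flags) {
    features$status <- dplyr::case_when(
      features$flag_isotope ~ "isotope",
      features$flag_fragment ~ "fragment",
      TRUE ~ "feature"
    )
  }
  p <- ggplot2::ggplot(
    features, ggplot2::aes(x = .data$rt, y = .data$mz)
  ) +
    ggplot2::labs(x = "retention time (s)", y = "m/z (Th)") +
    ggplot2::theme_minimal()
  if (has_flags) {
    p + ggplot2::geom_point(
      ggplot2::aes(size = log10(.data$max_intensity), colour = .data$status),
      alpha = 0.7
    )
  } else {
    p + ggplot2::geom_point(
      ggplot2::aes(size = log10(.data$max_intensity)),
      alpha = 0.7
    )
  }
}
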