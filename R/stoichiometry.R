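#' Steady-state gas consumption rates from in/out flows
#'
#' For every species measured in the feed, the net consumption rate is
#' `q = (flow_in * x_in - flow_out * x_out) * 60 / (1000 * molar_volume)`
#' in mol/h, converting volumetric flows (mL/min) at a single reference
#' condition. Net production (negative q) is reported with a warning rather
#' than an error, since closure checks on producing species are informative.
#'
#' @param record A `chemostat_record` (see [simulate_chemostat()] or
#'   [read_chemostat_record()]).
#' @return A tibble with columns `species` and `q_mol_h`.
#' @examples
#' rates <- steady_state_rates(simulate_chemostat(chemostat_sim_params()))
#' rates
#' @export
steady_state_rates <- function(record) {
  stopifnot(inherits(record, "chemostat_record"))
  gin <- tibble::as_tibble(record$gas_in)
  gout <- tibble::as_tibble(record$gas_out)
  missing <- setdiff(gin$species, gout$species)
  if (length(missing)) {
    stop(
      "no outflow measurement for species: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  joined <- dplyr::inner_join(gin, gout,
    by = "species", suffix = c("_in", "_out")
  )
  q <- (joined$flow_ml_min_in * joined$fraction_in -
    joined$flow_ml_min_out * joined$fraction_out) *
    60 / (1000 * record$molar_volume)
  if (any(q < 0)) {
    warning(
      "net production (negative q) for: ",
      paste(joined$species[q < 0], collapse = ", ")
    )
  }
  tibble::tibble(species = joined$species, q_mol_h = q)
}

#' Biomass yield on H2
#'
#' At steady state the biomass production rate is `dw * D * V` (g DW/h),
#' so the yield on H2 is `dw * D * V / q_h2` in g DW per mol H2.
#'
#' @param q_h2 H2 consumption rate (mol/h).
#' @param dw Culture dry weight (g/L).
#' @param dilution_rate Dilution rate D (1/h).
#' @param volume Working volume (L).
#' @return Yield in g DW per mol H2.
#' @export
biomass_yield <- function(q_h2, dw, dilution_rate, volume) {
  if (!is.finite(q_h2) || q_h2 <= 0) {
    stop("`q_h2` must be positive to compute a yield", call. = FALSE)
  }
  stopifnot(dw >= 0, dilution_rate > 0, volume > 0)
  dw * dilution_rate * volume / q_h2
}

#' Partition of fixed CO2 carbon into excreted and assimilated fractions
#'
#' The excreted fraction is the rate of organic-carbon excretion (supernatant
#' TOC times the liquid outflow, mol C/h) divided by the CO2 fixation rate;
#' the assimilated fraction is its complement, so the two always sum to 1
#' exactly. Fractions above 1 (balance not closing) are reported as-is with a
#' warning rather than clamped, since the degree of closure is informative.
#'
#' @param q_co2 CO2 fixation rate (mol/h).
#' @param toc_excretion_rate Organic carbon excretion rate (mol C/h),
#'   typically `toc_mm / 1000 * D * V`.
#' @return A named numeric vector `c(excreted_fraction, assimilated_fraction)`.
#' @examples
#' carbon_partition(1, 0.54)
#' @export
carbon_partition <- function(q_co2, toc_excretion_rate) {
  if (!is.finite(q_co2) || q_co2 <= 0) {
    stop("`q_co2` must be positive to partition fixed carbon", call. = FALSE)
  }
  if (toc_excretion_rate < 0) {
    stop("`toc_excretion_rate` must be non-negative", call. = FALSE)
  }
  excreted <- toc_excretion_rate / q_co2
  if (excreted > 1) {
    warning(sprintf(
      "excreted fraction %.3g exceeds 1: carbon balance does not close",
      excreted
    ))
  }
  c(excreted_fraction = excreted, assimilated_fraction = 1 - excreted)
}

#' Molar N:C ratio of dissolved organics
#'
#' @param tn Total nitrogen of the supernatant (mM N).
#' @param toc Total organic carbon of the supernatant (mM C).
#' @return `tn / toc` (mol N per mol C).
#' @export
nc_ratio <- function(tn, toc) {
  if (!is.finite(toc) || toc <= 0) {
    stop("`toc` must be positive", call. = FALSE)
  }
  if (tn < 0) stop("`tn` must be non-negative", call. = FALSE)
  tn / toc
}

#' Full stoichiometric summary of a chemostat record
#'
#' Chains [steady_state_rates()], [biomass_yield()], [carbon_partition()] and
#' [nc_ratio()] into the standard steady-state summary: consumption rates,
#' biomass yield on H2, CO2 fixed per H2, the excreted/assimilated carbon
#' partition, the N:C ratio of the excreted organics, and the growth rate
#' (equal to D) with its doubling time.
#'
#' @param record A `chemostat_record`.
#' @return A one-row tibble with columns `q_h2_mol_h`, `q_co2_mol_h`,
#'   `yield_dw_g_mol`, `co2_per_h2`, `excreted_fraction`,
#'   `assimilated_fraction`, `nc_ratio`, `growth_rate_h`,
#'   `doubling_time_h`.
#' @examples
#' stoichiometry_summary(simulate_chemostat(chemostat_sim_params()))
#' @export
stoichiometry_summary <- function(record) {
  stopifnot(inherits(record, "chemostat_record"))
  q <- steady_state_rates(record)
  q_h2 <- q$q_mol_h[q$species == "H2"]
  q_co2 <- q$q_mol_h[q$species == "CO2"]
  if (!length(q_h2) || !length(q_co2)) {
    stop("record must measure both H2 and CO2", call. = FALSE)
  }
  flow_l_h <- record$dilution_rate * record$volume
  toc_rate <- record$toc_mm / 1000 * flow_l_h
  part <- carbon_partition(q_co2, toc_rate)
  tibble::tibble(
    q_h2_mol_h = q_h2,
    q_co2_mol_h = q_co2,
    yield_dw_g_mol = biomass_yield(
      q_h2, record$dw_g_l, record$dilution_rate, record$volume
    ),
    co2_per_h2 = q_co2 / q_h2,
    excreted_fraction = part[["excreted_fraction"]],
    assimilated_fraction = part[["assimilated_fraction"]],
    nc_ratio = nc_ratio(record$tn_mm, record$toc_mm),
    growth_rate_h = record$dilution_rate,
    doubling_time_h = doubling_time(record$dilution_rate)
  )
}
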