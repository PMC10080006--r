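---
title: "Methods: progress-curve kinetics, chemostat balances and exometabolome accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: progress-curve kinetics, chemostat balances and exometabolome accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knallgas)
```

This vignette is the package's own account of the science it implements:
the models, the tunable parameters and their defaults, the numerical
choices, what the synthetic generators do and do not emulate, and the known
limitations. The package targets the quantitative physiology of aerobic
H2-oxidizing chemolithoautotrophs ("Knallgas" bacteria): whole-cell H2
uptake kinetics measured by membrane-inlet mass spectrometry (MIMS),
steady-state carbon/nitrogen balances of chemostat cultures, and accounting
of the organic carbon such organisms can excrete into their supernatant.

## Whole-cell kinetics from MIMS depletion curves

A stirred chamber holds a known liquid volume and a known dry weight of
cells. Dissolved H2 is read continuously through a gas-permeable membrane
coupled to a mass spectrometer operating in pulsed ion counting, so the raw
observable is an ion-count rate proportional to the dissolved concentration.
Injecting a bolus of H2-saturated water raises the concentration
near-instantaneously; the cells then draw it down. The depletion follows
whole-cell Michaelis-Menten kinetics,

$$\frac{dS}{dt} = -\,\frac{V_\max\, S}{K_s + S},$$

with $V_\max$ the chamber-volumetric maximal rate (nM/min) and $K_s$ the
apparent half-saturation constant (nM). Rather than relying on the implicit
analytical solution, the package re-simulates the curve on the sampling grid
with an explicit 1-s update — each second carries its own rate — and clamps
at zero on complete depletion (`integrate_mm_depletion()`). At 1-s
resolution this discretization stays within 0.5% of the pulse size of the
continuous solution across the realistic parameter range (the test suite
checks it against a bisection solution of
$K_s \ln(S_0/S) + (S_0 - S) = V_\max t$). Agreement is measured relative to
the initial concentration $S_0$, not pointwise: the continuous solution
approaches zero only asymptotically while the discrete series is clamped, so
a pointwise relative error degenerates in the depleted tail without saying
anything useful about the fit.

The analysis chain is:

1. **Calibration** (`calibrate_signal()`). Injecting `v` mL of saturated
   water (solubility $c_{sat}$, default 780 µM for H2 near 25 °C and 1 atm;
   the constant is a configurable argument, not a hard-wired value) into a
   chamber of `V` L steps the concentration by $\Delta S = v\,c_{sat}/(1000 V)$.
   The observed count jump divided by $\Delta S$ is the detector gain;
   several calibration additions are pooled by a least-squares slope through
   the origin. Because cells keep consuming during the calibration windows,
   the jump is estimated by short linear extrapolation of five samples on
   each side of the addition back to the addition time; with active biomass
   this removes a bias of order 1–2% that a naive before/after difference
   would carry. The baseline is the median signal before the first
   calibration addition.

2. **Segmentation** (`segment_pulses()`). One segment per analyte addition,
   from the first post-jump sample (the tie-break at the boundary) to the
   next addition or to the first sample below a 1 nM floor. The floor
   matters only for bookkeeping — a fully depleted tail at the noise floor
   carries no kinetic information.

3. **Per-pulse fitting** (`fit_pulse()`). Both parameters free, $S_0$ fixed
   at the first observed sample of the segment, least squares between the
   observed concentration series and the re-simulated curve. The objective
   is the concentration-domain sum of squares, the natural counterpart of
   overlaying a fitted curve on the raw trace. The optimizer is
   deliberately deterministic: a 15 × 15 log-spaced grid around a crude
   initial-rate estimate seeds a Nelder-Mead refinement on log-parameters
   with fixed tolerance (relative SSE 1e-8) and iteration cap, so identical
   inputs always give identical estimates, and the test suite verifies the
   result is at least as good as an exhaustive 200 × 200 log-grid search.
   A segment with less than 2% total depletion is flagged non-converged and
   excluded from aggregation rather than fitted.

4. **Two-phase aggregation** (`estimate_kinetics()`). Repeated-pulse
   experiments determine the two parameters in different regimes: early
   pulses, with fresh biomass and high $S_0$, pin $V_\max$ (the initial,
   near-linear part of each depletion is at saturation); late pulses, after
   the biomass has repeatedly run out of substrate, are the ones whose
   low-concentration tails constrain $K_s$ — and a starvation-induced drop
   in $V_\max$ does not move $K_s$. The package therefore reports the mean
   ± sample SD of $V_\max$ over the first four converged pulses and of
   $K_s$ over the last four, with `n` attached to each. Each pulse is
   fitted with both parameters free rather than sharing $K_s$ across
   rounds, because the two aggregates are reported as independent n = 4
   means with their own SDs. Specific rates divide the chamber rate by the
   biomass density (mg DW per litre of chamber liquid), giving
   nM min⁻¹ (mg DW)⁻¹.

Fitting saturating pulses ($S_0 \gg K_s$) constrains $V_\max$ tightly while
leaving $K_s$ ill-determined — the SSE surface is nearly flat along $K_s$ —
which is why a $V_\max$ protocol keeps some residual substrate and a $K_s$
protocol needs depletion through the low-concentration region. A dedicated
test documents this asymmetry.

### What the MIMS generator emulates

`simulate_mims_trace()` produces ground-truth-tagged traces: Michaelis-
Menten depletion between additions, instantaneous concentration jumps at
additions, a detector with gain, constant-plus-drift baseline, and Poisson
counting noise (the natural model for pulsed ion counting; Gaussian noise is
available for convenience). Starvation is modelled as a single
multiplicative factor on $V_\max$ from a stated onset time — the simplest
mechanism consistent with a reduced $V_\max$ at unchanged $K_s$. The
defaults are the study conditions the package is anchored to: a 0.5-L
chamber, 0.5 mg DW of cells, $V_\max$ = 953 nM/min/mg DW, $K_s$ = 353 nM,
one calibration addition and eight analyte pulses of ~1.56 µM each, 1-s
sampling. The generator does **not** emulate membrane transport lag, O2
co-consumption, temperature drift or saturation of the detector; passing
recovery tests on synthetic traces therefore demonstrates the correctness of
the estimation machinery, not robustness to every instrument artifact.

## Chemostat stoichiometry

At steady state in a chemostat the specific growth rate equals the dilution
rate $D$, and every balance reduces to algebra on measured flows:

- gas consumption $q = (F_{in} x_{in} - F_{out} x_{out}) \cdot 60 / (1000\,V_m)$
  mol/h, with $V_m$ the gas molar volume at a single configurable reference
  condition (default 24.45 L/mol, 25 °C and 1 atm) applied to both streams;
- biomass yield on H2 $Y = \mathrm{DW} \cdot D \cdot V / q_{H_2}$ (standard
  chemostat assumption: no wall growth, no sampling losses);
- carbon partition: excreted fraction $= (\mathrm{TOC} \cdot D \cdot V) / q_{CO_2}$,
  assimilated fraction its complement — the two sum to exactly 1 by
  construction, and a fraction above 1 is reported with a warning instead of
  clamped, because the degree of closure is itself informative;
- N:C of the excreted organics = supernatant TN / TOC (molar).

Note the partition needs no elemental composition of biomass: "assimilated"
is defined as the non-excreted complement.

`simulate_chemostat()` builds self-consistent records from the same algebra
run forwards. Its defaults are the study conditions: V = 0.35 L, D =
0.034 h⁻¹, feed 3 mL/min pure H2 plus 10 mL/min 5% CO2 in argon, yield
1.4 g DW/mol H2, 0.12 mol CO2 fixed per mol H2, 0.54 of fixed carbon
excreted, N:C 0.4. Two deliberate choices:

- **The absolute H2 consumption is underdetermined** by the yield-type
  parameters, so the generator pins it with `h2_consumed_fraction` (default
  0.85 of the supplied H2) — a typical utilization for a gas-limited
  culture. Every downstream summary is a ratio and does not depend on this
  choice; only the absolute $q$ values do.
- **Two dilution rates appear in this literature for the same kind of
  culture** (0.034 h⁻¹ in cultivation methods, 0.043 h⁻¹ in a results
  narrative). $D$ is an input everywhere in this package; the default is
  0.034 h⁻¹ and nothing downstream attempts to reconcile the two.

Measurement noise is multiplicative, truncated-Gaussian with a configurable
CV on each observable (outflow fractions, DW, TOC, TN); the feed set-points
are treated as exact. No reported noise magnitudes exist for these
instruments in the anchoring study; the 5% default is a conventional figure
for gas analysis and dry-weight work, stated here as a choice rather than
inferred.

A further tension the package surfaces without resolving: the bulk TN/TOC
ratio of the supernatant (0.4) is almost twice the elemental N:C (~0.21) of
the individually quantified compounds. Both numbers are computed by the
package from their own inputs (`nc_ratio()` versus `carbon_total()`), and
neither is "corrected" toward the other; the discrepancy is real information
about unidentified nitrogen-rich solutes or calibration bias.

## Exometabolome accounting

The module starts from an XCMS-style feature table (m/z, retention time,
per-sample intensities); peak detection and retention-time alignment are
upstream, published-tool territory and out of scope.

- **Abundance filter** (`filter_features()`): fold change > 5 between
  supernatant and blank medium, Welch t-test p < 0.05 on log10 intensities,
  and maximum intensity > 1e6 — all strict inequalities, read literally
  from the conventional "> 5, < 0.05, > 10^6" phrasing; a feature exactly
  on a threshold is removed. Welch's unequal-variance test on logs is the
  default behaviour of the online XCMS-style comparison this emulates. The
  filter preserves order and is idempotent.
- **Artifact flagging** (`flag_isotopes_and_fragments()`): a feature is an
  isotope satellite if a co-eluting (default |Δrt| ≤ 5 s), more intense
  feature sits 1.00336 Th below it (10 ppm tolerance); an in-source
  fragment if a co-eluting, higher-m/z, more intense feature exists whose
  per-sample intensity pattern correlates with it (Pearson r > 0.9). In the
  original workflow this curation was manual; the automated surrogate's
  tolerances are package choices, sized to chromatographic peak widths and
  Q-ToF mass accuracy. Flags are annotations; removal is an explicit,
  separate step, and the most intense member of a co-eluting group can
  never be flagged.
- **Annotation** (`match_mass()`): accurate-mass lookup against a local
  compound registry (20 proteinogenic amino acids plus homoserine,
  homoserine lactone and 2-aminobutyric acid), with M+H, M+Na and M−H
  adducts and a ppm tolerance. Registry masses are recomputed from
  monoisotopic atomic masses at load so formula and mass can never drift
  apart. Equal-formula compounds (Ile/Leu, Thr/Hse) are all returned —
  accurate mass cannot separate them.
- **Quantification** (`quantify_from_calibration()`): ordinary
  least-squares calibration line with intercept, inverse prediction,
  explicit dilution factor (e.g. 30× for diluted reactor supernatant), a
  warning outside twice the calibration range.
- **Carbon closure** (`carbon_total()`, `toc_coverage()`): concentrations ×
  element counts, summed to mM C and mM N, compared to bulk TOC as a
  percentage. With the packaged supernatant table the compounds carry
  6.58 mM C. The "Unknown 3" entry is registered as 2-aminobutyric acid
  (homoalanine, C4H9NO2, 4 C / 1 N): NMR shows an amino-acid backbone with
  an ethyl side chain, and a 4-carbon assignment is required for the
  compound sum to close against TOC the way it does. The bulk TOC value
  itself is not a published number; the pipeline's default
  (`toc_measured_mm = 5.485`) is a synthetic stand-in sized so that the
  packaged table closes at ~120%, the closure the method is known to
  produce — only the ratio, not the TOC, is meaningful.

The feature generator (`simulate_feature_table()`) plants each class with
its defining property: true signals pass all three filter thresholds,
blank-only and low-intensity features fail by construction, satellites and
fragments co-elute with their parent at the right mass offsets and scaled,
correlated intensities. True signals are placed on a 25-s retention-time
grid so distinct compounds never co-elute by chance — real tables do
contain chance co-elutions, which is precisely why the original curation
was manual; the generator trades that realism for an unambiguous ground
truth. Default counts follow the canonical bookkeeping: 7 true signals
(one irreproducible), 3 satellites, 2 fragments, 20 blank-only, 15
low-intensity → 12 pass, 5 flagged, 7 remain, 6 reproducible.

## Growth-rate arithmetic

`doubling_time(rate)` is `ln 2 / rate`: 0.034 h⁻¹ → 20.4 h (the "20 h"
figure), 0.14 h⁻¹ → 5.0 h.

## Pipeline, reproducibility and problem sizes

`run_pipeline()` chains the three stages with a validated configuration
(unknown keys are rejected; every parameter has a documented default) and
emits a JSON + Markdown report carrying seed, package version, input hashes
and the full configuration; identical configurations give byte-identical
report bodies. `make_fixtures()` writes every input as plain-text CSV/TSV/
JSON with a ground-truth sidecar and a seed-stamped manifest. All
randomness flows through explicit integer seeds via `withr::with_seed()`,
so every generator is bitwise reproducible.

The recovery studies shipped with the package use 20 replicate 8-pulse MIMS
traces and 50 noisy chemostat records (100 in the property tests) — sizes
chosen so the Monte-Carlo error on the recovered means and medians sits
well below the 5% recovery criterion while a full run stays interactive on
a laptop.

## Known limitations

- The MIMS fit fixes $S_0$ at the first observed sample rather than
  treating it as a third free parameter; with 1-s sampling and the noise
  levels of pulsed ion counting the difference is negligible, but very
  noisy first samples would propagate.
- Forward-Euler at 1 s is part of the method definition here, not merely a
  solver choice; refitting data simulated with a different integrator will
  show a (small) systematic offset.
- The chemostat balances assume a single gas reference condition for both
  streams and ignore water vapour and pressure corrections.
- Artifact flagging uses one isotope spacing and one correlation threshold;
  charge states > 1, adduct networks and multimers are not modelled.
- Absolute specific rates from real traces require the chamber dry weight;
  when only an OD is known, the DW-per-OD conversion must be supplied by
  the user.
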