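---
title: "Detecting N2 fixation from headspace pressure in closed-batch gas fermentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting N2 fixation from headspace pressure in closed-batch gas fermentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thpn2fix)
```

## The measurement problem

Hydrogenotrophic, autotrophic methanogens grown in sealed, pressurised
serum bottles convert their headspace according to

    4 H2 + CO2 -> CH4 + 2 H2O

Water condenses, so every reaction turnover removes four gas moles and
the pressure falls. If the organism is also a diazotroph, nitrogenase
additionally runs, net of its H2 by-product,

    N2 + 3 H2 -> 2 NH3 (dissolved)

which again removes four gas moles per N2 fixed. Combining the two
yields the ideal diazotrophic feed, seven parts H2 to one part each of
CO2 and N2:

    7 H2 + CO2 + N2 -> CH4 + 2 H2O + 2 NH3

The key observation is stoichiometric, not kinetic: with a 7:1:1 feed
at pressure `p0`, methanogenesis alone can at best consume all CO2,
leaving one part CH4, three parts H2 and one part N2 — five ninths of
the initial moles. At `p0 = 3` bar absolute that floor is exactly
`5/3` bar. Any measured pressure below this *theoretical threshold*
(THp_N2fix) is unreachable without nitrogenase turnover and therefore
proves biological N2 fixation; the deficit below the threshold, divided
by four and converted through the ideal gas law, quantifies the moles
of N2 fixed without any gas chromatography:

```{r threshold}
mix <- gas_mixture(c(H2 = 7, CO2 = 1, N2 = 1))
thp <- thp_n2fix(mix, p0_abs = 3)
thp
n2_fixed_from_pressure(1.47, thp, vessel_state(117, 50))
```

## Assumptions behind the threshold

* **Ideal gas, isothermal, isochoric.** Bottles are cooled to a common
  measurement temperature before reading the manometer, so the residual
  pressure is proportional to residual moles. No fugacity or
  solubility corrections are applied; at a few bar and these species
  the error is far below manometer resolution.
* **Water stays liquid, ammonia stays dissolved.** Neither contributes
  partial pressure; this is what makes the four-gas-moles-per-turnover
  bookkeeping exact.
* **No liquid-phase carbon source.** Carbonate in the medium would feed
  extra methanogenesis beyond the 4:1 gas ratio and invalidate the
  threshold; the method presumes carbonate-free medium.
* **Exact rational arithmetic.** Reaction extents and residual
  fractions are carried as exact rationals (`rational()`), so
  thresholds like 5/3 bar are bit-exact and acceptance checks need no
  tolerance. Floating point enters only at the pressure/temperature
  boundary.
* **Reaction order.** `full_conversion_residual()` advances reactions
  in list order to their limiting reagent. For the 7:1:1 feed the
  combined result is order-independent because H2 exceeds the
  methanogenesis demand; the test-suite verifies agreement with a
  brute-force advancement oracle under both orderings on randomised
  mixtures.

## From pressure series to rates

The analysis pipeline (`analyze_observations()`) follows the closed-
batch workflow:

1. **Zero-control baseline.** An uninoculated bottle, gassed on the
   same manifold, reports the *real* starting pressure of each gassing
   round (removing the needle loses a little gas). Its readings anchor
   the fill pressures, the per-round threshold, and the N2 baseline
   against which fixation deltas are taken.
2. **Headspace volume tracking.** Each liquid sampling (0.75 mL by
   default) enlarges the headspace by exactly the withdrawn volume;
   `apply_withdrawal()` and the reader's cumulative bookkeeping keep
   the ideal-gas conversion honest across sampling events.
3. **Speciation.** Total moles come from `p V / R T`; per-species
   amounts multiply by the normalised GC composition
   (`normalize_gc()`), or by the exact feed fraction of N2 (default
   0.11392, the certified composition of the 7:1:1 mixture) before the
   first GC reading. The two are never multiplied together.
4. **Interval rates.** NUR, HUR, CUR (consumption, non-positive) and
   MER (evolution, non-negative) are mole deltas over
   `liquid volume x interval length`, in mmol L^-1 h^-1; qN2 divides
   |NUR| by the interval-end biomass (OD578 times a strain-specific
   coefficient). Negative NUR indicates N2 fixation.
5. **Balances.** Y(CH4/CO2) = MER/|CUR|, Y(x/CO2) = rx/|CUR| with
   rx = delta-x/delta-t times the biomass carbon content, and the
   carbon balance is their sum. HUR:CUR is 4 for pure methanogenesis.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `temperature_measurement_k` | 298.15 | K | readings at room temperature; the exact room value is configurable |
| `atmospheric_bar` | 1.000 | bar | so 2 bar relative is exactly 3 bar absolute; 1.013 available |
| `bottle/liquid volume` | 117 / 50 | mL | standard serum-bottle geometry; per-bottle override via the observation table |
| `initial_n2_fraction` | 0.11392 | – | certified N2 content of the 7:1:1 gas; set to 1/9 for nominal mixtures |
| `od_coefficient` | (required) | g L^-1 per OD | experimentally determined per strain and instrument; no universal value exists |
| `carbon_content_cmmol_g` | 37.7 | C-mmol g^-1 | standard biomass composition CH1.8O0.5N0.2 (26.5 g C-mol^-1) |
| `r2_min` | 0.999 | – | calibration quality gate; failing curves are an error, never a warning |
| `undercut_margin_bar` | 0.02 | bar | fixation is flagged at `p < THp - margin`; about four standard deviations of typical manometer noise, so a non-fixing culture sitting exactly on the methanogenesis floor is not flagged by chance across the many looks of a full experiment |

The per-N2 gas-mole removal factor (4) is exported as
`N2FIX_GAS_MOLES_PER_N2` for sensitivity analysis.

## What the simulator emulates — and what it does not

`simulate_closed_batch()` exists so that every pipeline operation can
be validated against known ground truth. It reproduces the design of
the target experiments: 117 mL bottles, 50 mL liquid, 7:1:1 feed at
3 bar absolute, cultivation at 338.15 K with pressures read at
298.15 K, 0.75 mL withdrawals at roughly 40/59/77 h, re-gassing after
the first two sampling rounds, NH4+ dosed as a percentage of
40 mmol L^-1, and Gaussian measurement noise on pressure, OD and NH4+
with Dirichlet jitter on GC compositions. A systematic 0.02 bar
gassing loss makes the zero-control machinery do real work.

The growth model is deliberately minimal: Monod kinetics on headspace
H2 and CO2 amounts (gas-liquid transfer is assumed non-limiting, which
keeps parameters identifiable), biomass yield per mol CH4, and a dual
nitrogen supply. NH4+ is the preferred source; while it is available a
configurable share of assimilatory nitrogen demand can come from
fixation, scaled down above an NH4+ switch-off concentration. Once
NH4+ is exhausted, fixation carries growth at a reduced rate.
Nitrogenase only becomes available after a minimal amount of NH4+ has
been assimilated, which reproduces the observation that wholly
NH4+-free cultures do not grow at all.

Two choices deserve emphasis:

* **Uncoupled fixation.** Specific N2 uptake rates measured by the
  threshold method exceed the nitrogen demand of biomass formation by
  an order of magnitude, and published carbon balances are
  correspondingly inconsistent where NUR is high. A purely
  growth-coupled model therefore cannot produce detectable pressure
  undercuts. The simulator includes a nitrogenase activity term
  (`q_n2_mmol_g_h`, default 3 mmol N2 g^-1 h^-1, within the measured
  qN2 range) that runs whenever the enzyme is active, with the fixed
  nitrogen excreted as dissolved reduced N; a small fraction
  (`aa_from_fixation_fraction`) appears as the measured amino-acid
  panel, dominated by Glu, Ala, Gly and Asn. The excreted-N pool is
  tracked so elemental nitrogen is conserved to machine precision.
* **Deterministic dynamics.** Replicate bottles share one true
  trajectory per configuration and differ only in measurement noise.
  Passing recovery tests therefore demonstrates correctness of the
  accounting, not robustness to biological replicate variability,
  media batch effects, leaky stoppers, or GC drift — none of which the
  simulator models. Kinetic defaults (mu_max 0.1 h^-1, yield 2 g per
  mol CH4, OD coefficient 0.3 g L^-1 per OD) are illustrative, chosen
  to land growth in the observed OD 0.2–0.7 window over ~120 h; they
  are not fitted strain constants.

## Numerical choices

* Euler stepping at `dt = 0.1 h` with adaptive halving (down to
  dt/1024, then a proportional clamp) whenever a pool would be
  overdrawn; the regimes here are not stiff.
* Pool exhaustion is asymptotic under the clamp; availability tests
  use a 1e-9 threshold rather than exact zero.
* GC jitter draws from a Dirichlet with concentration chosen so the
  mid-fraction standard deviation equals `gc_sd`, then renormalises;
  zero channels stay zero.
* Ties in the limiting-reagent search (e.g. an exactly 4:1 feed) are
  broken toward the first consumed species in the reaction's
  coefficient order; the residual is unaffected.
* Degenerate inputs: mixtures lacking every reactant of a reaction
  yield zero extent and the unchanged pressure rather than an error;
  an all-zero GC reading, a withdrawal at least as large as the liquid
  volume, and a threshold request without N2 in the feed are errors.

## Validation strategy and problem sizes

The test-suite validates, at sizes chosen to keep the default run in a
few minutes on one CPU:

* exact threshold anchors (5/3 bar for 7:1:1 at 3 bar; 0.6 bar for
  4:1) and the 1:3:1 residual, as exact rational identities;
* agreement of `full_conversion_residual()` with an independent
  brute-force advancement oracle on over 1000 randomised mixtures and
  reaction orderings;
* noise-free rate recovery from simulated bottles to within 0.5%
  relative, and recovery under default noise at the 40/59/77 h cadence
  to within 15% on replicate means;
* detection specificity and sensitivity over 100 seeded runs each:
  nitrogenase-off, NH4+-replete runs never flag fixation, and
  nitrogenase-on, NH4+-limited runs always do;
* elemental N and C conservation within 1e-6 relative on every
  simulated trajectory, including withdrawals and re-gassing;
* calibration round-trip identity on the 100–1000 umol L^-1 standard
  range and rejection of fits below R^2 = 0.999.

## Known limitations

* The threshold is only as sharp as the gassing pressure is known;
  the zero control is essential, and a leaky bottle mimics fixation.
  The margin guards against noise, not against leaks.
* Between the gassing and the first GC reading the N2 amount rests on
  the certified feed fraction; a mis-specified `initial_n2_fraction`
  biases NUR for fill-start intervals.
* Y(x/CO2) and rx use a generic biomass composition; strain-specific
  elemental analysis would sharpen the carbon balance.
* The pressure-only NUR (`nur_thp`) is a lower bound averaged since
  the last fill: it only counts turnovers after complete H2/CO2
  conversion is already implied by the threshold.
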