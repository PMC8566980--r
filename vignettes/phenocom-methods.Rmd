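---
title: "Methods: sensor processing, the significant-area statistic, and colonization profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensor processing, the significant-area statistic, and colonization profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenocom)
library(dplyr)
```

phenocom analyses greenhouse trials in which maize hybrids, inoculated or
not with a synthetic bacterial community (SynCom), grow under contrasting
irrigation regimes while every plant carries its own sensors. This
vignette documents the models and conventions behind each stage, the
tunable parameters, what the synthetic-data generator does and does not
emulate, and the numerical choices a reader would otherwise have to
reverse-engineer from the code.

## Environmental derivation and binning

Stations log air temperature (°C), relative humidity (%) and illuminance
(lux). Two derived channels are added per record:

* **PAR** (µmol m⁻² s⁻¹) = 0.0185 × lux, the fixed greenhouse correction
  for the light sensors used in this class of platform.
* **VPD** (kPa) from the Arden–Buck saturation-pressure form,
  `(1 − RH/100) · 0.61121 · exp(17.502 T / (240.97 + T))`. VPD is zero
  exactly at saturation, strictly decreasing in RH, strictly increasing
  in temperature below saturation; these monotonicity properties are
  enforced by tests.

Downstream statistics work on clock-aligned bins (default 30 min,
half-open `[start, start + width)`, starting at 00:00; the width must
divide 24 h). Within each bin the raw points of **all stations are
pooled first, then outliers are removed, then the mean is taken**. The
logging protocol states both pooling and outlier removal without fixing
their order; filtering the pooled points was chosen because it lets a
single faulty station reading be identified against the other stations'
points in the same half hour. The outlier rule is Tukey's IQR fence with
the conventional multiplier k = 1.5 and type-7 (linear-interpolation)
quartiles — both fixed and documented so test expectations are exact.
Bins whose points are all removed, or with no data (sensor outages are a
fact of such platforms), propagate as missing bins, never as zeros, and
no imputation is attempted.

## The leaf-temperature contrast and its signed significant area

Plant streams aggregate in two steps: within a bin each plant contributes
the mean of its raw 5-min points, then the Tukey filter runs across the
biological replicates of a treatment cell, and the retained replicate
values are kept alongside their mean — the per-bin test needs them.

For two arms (inoculated vs uninoculated) the per-bin contrast is
ΔT_leaf = mean(inoculated) − mean(uninoculated) with a two-sample test
per bin at level α (default 0.05). Two engines are exposed because the
underlying protocol names only a significance level, not a test:

* **Welch's t** (default). With the usual four replicates per arm an
  exact rank test is very coarse — its smallest achievable two-sided
  p-value is 0.0286 — so a location test on means is the practical
  default at this sample size.
* **Mann–Whitney** via `test = "mannwhitney"` for sensitivity analysis.

No multiple-testing correction is applied across bins, matching the
per-bin convention of the protocol; a Benjamini–Hochberg option exists
(`adjust = "BH"`) for sensitivity analysis. Bins with fewer than two
retained replicates in either arm are *untestable*: their p-value is
missing and they can never be significant, but they still count in the
bin denominator, which therefore stays purely temporal (a 20-day window
at 30 min is always 960 bins).

The **signed significant-area statistic** summarises a contrast window in
"arbitrary area units" (aau): 1 aau = 1 °C persisting for one 30-min bin.
Rectangle integration runs over significant bins only, with no contiguity
requirement — each significant bin contributes |Δ| · (width / 30 min) to
`pos_area` (inoculated hotter) or `neg_area` (uninoculated hotter).
Degenerate bins with zero pooled standard error get p = 1 when the means
agree and p = 0 otherwise, so constant identical arms are never flagged.
The statistic is additive over any split of the series and scales
linearly with the data (Welch p-values are scale invariant); both
properties are tested.

Note the aau normalisation is a convention: absolute published area
values are reproducible only under the same bin width, test, and the
original data. What transfers is the construction.

## Sap flow and daily windows

The thermal-dissipation (Granier) conversion is available but **off by
default**: field reports often publish sap flow in g H₂O h⁻¹ without
their probe calibration, so analyses run on the recorded signal unless a
`granier_calibration()` is supplied. The defaults are the classic
heat-dissipation constants α = 119×10⁻⁶ m³ m⁻² s⁻¹ and β = 1.231 on the
flow index K = (ΔT_max − ΔT)/ΔT; flow = α K^β × sapwood area × water
density, i.e. 42.84 g h⁻¹ at K = 1 with 1 cm² of sapwood.

Daily comparisons use the half-open window 10:00–16:00 — the hours of
maximal transpiration — averaging each plant's in-window points (72 per
day at 5-min cadence) and testing arms per day with the same engine as
the binned contrast. Star codes mark the smallest passed threshold of
{0.05, 0.01, 0.001}.

## Yield, harvest index and phenology

The harvest index is HI = 100 × mean grain yield / mean total aboveground
biomass (both g). Yield components run through the standard chain:
Shapiro–Wilk on model residuals, Levene across the twelve treatment
cells, then a full-factorial three-way ANOVA (genotype, inoculation,
irrigation; 7 effect terms + residual). **Type II sums of squares** are
used: harvested designs lose the odd plant, Type II is robust to that
mild imbalance, and it reduces to the classical balanced table otherwise
(the terms then partition the total SS exactly, which is tested). Tukey
HSD letter groups are produced only for terms significant at α; letters
come from maximal cliques of the non-significance graph, so two levels
share a letter exactly when their HSD comparison is not significant.

Phenology: unpaired t-tests per hybrid between arms on emergence,
anthesis and silking days; the anthesis–silking interval uses only
plants with both dates, while *flowering proportions* count every plant
(plants lacking either date are flowerless). The flowering decision rule
in the source protocol is grammatically ambiguous ("exceeded by 10% the
number of flowerless plants" does not fix a base or direction); the
implemented rule — flag an inoculation effect when the flowering
proportions of the two arms differ by more than 10 percentage points —
is an explicit, configurable stand-in (`flowering_margin`), not a
verified reading of the original intent.

## Colonization robustness and community structure

All abundance tests run on within-sample relative abundances. The
two-group Kruskal–Wallis statistic carries the tie correction; p-values
switch automatically to **exact enumeration of all group labelings** when
the pooled size is ≤ 10 — with four replicates per arm that is C(8,4) =
70 labelings and a minimum p of 2/70 ≈ 0.0286 — and to the χ²(1)
approximation above that. Constant pooled data give H = 0, p = 1 by
convention. A SynCom OTU is a **robust colonizer** in a hybrid × regime
cell iff its test is significant at α *and* its median relative abundance
is higher in inoculated plants; significance alone would equally flag
displaced taxa. Per-regime rollups report OTUs robust in at least one
hybrid. Resident (non-SynCom) OTUs get the same test per regime — hybrids
pooled by default, per-hybrid via `pool_hybrids = FALSE`, since protocols
differ on this — and are labelled enriched / depleted / unchanged; the
summary reports per-regime counts plus the union and intersection across
regimes, because "shifted in both regimes" is ambiguous between the two.
No multiple-testing correction is applied to per-OTU calls, matching the
stated per-OTU `P < 0.05` convention of the profiling protocols this
mirrors.

Community structure: Bray–Curtis dissimilarities (vegan), classical PCoA
via eigendecomposition of the double-centred squared-distance matrix with
negative eigenvalues reported rather than dropped (explained fractions
are relative to the positive spectrum), and ANOSIM with
R = (mean between-group rank − mean within-group rank) / (M/2),
M = n(n−1)/2 — the normalisation that makes R = 1 exactly when every
between-group distance exceeds every within-group distance. Ties take
average ranks. The permutation p-value is (1 + #{R* ≥ R}) / (1 + n_perm)
with a mandatory seed (the global RNG state is restored); for two groups
an exact mode enumerates all labelings, which the tests check against a
brute-force oracle.

## The synthetic-data generator

The generator exists so the whole chain is testable without the original
greenhouse data. It emulates the *statistical structure* the analysis
assumes, at the reference trial's layout: 3 hybrids × 2 × 2 with 4
sensor-equipped plants per cell (48 plants), 117 days, plant sensors
every 5 min, four stations every 15 min, drought from DAS 50 to 80 with
rehydration at 80.

* **Environment**: sinusoidal diurnal temperature (default 25 ± 8 °C
  peaking at 14:00 — a subtropical greenhouse range), anti-phase RH
  (70 ± 20 %), and a clipped daylight sine for illuminance with a
  clear-day maximum of 21 650 lux, which converts to the ~400 µmol m⁻²
  s⁻¹ PAR peak such trials report. Stationary AR(1) Gaussian noise
  (ρ = 0.6) is added per station; RH is clamped to [0, 100] and
  illuminance is exactly zero between dusk and dawn. The day length is
  fixed at 12 h — photoperiod detail is irrelevant to the statistics
  under test. This is deliberately not a climate model: no weather
  fronts, no seasonal trend, no cross-channel physics beyond the shared
  phase.
* **Plants**: T_leaf = air T + per-cell offset + 0.5 °C/kPa × VPD +
  Gaussian noise (sd 0.3 °C). The default inoculation offset of
  −1.5 °C is a calibration knob, not a published value — no quantitative
  effect-size table exists for these offsets — chosen as a mid-single-°C
  cooling consistent with the reported ΔT_leaf excursions of up to
  ~3 °C. Sap flow = per-cell gain × VPD × soil-availability factor, with
  default gains 2.27 vs 1.0 g h⁻¹ kPa⁻¹ reproducing the strongest
  reported daily ratio (≈ 5 vs 2.2 g h⁻¹). SWC holds its set point under
  WW, decays exponentially through the drought window under DS, recovers
  over two days after rehydration, and dips diurnally in proportion to
  VPD — qualitative drought curves, not a soil-hydrology model.
* **OTU table**: Dirichlet-multinomial counts (overdispersion typical of
  amplicon data), 23 SynCom OTUs mapped onto 17 isolate labels plus 200
  power-law residents, library size 10 000. Inoculated samples multiply
  SynCom expected proportions by 10 and 20 mid-rank residents by 5
  (recruitment/displacement). The SynCom baseline (1.6 %) was solved in
  closed form so the inoculated-arm SynCom aggregate lands near 10.5 %,
  the middle of the reported 9–12 % range. Real tables have ~17 000
  OTUs, cross-sample correlation and taxonomy structure; none of that is
  emulated, so passing tests show the *statistics* behave, not that the
  generator is a microbiome.
* **Yield**: per-plant components are cell means plus Gaussian residuals
  (grain sd 8 g; other components scale with it, so residual_sd = 0 is
  exactly deterministic). Default grain means encode the reported
  drought contrast (38.7 vs 9.8 g and 42.7 vs 12.4 g for the responsive
  hybrids, no inoculation effect under WW), biomass means 200 g (WW) /
  150 g (DS), a 9-day anthesis delay under drought, and per-cell
  flowering probabilities including the reported 0.59 vs 0.80 anthesis
  contrast.

Everything is seed-deterministic: identical (design, params, seed) give
bit-identical output, and the pipeline manifest checksums are identical
across runs — both tested.

## Null calibration and power at the study conditions

The test suite verifies, at the defaults above:

* With no injected offset, the fraction of significant bins in a 960-bin
  series sits at α within twice the binomial standard error of such a
  series (√(α(1−α)/960) ≈ 0.007). Welch at n = 4/arm is in fact slightly
  conservative (empirical rate ≈ 0.041 at α = 0.05), which is why the
  per-series binomial spread, not a pooled Monte-Carlo error over tens of
  thousands of bins, is the meaningful yardstick.
* An injected −1.5 °C offset (sd 0.3 °C, 4/arm) yields
  neg_area ≥ 10 × pos_area in ≥ 95 % of 100 replicate windows.
* Under the null, exact Kruskal–Wallis significance at 4 + 4 requires
  complete separation (probability 2/70), and the direction rule halves
  the robust-call rate — the false-positive rate stays below α by
  construction at this n.
* The yield ANOVA flags the inoculation × irrigation interaction in
  ≥ 95 % of 200 simulated trials at 10 plants/cell, and its p-values are
  uniform under an equal-means null.

Problem sizes in the suite (100-replicate contrast windows, 200 ANOVA
replicates, 600 null OTUs, one full 48-plant × 117-day pipeline run
executed twice for the determinism check) were chosen so the whole suite
completes in a few minutes on a laptop while keeping Monte-Carlo error
well below the tested margins.

## Known limitations

* The generator's treatment effects are homogeneous within arms by
  default (every hybrid gets the same offset unless a per-cell table is
  supplied); real trials show strong hybrid × inoculation structure.
* Absolute published headline numbers that depend on the original data —
  a specific significant fraction, aau totals, an ANOSIM R from 17 000
  OTUs — are not reproduction targets; the package reproduces the
  *constructions* and verifies them on oracles and synthetic truth.
* The flowering decision rule is an explicit stand-in (see above).
* ANOSIM's exact mode enumerates two-group labelings only; multi-group
  designs use seeded permutations.
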