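---
title: "warmsoil: models, conventions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{warmsoil: models, conventions and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(warmsoil)
```

`warmsoil` analyses decade-scale warming × management field experiments on
soil microbial carbon cycling. This vignette documents the models it
implements, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the numerical choices made where
the underlying field conventions are genuinely open. No empirical claim is
made here beyond what the package's tests and acceptance script compute.

## The experimental world

The data model assumes a randomized complete block design: two managements
(conservation agriculture = no tillage, chopped residue retained;
conventional = annual tillage, residue removed) × two warming levels
(ambient, +2 °C by infrared heating) × four blocks, sampled biennially over
a decade (2010–2020). Community sequencing typically covers three of the
four blocks; physiological and chemical measurements cover all four. Plot
identity is a deterministic function of (management, warming, block) and is
assumed stable across years — this is required for within-plot time-decay
pairing and is stated as an assumption rather than inferred.

Temporal distance is always measured in calendar years (lags 2, 4, …, 10
for a biennial series), never in sampling indices.

## Microbial physiology from ¹⁸O-H₂O incubations

In the substrate-independent ¹⁸O method, microbes growing during a 48 h
incubation incorporate oxygen from ¹⁸O-enriched soil water (30 atom%) into
new DNA. The field convention reports growth, respiration and uptake as
cumulative µg C g⁻¹ dry soil over the incubation.

**Growth.** The quantitative link between raw isotope measurements and
C_growth is not standardized across laboratories, so the package adopts the
transparent proportional-labeling model: the fraction of DNA oxygen that is
newly synthesized equals the atom% excess of the labeled tube over the
natural-abundance control, relative to the excess of the soil water,

$$G = O_\mathrm{DNA}\cdot
      \frac{a_\mathrm{lab} - a_\mathrm{ctl}}{a_\mathrm{water} - a_\mathrm{ctl}}
      \cdot \frac{f_{co}}{m_\mathrm{soil}},$$

where `f_co` (µg biomass C per µg new DNA-O) absorbs the soil-specific
biomass-C:DNA ratio and any extraction-efficiency correction.
**`f_co` has deliberately no default**: it cannot be reconstructed from
first principles and silently defaulting it would fabricate provenance.
`compute_growth()` errors until the user supplies it; the synthetic
generator records the value it used (default 1.8) in its ground truth.

**Respiration.** Headspace CO₂ accumulation (ppm v/v) is converted with the
ideal gas law at the recorded headspace volume, temperature and pressure
(101325 Pa assumed, with a log message, when unrecorded). Negative CO₂
deltas — common blank drift — are clamped to zero with a warning rather
than rejected. Respiration is assumed cumulative over the same 48 h as
growth; a rate-based alternative would only rescale both terms of CUE
identically.

**CUE.** `CUE = G/(G+R)`, bounded in [0, 1]; uptake `= G + R` holds to
machine precision by construction. `G = R = 0` raises an explicit
undefined-CUE error instead of propagating NaN.

## Necromass from amino sugars

Muramic acid occurs only in bacterial cell walls; glucosamine is mostly
fungal. The standard conversions are

* bacterial residue C = muramic acid (µg g⁻¹) × 45 → µg C g⁻¹,
* fungal residue C = (mmol glucosamine − 2 × mmol muramic acid) × 179.2 × 9
  → mg C g⁻¹ (179.2 mg mmol⁻¹ is the glucosamine molar mass).

The two equations use different unit systems (mass vs molar); the profile
type therefore carries muramic acid in both representations and bridges
them with a molar mass of 251.2 g mol⁻¹ (configurable — the value used by
any given laboratory is rarely stated). `summarize_necromass()` harmonizes
both pools to mg C g⁻¹ (the bacterial µg→mg conversion applied exactly
once) before computing the fungal fraction of necromass and the
contribution of total necromass to SOC.

A glucosamine pool smaller than twice the molar muramic acid implies
negative fungal necromass, which is physically meaningless; the default is
a hard error (strict mode), with an explicit `clamp = TRUE` escape that
floors at zero and warns. Silent clamping was rejected because it hides QC
problems. Galactosamine is stored but enters no conversion; it is retained
for QC ratios only.

## Root exudation

The cuvette-trap equation `c = (Δc·V)/(G·T) · S · 24 · d` mixes mg L⁻¹,
litres, grams, hours, g C m⁻² and days. The package computes in mg and
applies a single, documented mg→g conversion at the end
(`convert_mg_to_g = TRUE`), yielding g C m⁻² per growth period; the
unconverted mg-scale value is available for unit-cancellation checks.

## Community turnover and divergence

**Metric.** Similarity is abundance-based Bray-Curtis
(`1 − Σ|xᵢ−yᵢ|/Σ(xᵢ+yᵢ)`) on counts rarefied without replacement to a
common depth (defaults 24 579 for bacteria, 21 550 for fungi — the
conventional depths for this kind of survey — both overridable). The
underlying field convention ("β similarity") does not pin down a metric;
Bray-Curtis is the community-ecology default, and the similarity matrix is
an explicit object so other metrics can be plugged in.

**Time-decay relationships.** The moving-window census forms all
within-plot pairs of time points: with 6 biennial years that is 15 pairs
per plot ({2 yr: 5, 4 yr: 4, 6 yr: 3, 8 yr: 2, 10 yr: 1}) and 45 per
treatment with 3 sequenced blocks — asserted exactly in the tests. The fit
is OLS of log₁₀ S on log₁₀ Δt; the turnover rate is v = −slope. The slope
is invariant to the logarithm base as long as both axes use the same base
(also asserted). Zero-similarity pairs have no defined logarithm and are
dropped with a reported count; epsilon-flooring was rejected because the
chosen floor would leak into the slope.

**Slope comparison.** Two treatments' TDR slopes are compared by
permutation with the **plot** as the exchangeable unit — all of a plot's
pairs move together, since pairs within a plot share samples and are not
independent. The two-sided p-value uses the add-one convention
`(1 + #{|Δ|ₚₑᵣₘ ≥ |Δ|ₒᵦₛ})/(1 + n_perm)`. With only 3 plots per treatment
the permutation space is coarse (20 distinct splits); calibration tests
therefore pool more plots.

**Lineage TDRs.** A lineage's TDR subsets the table to the lineage's taxa
at a given rank, renormalizes within the subset, and refits. The
warming-induced relative change is `(v_warm − v_control)/v_control`,
defined only for positive control turnover.

**Divergence.** For each (block, year) with exactly one warmed and one
ambient sample, the paired Bray-Curtis dissimilarity is regressed on
calendar year by OLS with adjusted R². Incomplete pairs are skipped with a
log; fewer than 3 years yields an NA trend rather than an error.

## Effect sizes

Cohen's *d* uses the classic pooled-SD form with blocks as the replication
unit (n = 4 per group per year); the small-sample Hedges correction is an
off-by-default flag, because at n = 3–4 it is material and the unadorned
convention is the one usually reported. Positive *d* means warmed > ambient.
Trajectories of *d* against year are fit by OLS (slope, adjusted R², two-
sided slope-test p — the convention used for figure-level statistics) with
the standardized-major-axis slope `sign(r)·sd(y)/sd(x)` reported alongside
(the convention for slope comparisons). `|slope_SMA| ≥ |slope_OLS|` always,
with equality only at |r| = 1. The ln response ratio `ln(X̄_t/X̄_c)`
requires strictly positive means. The early/late stage contrast splits at
2015/2016 by default. No multiple-testing correction is applied within the
module; a log note flags runs fitting more than 10 series.

## The synthetic generator: what it emulates, and what not

The generator produces the full factorial design plus communities,
incubation raws, amino sugars and measurements, with every latent value
recorded as ground truth. Its defaults are the stated world of the
package's acceptance tests:

* **SOC**: baselines 16 / 13 mg C g⁻¹ (conservation / conventional), a
  warming **multiplier of 1.031 under conservation from onset year 2016**
  (the +3.1 % late-stage warming effect), none under conventional.
* **CUE effect trajectory**: the warming effect size under conservation is
  linear with slope 0.83 per year and intercept −4.15, crossing zero at
  year 5 — negative early, positive late; zero under conventional.
* **Turnover**: fungal replacement rates exceed bacterial ones
  (ρ = 0.30–0.40 vs 0.10–0.12 per 2-year step), and warming accelerates
  turnover only under conservation.
* **Divergence drift**: a per-step directional shift of warmed plots
  (0.03 fungi, 0.01 bacteria per step under conservation; zero under
  conventional).
* 500 taxa per domain, depth 25 000, lognormal base abundances —
  configuration, not contract.

**Community mechanism.** Per (management, block), one initial
relative-abundance vector is shared by both warming arms (warming was
imposed on pre-existing plots). At each 2-year step a fraction ρ of
abundance mass is reassigned to previously unused taxa, so the mass shared
with the first year is exactly `∏(1−ρ)` — an analytically checkable
geometric decay (the tests assert shared mass 0.5 and 0.25 after one and
two steps at ρ = 0.5). Two deliberate couplings make the null hypotheses
exact:

* *Replacement draws are shared between the paired warming arms of a
  block*, so with equal ρ and zero drift the paired communities stay
  identical up to multinomial sampling noise and the divergence slope is
  genuinely zero. Year-to-year environmental filtering common to a block
  is the field-world reading of this choice.
* *The replacement support size is chosen to keep Σ√pᵢ approximately
  stationary.* Σ√p sets the multinomial Bray-Curtis noise floor; if
  richness grew freely the noise floor itself would trend upward with
  time and a zero-drift divergence series would show a spurious positive
  slope. This was observed during development and fixed by construction,
  not by widening a test tolerance.

**Measurements.** Block effects are persistent in time and shared between
warming arms (field spatial heterogeneity dominates analytical noise);
measurement noise is Gaussian and small by comparison (SOC noise SD
0.05 mg g⁻¹ vs block SD 0.4). The injected CUE effect size is expressed in
units of the realized between-block SD, so the per-year Cohen's *d*
computed across blocks recovers the injected trajectory *exactly* at zero
noise. Incubation raws are constructed by inverting the physiology module,
and amino-sugar noise is applied to the glucosamine excess above the
2 × muramic floor, so generated profiles always satisfy the strict-mode
precondition.

**Not emulated:** sequences, chimeras, primer or copy-number bias,
compositional effects of varying library size beyond multinomial sampling,
per-treatment variance components calibrated to real field data (the noise
defaults are plausible placeholders), metagenome functional profiles. A
green recovery test therefore establishes that the *estimators* are
correct under the stated generative model — not that the model captures
every feature of real soil survey data.

## Numerical conventions and degenerate inputs

* Validation failures, configuration errors and I/O errors raise classed
  conditions (`warmsoil_validation_error`, `warmsoil_config_error`,
  `warmsoil_io_error`) so callers can branch without parsing messages.
* Missing measurements are NA-marked, never silent zeros; every operation
  that drops NAs reports the count.
* Measurement CSVs carry a `#units` record line and serialize doubles with
  17 significant digits, so read(write(x)) round-trips bitwise.
* Rarefaction is sampling without replacement with an explicit seed;
  samples below depth are dropped and listed.
* All generator randomness derives from one integer master seed through a
  deterministic label-hash; no time-based seeding, all derived seeds below
  2³¹.
* The pipeline config is JSON rather than YAML: the target environment
  ships no YAML parser, and JSON round-trips through `jsonlite` without an
  extra dependency.

## Known limitations

* The permutation test's resolution is bounded by the number of plots;
  with 3 + 3 plots the smallest attainable p is 1/20 regardless of
  `n_perm`.
* Cohen's *d* from n = 4 blocks is noisy (relative SE ≈ 30 % at large
  effects); trajectory trends inherit that noise, which is why the
  acceptance criteria are formulated over 20 seeded replicates.
* `f_co` linearity means mis-specifying it rescales growth, uptake and CUE
  jointly but leaves CUE's ordering across treatments intact only when the
  same `f_co` applies to all samples — per-sample calibration is out of
  scope.
* The geometric-replacement model yields exponential, not exact power-law,
  similarity decay; the log-log TDR slope is still monotone in ρ (asserted
  over a ρ grid), which is the property the analyses rely on.
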