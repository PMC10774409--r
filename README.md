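# warmsoil

Analysis toolkit for decade-long **warming × agricultural-management field
experiments** on soil microbial carbon cycling. It is written for soil
ecologists and biogeochemists who run (or simulate) factorial field trials —
management (conservation vs conventional agriculture) × warming (ambient vs
+2 °C) × blocks × repeated sampling years — and need a reproducible,
testable path from raw measurements to the headline statistics:

* **Microbial carbon use efficiency (CUE)** from substrate-independent
  ¹⁸O-H₂O incubations: growth from DNA ¹⁸O enrichment
  (proportional-labeling model with an explicit, user-supplied conversion
  factor `f_co`), respiration from headspace CO₂ via the ideal gas law, and

  `CUE = C_growth / (C_growth + C_respiration)`

* **Microbial necromass carbon** from amino-sugar biomarkers:

  `bacterial C = muramic acid (µg g⁻¹) × 45`
  `fungal C    = (mmol glucosamine − 2 × mmol muramic acid) × 179.2 × 9`

  with the fungal fraction of necromass and the contribution of necromass
  to SOC.

* **Root exudation carbon** from in-situ cuvette traps:
  `c = (Δc·V)/(G·T) · S · 24 · d`.

* **Community temporal turnover** via moving-window **time-decay
  relationships (TDR)**: all within-plot pairs of time points (15 per plot,
  45 per treatment for 6 biennial years × 3 sequenced blocks), an OLS fit of
  log₁₀ Bray-Curtis similarity on log₁₀ time lag; the turnover rate is
  `v = −slope`. Treatment slopes are compared by a plot-level permutation
  test.

* **Warming-induced divergence**: per-block, per-year Bray-Curtis
  dissimilarity between paired warmed and ambient plots, regressed on year.

* **Effect-size trajectories**: per-year Cohen's *d* (warmed vs ambient,
  pooled SD across blocks) with OLS and standardized-major-axis trends,
  ln response ratios, and early/late stage contrasts.

* A fully **seeded synthetic-data generator** that emulates the factorial
  design and injects known ground truth (geometric-replacement community
  turnover, a directional warming drift, an SOC warming multiplier from an
  onset year, a CUE effect-size trajectory crossing zero mid-study), so the
  whole pipeline is testable without any field data.

## Worked example

```r
library(warmsoil)

cfg <- generator_config(seed = 42, n_taxa = 200, depth = 5000)
exp <- generate_experiment(cfg)

## physiology: CUE from the raw incubation table
cue <- cue_from_incubation(exp$incubations,
                           f_co = exp$config$incubation_constants$f_co)
head(cue[c("sample_id", "c_growth", "c_respiration", "cue")], 3)
#>              sample_id c_growth c_respiration    cue
#> 1 conserv-amb-b1-y2010    3.346         7.197 0.3174
#> 2 conserv-amb-b1-y2012    3.459         7.303 0.3214
#> 3 conserv-amb-b1-y2014    3.562         7.621 0.3185

## necromass: mg C per g soil, fungal fraction, contribution to SOC
nec <- summarize_necromass(exp$aminosugars, exp$measurements$data$soc)
head(nec, 3)
#>              sample_id bacterial_c fungal_c total_c fungal_fraction contribution_to_soc
#> 1 conserv-amb-b1-y2010       2.080    7.416   9.496           78.10               58.18

## community turnover: time-decay relationships
rt  <- rarefy(exp$tables$fungi, 4500, seed = 42)
sim <- bray_curtis_similarity(rt)
tdr_fit(sim, exp$design, "conservation", "warmed")
#> tdr_result [conservation.warmed]: w = -1.1111 (v = 1.1111), adj R2 = 0.922, n = 45 pairs
#>   pairs per interval: 2 yr: 15, 4 yr: 12, 6 yr: 9, 8 yr: 6, 10 yr: 3
tdr_fit(sim, exp$design, "conservation", "ambient")
#> tdr_result [conservation.ambient]: w = -0.7718 (v = 0.7718), adj R2 = 0.940, n = 45 pairs

## warming effect-size trajectory of SOC (Cohen's d per year, OLS trend)
effect_size_series(exp$measurements, exp$design, "soc", "conservation")
#> effect_size_series: soc (conservation)
#>   trend slope 0.2111 (SMA 0.2405), adj R2 0.713, p 0.0216

## warmed-vs-ambient divergence through time
divergence_series(sim, exp$design, "conservation")
#> divergence_series [conservation]: slope = 0.0093058, adj R2 = 0.631, p = 4.95e-05, n = 18
```

Reading the output: the warmed conservation plots turn over faster than
their ambient pairs (fitted v 1.11 vs 0.77 — the generator injected a
higher replacement rate plus a directional drift for that arm); the SOC
effect-size trajectory jumps after the configured 2016 onset of the 3.1 %
warming multiplier, giving a positive trend (p ≈ 0.02); and the paired
warmed-ambient dissimilarity increases linearly with year only where drift
was injected.

## Pipeline and CLI

One JSON config drives the whole run (simulated or file-based inputs):

```r
run_pipeline(list(simulate = list(seed = 7),
                  params = list(n_perm = 999, seed = 7)),
             out_dir = "run7")
build_report("run7")   # Markdown report incl. truth-vs-recovered tables
```

or from the shell: `inst/scripts/warmsoil simulate --seed 7 --out sim7`
(subcommands: `simulate cue exudation necromass tdr divergence effects run
report`).

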