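# pitfoam

Foam accumulating on swine manure deep-pit storages traps methane and has
caused barn fires and explosions. Longitudinal field surveys of such pits
collect, per farm and month, amplicon OTU tables (bacterial 16S rRNA and
methanogen *mcrA*), the pit surface texture (no-foam, crust, foam), diet
records and manure chemistry. **pitfoam** implements the statistical chain
such studies need, end to end, as a tidyverse-style R package:

* **OTU-table QC** — removal of OTUs seen fewer than 5 times overall;
  per-sample read-depth and Good's coverage filters
  (1 − F₁/N; presets 10,000 reads / 0.97 for 16S, 4,000 / 0.99 for
  *mcrA*); total-sum scaling to relative abundances (no rarefaction);
  taxonomic aggregation with pooling of unclassified taxa.
* **Community comparison** — Bray–Curtis dissimilarity
  d(i,j) = Σ|xᵢ−xⱼ| / Σ(xᵢ+xⱼ); one-factor PERMANOVA
  (pseudo-F from the squared-distance partition, R² = SS_between/SS_total)
  with *farm-stratified* permutations so repeatedly sampled farms act as
  experimental blocks, plus an exact full-enumeration mode for small n;
  NMDS by SMACOF majorization with isotonic regression (Kruskal stress-1);
  quadratic least-squares surfaces for overlaying covariates such as the
  methane production rate (MPR) on an ordination.
* **Ordered-trend tests** — Jeffreys–Zellner–Siow one-way Bayes factors
  (Cauchy prior on standardized effects, deterministic quadrature over the
  mixing variance) and the posterior probability that the observed ordering
  of texture means fails, from conjugate posterior draws.
* **Correlation screen** — Spearman's ρ (t-approximation p) for monotonic
  and Hoeffding's D (permutation p) for arbitrary dependence;
  Benjamini–Hochberg adjustment within each (texture, test) family;
  classification: monotonic if adjusted Spearman p < α, non-monotonic if
  only adjusted Hoeffding p < α, else none.
* **Community stability** — within-farm Bray–Curtis dissimilarity versus
  time lag, fit to y = a·e^(bx) (a smaller slope b = a more stable
  community), 999-fold bootstrap slope distributions per texture, compared
  by the kernel-density overlap coefficient OVL = ∫ min(f̂₁, f̂₂).
* **Core communities** — prevalence-threshold core sets per texture, Venn
  partition of shared/unique members, bootstrap percentile CIs of mean
  relative abundances, and Bayes-factor differential abundance
  (conventional thresholds BF₁₀ ≥ 100 at genus, ≥ 20 at species rank).
* **Synthetic cohorts** — `generate_cohort()` draws a full survey with
  known ground truth: per-farm texture Markov chains, logistic-normal
  compositions with farm/texture/drift effects, negative-binomial depths,
  singleton OTUs (so coverage filters bite), ordered diet means, and
  planted within-texture correlations. Every downstream stage is validated
  against these planted signals.

All results are tibbles or small S3 objects with `tidy()`/`glance()`
methods and `autoplot()`s; every stochastic step takes a seed.

## Worked example

```r
library(pitfoam)

cohort <- generate_cohort(cohort_config(seed = 42))
cohort
#> <manure_cohort> 561 samples, 46 farms x 13 months
#>   16S OTUs: 2300  mcrA OTUs: 460
#>   textures: no_foam 194, crust 185, foam 182

qc    <- qc_pipeline(cohort$counts_16s, min_total = 5,
                     min_reads = 10000, min_coverage = 0.97)
relab <- relative_abundance(qc$counts)
meta  <- dplyr::semi_join(cohort$metadata,
                          tibble::tibble(sample_id = names(relab)[-1]),
                          by = "sample_id")

d <- bray_curtis(relab)
permanova(meta, d, farm, n_perm = 999, seed = 1)
#> PERMANOVA: farm
#>   pseudo-F = 17.32, R2 = 0.6614, p = 0.001 (999 sampled permutations)
permanova(meta, d, texture, strata = farm, n_perm = 999, seed = 1)
#> PERMANOVA: texture (strata: farm)
#>   pseudo-F = 28.21, R2 = 0.1132, p = 0.001 (999 sampled permutations)
```

The farm a sample came from explains far more community variance
(R² = 0.66) than the surface texture does (R² = 0.11), yet the texture
effect is highly significant even when permutations are restricted to
within-farm relabelings — the blocked design the analysis assumes.

```r
trend_table(meta, c("DDGS", "SBM", "MPR"), seed = 1)
#>   variable observed_trend            bf10 p_not_trend significant
#> 1 MPR      Foam > Crust > No-foam 3.60e97           0 TRUE
#> 2 DDGS     Foam > Crust > No-foam 2.22e73           0 TRUE
#> 3 SBM      No-foam > Crust > Foam 1.22e53           0 TRUE
```

Distiller's grains (DDGS) and methane production rate rise from no-foam to
foam manures while soybean meal falls — decisive Bayes factors, and
essentially zero posterior probability that the observed orderings are
artifacts.

```r
screen_correlations(meta, tibble::tibble(var_a = "LCFA", var_b = "SCFA"),
                    n_perm = 199, seed = 1)
#>   group       n spearman_rho spearman_p_adj hoeffding_D classification
#> 1 no_foam   158       0.0964       2.28e- 1    0.000285 none
#> 2 crust     144       0.101        2.26e- 1    0.00246  none
#> 3 foam      143       0.799        5.26e-33    0.269    monotonic
```

The long-chain/short-chain fatty acid coupling appears in foam samples
only (ρ = 0.80) — the signature of efficient LCFA → SCFA conversion.

```r
stability_comparison(relab, meta, n_boot = 999, seed = 1)
#> Stability fit [no_foam]: y = 0.08386 * exp(0.06037 x), 501 pairs
#>   bootstrap slope median 0.06007 (95% 0.04864..0.07416, 999 reps)
#> Stability fit [crust]: y = 0.0654 * exp(0.03474 x), 366 pairs
#>   bootstrap slope median 0.03449 (95% 0.02413..0.04914, 999 reps)
#> Stability fit [foam]: y = 0.06212 * exp(0.02383 x), 389 pairs
#>   bootstrap slope median 0.02284 (95% 0.01108..0.03932, 999 reps)
#> # A tibble: 3 x 3
#>   group_a group_b    ovl
#> 1 no_foam crust   0.0532
#> 2 no_foam foam    0.0107
#> 3 crust   foam    0.386
#> no-foam vs pooled crust+foam OVL = 0.0360
```

Non-foaming communities drift apart fastest (slope 0.060/month versus
0.023 under foam); their bootstrap slope distribution barely overlaps the
pooled crust+foam distribution (OVL = 0.036) — foaming communities are
the stable ones.

`run_pipeline(pipeline_config(...))` chains all stages for both markers
and writes every table plus a hash manifest; `inst/cli/pitfoam.R` exposes
the same stages as shell subcommands (`simulate`, `qc`, `ecology`,
`trends`, `correlations`, `stability`, `cores`, `all`).

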