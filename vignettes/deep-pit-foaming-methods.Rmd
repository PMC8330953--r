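---
title: "Methods: community analysis of deep-pit manure foaming surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community analysis of deep-pit manure foaming surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pitfoam)
```

pitfoam analyses longitudinal, multi-farm surveys of swine deep-pit manure:
per farm and month, an observer records the pit surface texture (no-foam,
crust, or foam), manure chemistry and diet composition are measured, and the
bacterial (16S rRNA) and methanogen (*mcrA*) communities are profiled as OTU
count tables. The scientific questions are which diet and chemistry
variables track foaming, whether foaming pits harbour distinct and more
stable microbial communities, and which taxa define each state. This
vignette records the models behind each stage, the defaults and why they
were chosen, what the bundled cohort generator does and does not emulate,
and the numerical decisions a maintainer would want written down.

## Quality control

OTUs observed fewer than `min_total = 5` times across all samples are
removed first; samples are then filtered on read depth and Good's coverage
`1 - F1/N` (`F1` = OTUs seen exactly once in the sample, `N` = its reads).
The shipped presets are 10,000 reads at 0.97 coverage for 16S tables and
4,000 reads at 0.99 for *mcrA* tables, the conventional thresholds for
these markers. Whether coverage should be judged before or after the
rare-OTU filter is genuinely ambiguous (removing table-wide rare OTUs
deletes most of a sample's singletons and raises its coverage); both are
supported via `coverage_on`, and the default `"filtered"` follows the
filter order itself — rare OTUs first, samples second. The choice is
recorded in the `QcReport` parameters. Counts are never rarefied; all
downstream stages use raw counts or total-sum-scaled relative abundances.

Taxonomic aggregation sums counts over OTUs sharing the lineage name at
the requested rank; OTUs unclassified there are pooled per deepest
classified parent ("unclassified Archaea" and the like), so per-sample
totals are conserved exactly.

## Dissimilarity, blocked PERMANOVA, ordination

Bray–Curtis dissimilarity is computed from the definition
`d(i,j) = sum|x_i - x_k| / sum(x_i + x_k)`. PERMANOVA uses the one-factor
squared-distance partition (`SS_total = sum_{i<j} d_ij^2 / N`, within-group
sums weighted by group size) and `pseudo-F = (SS_b/(a-1)) / (SS_w/(N-a))`.
Farms are handled as *permutation strata*, not as a second model term: the
study design samples the same pits repeatedly, so exchangeability holds
within a farm, and the texture test must only relabel samples within
farms. A deliberate property of this implementation: when texture is
constant within every farm, the stratified permutation distribution
degenerates and p approaches 1 — the analysis refuses to manufacture
significance from pseudoreplication. The p-value carries the add-one
correction `p = (1 + #{F* >= F}) / (1 + n_perm)` and can never be 0; for
n ≤ 10 the `method = "exact"` mode enumerates all distinct label
arrangements instead, making p exact.

NMDS minimizes Kruskal's stress-1 by alternating isotonic regression of
configuration distances on the input dissimilarities (primary tie
treatment: tied dissimilarities may take unequal fitted distances) with
Guttman-transform configuration updates. Restarts combine a
classical-scaling start with random starts scaled to the mean
dissimilarity; the best final stress wins. Convergence is declared when
the stress decrease falls below `tol` (default 1e-7); within a run the
stress trace is non-increasing, and coincident points (zero configuration
distance) contribute zero weight to the update.

The contour overlay of a covariate such as MPR on an ordination is a
full quadratic polynomial least-squares surface in the ordination
coordinates, with R² clipped to [0, 1] and defined as 0 for a constant
covariate. This is a deterministic, dependency-free stand-in for the
spline-based contour fitters ordination packages use; its R² plays the
same role but is not numerically comparable to theirs.

## Bayes-factor ordered trends

Diet and manure variables are compared across the three textures with a
Jeffreys–Zellner–Siow one-way Bayes factor: sum-to-zero group effects
projected to `a - 1` orthonormal contrasts with a multivariate Cauchy
prior of scale `prior_scale = 0.5` ("medium") via its normal scale-mixture
representation, flat grand mean, Jeffreys variance. The remaining
one-dimensional integral over the mixing variance is evaluated by
trapezoid quadrature on a 4001-point log grid spanning e±30 — wide and
dense enough that the result is stable to well under 0.1% and fully
deterministic. For two balanced groups this model reduces exactly to the
JZS two-sample test with effect scale `sqrt(2) * prior_scale`, which is
how the implementation is cross-checked against an independent
double-integration oracle in the tests. Published Bayes factors from
field data are not reproduction targets: they depend on that data, and
the default-prior family used there is matched only in spirit.

The "p-value" reported beside each trend is the posterior probability
that the observed ordering of group means does **not** hold, estimated
from independent conjugate posterior draws of each group mean
(noninformative normal-inverse-gamma limit, i.e. `mean_g +
(s_g/sqrt(n_g)) t_{n_g-1}`), with 10,000 draws by default and strict
inequalities — ties count against the trend. Missing values are dropped
per variable (complete case), so group ns can differ across rows of the
table. The trend analysis is unblocked (no farm random effect); output
metadata carries that caveat, and strongly farm-confounded variables
should be read accordingly.

## Correlation screen

Monotonic dependence is tested with Spearman's ρ (Pearson correlation of
mid-ranks; two-sided p from the t-approximation with n−2 df), arbitrary
dependence with Hoeffding's D computed from the classical rank statistic
with half-corrections for ties, scaled so independence gives ≈0 and exact
functional dependence 1. The Hoeffding p-value is a seeded permutation p
(default 199 permutations — the granularity needed at α = 0.05) rather
than an asymptotic table lookup. Benjamini–Hochberg adjustment is applied
within each (texture group × test family), matching per-group reporting;
a pair is *monotonic* if its adjusted Spearman p < α, *non-monotonic* if
only its adjusted Hoeffding p < α, otherwise *none*. Because |ρ| and D
are not on one scale, "strongest" associations are ranked within
classification type, and both statistics are always reported. Groups
with fewer than `min_n = 8` complete pairs (or a constant variable) are
skipped with a recorded reason.

## Community stability

For each texture, every unordered pair of same-texture samples from the
*same farm* contributes (lag in months, Bray–Curtis dissimilarity);
zero-lag pairs are excluded. Restricting to within-farm pairs is the
central design decision of this stage: between-farm dissimilarity is
dominated by the farm block (R² ≈ 0.5–0.85) and would swamp the temporal
signal. Pairs are pooled across farms and fit by nonlinear least squares
to `y = a * exp(b * x)` (lag in calendar months), initialized from the
log-linear fit of `log(y + 1e-6)`; a start that already fits exactly is
accepted as the solution (the gradient is singular there), and a
perturbed-start retry guards other non-convergences. The bootstrap
resamples *samples* with replacement (each keeps its farm identity),
rebuilds the lag pairs and refits, 999 times by default; replicates that
cannot be fit are redrawn up to a 20% budget, beyond which the group
errors. Slope distributions are compared by the overlap coefficient:
Gaussian KDEs with Silverman bandwidths on a shared 1024-point grid
extending 3 bandwidths beyond both samples, integrated by trapezoid. All
pairwise texture comparisons are reported plus the pooled comparison of
no-foam against crust and foam combined. Groups with fewer than
`min_pairs = 10` lag pairs are skipped with a reason — a two-parameter
decay curve on fewer pairs is not meaningful.

## Core communities and differential abundance

A texture's core is the set of taxa present (count > 0) in at least a
`prevalence` fraction of its samples, default 1.0 ("in every sample"),
evaluated on the QC-filtered table per OTU (aggregation, if any, happens
afterwards). Venn partitions count the disjoint regions of 2–3 core sets.
Differential abundance runs the same JZS Bayes factor per taxon on
relative abundances across textures, with bootstrap percentile CIs
(percentile of the resampled mean) per texture and a "most abundant in"
label from the largest group mean; default thresholds are BF₁₀ ≥ 100 at
genus rank and ≥ 20 at species rank. Taxa with (near-)zero variance get
`bf10 = NA` and are never flagged.

## The synthetic cohort generator

`generate_cohort()` draws the whole survey from one seed, so identical
configs are bit-identical. Per farm, textures follow a first-order Markov
chain (default self-transition 0.88–0.92: pits persist in their state,
and a no-foam-heavy initial distribution relaxing toward a crust/foam
attractor reproduces the declining no-foam / rising crust proportions
such studies report). Community composition is logistic-normal: baseline
OTU log-abundances (sd 1.5) plus Gaussian farm effects, texture effects
and a per-farm random-walk drift whose monthly step sd depends on the
current texture (defaults 0.10 / 0.04 / 0.02 for no-foam / crust / foam,
so non-foaming communities decay fastest), pushed through a softmax and
sampled multinomially at negative-binomial depths (dispersion 5, so a
realistic fraction of samples fails the depth filters). Effect sds are
marker-specific (farm 0.14 / texture 0.12 for 16S, 0.50 / 0.40 for
*mcrA*), chosen once so the generated variance hierarchy matches what
these surveys find: farm blocking dominates texture for both markers and
is much stronger for methanogens. Singleton reads are allocated to a
shared rare-OTU pool at a Gamma-distributed per-sample rate (means 1.5%
for 16S, 0.4% for *mcrA*), which makes Good's coverage nontrivially < 1
and lets the coverage filter bite, while keeping tables at desk scale;
column sums still equal the drawn depths exactly. Diet and chemistry
variables are Gaussian with per-texture means encoding the orderings the
field reports (DDGS, NDF, MPR highest under foam; SBM highest under
no-foam; fiber fractions, temperature and depth highest under crust;
SCFA and acetic acid accumulating in no-foam; LCFA in crust), and planted
correlations (default: LCFA–SCFA, ρ = 0.8, foam only) are induced on the
z-scores before scaling, either linearly or through a centred quadratic
for non-monotonic shapes. A missingness rate (default 5%) drops
farm-months at random, since per-farm attrition is survey-specific.

What the generator does **not** emulate: phylogenetic correlation among
taxa, compositional count correlation beyond the logistic-normal,
sequencing error or chimeras, seasonal covariates, diet changing within a
farm over time, and any direct coupling between the chemistry variables
and the community (MPR, for instance, is ordered by texture but not
driven by methanogen abundances, so an MPR-vs-ordination surface R²
reflects texture structure only). Passing tests on these cohorts
therefore demonstrate that the statistics recover the structure they
claim to detect — not that real manure data satisfy the generative
assumptions.

## Problem sizes and numerical choices

The test-suite defaults keep everything deterministic and quick: the
recovery study runs 20 cohorts at the full default design (46 farms × 13
months) with 199 permutations/bootstraps and 2,000 posterior draws;
size/type-I calibration uses 1,000 null simulations of 18 samples at 199
permutations; the Hoeffding screen study uses 500 replicates at n = 200
with 99 permutations; slope recovery, 100 fits of 200 pairs. The
acceptance script runs the full pipeline at production settings (999
permutations and bootstraps, 10,000 posterior draws). Other numerical
conventions: permutation and enumeration comparisons use a 1e-12 slack on
F-statistic ties; the BH step-up is the textbook `min` cascade; posterior
trend ties are failures; Bray–Curtis refuses all-zero samples rather than
defining 0/0; and every seed the user passes is forwarded verbatim to
`set.seed()` at the entry point of the routine that consumes it.

## Known limitations

PERMANOVA is one-factor (the blocked design is handled by restricted
permutation, not by modelling farm as a term), so farm and texture R²
come from separate tests, and dispersion differences between groups can
masquerade as location effects as in any PERMANOVA. The trend Bayes
factors assume independent observations; repeated measures from one farm
violate that, which is why the blocked PERMANOVA — not the trend table —
carries the community-level inference. Hoeffding's permutation p is
granular at 1/(n_perm + 1). The quadratic environmental surface cannot
follow multimodal gradients a spline smoother would. The stability fit
treats pooled pairs as independent although pairs sharing a sample are
not; the bootstrap over samples (not pairs) is the mitigation.
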