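---
title: "Models and methods behind metstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metstab)
```

## The problem

Final-stage variety trials evaluate a small set of candidate genotypes in
many location-year combinations (environments), each laid out as a
randomized complete block design (RCBD). The phenotype of genotype *i* in
block *k* of environment *j* is modeled as

y_ijk = mu + g_i + tau_j + (ge)_ij + b_k(j) + e_ijk,

with genotype effects g_i, environment effects tau_j,
genotype-by-environment interaction (ge)_ij, blocks nested in environments,
and plot error. The interaction is the scientifically interesting nuisance:
it erodes the correlation between phenotype and genotypic value, and it is
the raw material for stability and adaptability analysis. `metstab`
implements the full analysis chain a breeding program runs on such data:
joint ANOVA and genetic parameters, multiplicative interaction models (AMMI
and GGE), a battery of univariate stability indices, BLUP-based
simultaneous selection statistics, and a rank-concordance comparison of all
those methods.

## Data model

The single input currency is a long-format plot table (`met_table`): one
row per genotype x environment x block x trait. Labels are opaque strings
ordered by first appearance, which makes every derived matrix and ranking
deterministic. Cell means (`cell_means`) are the genotype x environment
table of block-averaged phenotypes; all stability mathematics operates on
this matrix (plus the plot-level table where an index is defined at plot
level). Missing cells are an error on every decomposition path — the
methods here assume complete two-way tables, and imputation is a research
topic of its own, deliberately out of scope.

## ANOVA chain and genetic parameters

`individual_anova()` fits the per-environment RCBD partition;
`homogeneity_check()` applies Bartlett's test to the residual mean squares
and the conventional screening rule that a joint analysis is admissible
when the max/min residual mean-square ratio is below 7. `joint_anova()`
partitions the total SS into genotypes, environments, blocks within
environments, G x E and residual (the balanced fixed-effects layout, via
`stats::aov`), optionally appending IPCA axis rows from the AMMI
decomposition with Gollob degrees of freedom g + e - 1 - 2k. The axis df
are informational; no axis significance test is attempted.

Variance components come from the balanced expected mean squares:
sigma_e^2 = MS_res, sigma_ge^2 = (MS_GxE - MS_res)/r, sigma_g^2 =
(MS_G - MS_GxE)/(r e). Negative method-of-moments solutions are truncated
at zero and flagged, the standard practice. Two phenotypic-variance
conventions circulate in the literature; both are offered.
`component_sum` (the default) takes sigma_p^2 as the plain sum of the three
components — this is the convention consistent with reported variance
tables in cassava VCU work, where sigma_p^2 equals the printed component
sum and heritability follows from it. `mean_basis` divides the interaction
and error by E and ER, which is the correct variance of a genotype mean;
use it when heritability should refer to selection on means across the
whole trial series.

Selective accuracy is sqrt(1 - 1/F) with F = MS_G / MS_GxE. F below 1 would
make the root imaginary; the value is truncated to 0 with a warning because
a trial in which interaction noise swamps genotype signal has no
discriminating power, not negative power.

The expected genetic advance uses GA = k sigma_p h^2 with k = 1.554, the
standardized selection differential for keeping the best 15% of a normal
population; `genetic_parameters()` accepts an externally estimated GA when
one is available from another source, and GAM is always GA as a percentage
of the mean.

`scott_knott()` implements the original recursive likelihood partitioning:
at each node the contiguous split of the mean-sorted genotypes maximizing
the between-group SS B0 is accepted when lambda = pi/(2(pi-2)) B0 /
sigma0^2 exceeds the chi-square critical value at g/(pi-2) df, with
sigma0^2 = (sum (m_i - m)^2 + nu s2y)/(g + nu) and s2y the variance of a
treatment mean. Identical means can never separate, and the partition is
invariant to input order because it operates on the sorted means.

## AMMI, GGE and the biplot constructs

`ammi_decompose()` removes both main effects and SVD-decomposes the doubly
centered residual; `gge_decompose()` removes only environment means
(centering "2", no scaling), so its axes carry G + GxE jointly. Scores are
sign-fixed by forcing the largest-magnitude genotype loading positive on
each axis — SVD is sign-indeterminate and all the derived statistics (ASV,
WAASB, sector winners) are invariant to those flips, so the convention
matters only for reproducible coordinates across platforms. AMMI scores are
scaled symmetrically (sqrt of the singular value to each side). For GGE the
singular-value partitioning is selectable, and defaults to
environment-metric preserving ("SVP 2" in biplot software), the appropriate
choice when the biplot is read for environment evaluation, which matches
how these trials are interpreted.

ASV is the Purchase weighted distance in the IPCA1-IPCA2 plane, with the
first-axis coordinate weighted by SS_IPCA1/SS_IPCA2.

`which_won_where()` computes the convex hull of the genotype markers in the
PC1-PC2 plane. Rather than intersecting perpendicular rays explicitly, each
environment is assigned to the hull vertex maximizing the rank-2 predicted
value (the inner product of the paired scores with singular values restored
once). The two constructions are equivalent — the argmax of a linear
functional over a point set is attained at a hull vertex — and the argmax
form is robust to the degenerate near-boundary cases that ray geometry
handles badly. Collinear genotype markers have no polygon and raise an
error. Only the first two axes enter the sectoring, as the construct is
defined on the biplot; higher axes are ignored deliberately.

Environment discrimination is the marker vector length; representativeness
is the cosine of the angle with the average-environment coordinate (the
mean environment marker). Angles are also labeled acute / orthogonal /
obtuse with a configurable 5-degree band around 90 degrees, since those
qualitative classes are how the biplot is read.

## Stability indices

All Table-style univariate statistics are computed from the cell-means
matrix against the environmental index I_j = Ybar_.j - Ybar_.. (an
environment is favorable when I_j > 0):

* Eberhart-Russell: slope b_i, deviation variance S2d_i =
  sum(delta^2)/(e-2) - MS_res/r (reported as computed, possibly negative —
  only its ranking is consumed, and truncation would destroy rank
  information), RMSE = sqrt(sum(delta^2)/e), and R^2 as regression over
  total SS.
* Perkins-Jinks: the same regression applied to the interaction residuals,
  so B_i = b_i - 1 identically and D_i is the deviation mean square.
* Wricke ecovalence W_i: the genotype's share of the interaction SS; the
  W_i sum exactly to the interaction SS of the matrix.
* Lin-Binns superiority P_i: mean squared distance from the
  per-environment winner, divided by 2e.
* Annicchiarico confidence indices on the percentage scale p_ij = 100
  Ybar_ij / Ybar_.j, li = mean(p) - Z_(1-alpha) sd(p), with a one-sided
  Z (default alpha 0.25, Z = 0.6745) and the sample standard deviation;
  computed for all environments and separately for the favorable and
  unfavorable classes (an empty class yields NA with a warning, not an
  error, because one-sided trials legitimately occur).
* Dispersion: DP is the population standard deviation (n denominator) of
  the genotype's plot-level values — plot level, not mean level, because
  the two orderings genuinely differ and reported tables distinguish them —
  while S2x is the variance (e-1) of its environment means.
* Nassar-Huehn: within-environment ranks, by default on the corrected
  values X_ij - Ybar_i. + Ybar_.. so that genotype main effects do not
  masquerade as stability; Si(1) is the mean absolute rank difference over
  environment pairs and Si(6) the mean absolute deviation from the
  genotype's mean rank, scaled by it. Ties get mid-ranks.

## BLUP-based simultaneous selection

`fit_blups()` treats environments and blocks as fixed and genotypes and
interaction as random, plugging the EMS components into the balanced-case
closed forms. Note that the interaction BLUP is *not* just the shrunken
interaction residual: the genotype mean deviation Ybar_i. - Ybar_..
estimates g_i + mean_j (ge)_ij, and the mixed model splits it between the
two random terms. The closed form therefore carries a second term,

(ge)_ij = c_ge z_ij + c_a (Ybar_i. - Ybar_..),
c_ge = var_ge / (var_ge + var_e / r),
c_a = (var_ge / e) / (var_g + var_ge / e + var_e / (e r)),

which is what an iterative REML solver returns (the test-suite checks
agreement with an independent EM-REML implementation to 1e-6). Genotypic
values GV_ij = mu + g_i + (ge)_ij deliberately exclude the environment main
effect, so the harmonic mean HMGV penalizes interaction instability but not
environment quality; HMGV values consequently sit at or just below the
genotype means. WAASB decomposes the interaction BLUP matrix (doubly
centered, which removes the c_a term exactly) and averages absolute scores
over all axes with explained-proportion weights. The pure-stability WAASB
is kept separate from performance; `performance_stability_score()` provides
the equal-weights composite of the two rank scales, and
`performance_stability_quadrants()` the four-group mean x WAASB
classification.

## Method comparison

`rank_matrix()` converts every index column into genotype ranks under a
per-method direction registry: variance-type statistics ascending,
confidence indices / HMGV / means descending, regression slopes by
closeness to their target (1 for b_i and R^2, equivalently 0 for B_i since
B_i = b_i - 1 — the registry stores the target on the printed scale of each
column). Tied values receive average ranks; display ranks round half-up
(the convention used when such tables are printed), while the exact
averages feed all statistics. Spearman correlations use the exact ranks
with two-sided p-values and 0.05/0.01/0.001 stars. The method grouping
eigen-decomposes the correlation matrix, takes loadings on the first two
components and cuts a Ward tree on those 2-D loadings at k = 4 groups by
default; the source analyses report four groups but not the clustering
algorithm, so Ward on the loading plane is this package's choice — it is
the smallest-assumption reproduction consistent with grouping methods by
biplot proximity. Groups whose rankings track the trait-mean ranking
(mean |rho| at or above 0.6) are labeled dynamic (agronomic) stability,
essentially uncorrelated groups (below 0.3) static (biological) stability,
the rest weak.

## The synthetic generator

`generate_met()` draws every random term independently normal and
zero-mean: genotypes at var_g, environments at env_effect_sd^2 (drawn once,
then treated as fixed downstream, mirroring the fixed-environment joint
ANOVA), interaction at var_ge, blocks at block_effect_sd^2, plot error at
var_error. The defaults are the conditions of a published cassava VCU
series: 12 genotypes x 12 environments x 3 blocks, grand mean 26.14 t/ha,
var_g = 20.16, var_ge = 17.87, var_error = 6.54. Environment and block
spreads (4.7 and 0.9) were calibrated once from the magnitudes of the
corresponding ANOVA strata in that series — sigma_env^2 approximately
(MS_E - MS_blocks)/(g r) and sigma_block^2 approximately
(MS_blocks - MS_res)/g — and are not tuned thereafter. One integer seed
drives deterministic per-effect substreams, so the same seed always
reproduces the same table and each effect's draw is insensitive to the
sizes of the others.

What the generator emulates: the variance structure, balance, and effect
magnitudes the ANOVA/BLUP framework assumes. What it does not emulate:
skewed or outlier-contaminated errors, heterogeneous per-environment error
variances, spatial field trend, or multi-trait genetic correlation. Tests
passing on synthetic data therefore validate the estimators under the
model's own assumptions; they say nothing about robustness to violations
of those assumptions in real trials.

```{r}
met <- generate_met(synthetic_config(seed = 1))
ja <- joint_anova(met, "trait", include_ipca = FALSE)
vc <- variance_components(ja, reps = 3, n_env = 12)
round(c(var_g = vc$var_g, var_ge = vc$var_ge, var_e = vc$var_e), 2)
```

## Numerical choices and degenerate inputs

* SVD sign: largest-|.| genotype loading forced positive per axis.
* Ranks: mid-ranks on ties everywhere; display ranks round half-up.
* Scott-Knott: recursion stops at singleton groups; groups are lettered
  a, b, c, ... by descending group mean.
* selective accuracy at F < 1, negative EMS solutions, empty Annicchiarico
  classes, all-zero interaction in WAASB: each degrades gracefully
  (truncate / flag / NA / zero with a warning) rather than erroring, since
  all occur in legitimate small or quiet trials. Genuinely unanswerable
  requests (ASV without a second axis, which-won-where on collinear
  markers, harmonic means of non-positive values) raise errors that name
  the offending quantity.
* S2di may be negative; it is reported as computed.

## Problem sizes used in the test-suite

The tests run the full 12 x 12 x 3 design where the published df layout is
asserted, and 4-8 genotype x 3-6 environment designs for the
property-based checks; the parameter-recovery study uses 200 simulated
trials at the published variance magnitudes, which recovers the three
components to within a few percent in the mean. These sizes are the
package's choice of a demonstration scale; all functions are O(g e r) or a
small SVD and run comfortably at far larger trial networks.

## Known limitations

Unbalanced or incomplete data are rejected rather than analysed (REML for
unbalanced networks is the natural extension and the reason the BLUP module
isolates its variance-component source); there are no axis-significance
tests for AMMI, no bootstrap regions for biplots, no Shukla/Thennarasu/Kang
statistics, and no multi-trait composite indices. The Spearman p-values use
the large-sample approximation, adequate at g = 12 but approximate below
g = 7.
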