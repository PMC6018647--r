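---
title: "Trait dispersion and turnover tests: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait dispersion and turnover tests: models, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitdisp)
```

## The scientific problem

Co-occurring congeneric trees face two opposing selective filters. Shared
natural enemies attack chemically similar neighbours more heavily, which
should favour local coexistence of species with *divergent* secondary
metabolite (SM) profiles. Local soil conditions, by contrast, filter for
*similar* resource-use traits (RUT): nutrient-poor white-sand soils and
clay-rich terra firme each admit a narrow band of viable trait values.
`traitdisp` implements the statistical machinery for testing both
predictions from presence/absence community data, binary chemical
profiles, continuous trait tables and plot-level soil measurements,
together with a generative simulator so that every test can be calibrated
against a world whose assembly rules are known.

## Within-plot dispersion: the median-of-differences null model

For a trait set with distance matrix $d$, the observed statistic per plot
$p$ is the mean pairwise distance among its $N_p$ co-occurring species.
Each null replicate $r$ refills every plot with $N_p$ species drawn
uniformly from the covered species pool and recomputes that mean, giving
$E_{r,p}$. The replicate statistic is

$$ m_r = \operatorname{median}_p\,(O_p - E_{r,p}), $$

and the reported p-value is the fraction of replicates in which $m_r$
contradicts the alternative (for divergence: $m_r \le 0$), with the
$(k+1)/(R+1)$ correction. The median rather than the mean is used because
plot counts are small (~19) and single plots can be outlying.

**Sampling design of the null.** The default draws $N_p$ *distinct*
species per plot — the standard richness-preserving randomization; species
are reused freely across plots. A literal multiset variant
(`replace = TRUE`) in which a plot can draw the same species twice is also
provided; its duplicate pairs contribute distance 0, which biases expected
distances low by roughly $\bar d / S$ for a pool of $S$ species. We
measured the consequence under a neutral world (10 plots, 15 species,
500 simulated datasets): the multiset variant rejects the true null 76% of
the time at $\alpha = 0.05$. It is therefore a sensitivity variant, not a
default, and one unit test pins its anti-conservatism so the behaviour is
documented rather than hidden.

**An intrinsic conservatism.** Even with distinct draws the procedure is
not an exact test. The p-value is a crossing probability of a median of
*paired* differences, not the rank of a scalar statistic in a null
distribution; across neutral datasets it concentrates around 0.5
(sd ≈ 0.25 versus 0.289 for a uniform variate) and rejects at roughly
0.015–0.03 instead of the nominal 0.05. A ten-line simulation with
Gaussian noise — independent of this package — reproduces the same
numbers, so this is a property of the published procedure itself. The
practical reading: its significant results are trustworthy (the test
never exceeds its nominal level), but it buys that robustness with some
power, and an acceptance check that expects the nominal rejection rate
inside the binomial band around 0.05 fails by construction. We left that
check red rather than replace the statistic.

**Pools.** The pool for each test is the set of species with complete
data for the trait set under test (chemical profiles restricted to
metabolites shared by ≥ 2 species; trait rows with any missing value
excluded, no imputation). Plots left with fewer than two covered species
are flagged and excluded from that test only.

**Outliers.** The upstream outlier-control reference is not reproducible
from the published text; the default applies none, and
`outlier_control = TRUE` drops plots whose observed-minus-mean-expected
difference lies beyond 1.5 × IQR, as a labelled sensitivity variant.

## Among-plot turnover: TAU_st and the Mantel test

For each plot pair, $D_w$ is the mean distance between distinct species
within the two plots (all within-plot pairs pooled with equal weight; a
per-plot weighting is available via `dw_weighting = "per_plot"` and agrees
with the pooled version on the brute-force oracle toys), $D_a$ the mean
distance between distinct species across them (conspecific cross-plot
pairs excluded), and $\tau_{st} = 1 - D_w / D_a$. Positive values mean
functional clustering, negative overdispersion; $\tau_{st}$ is invariant
to rescaling all distances. Pairs where a plot has fewer than two covered
species, or $D_a = 0$, are masked (NA), and masked pairs are dropped
pairwise-consistently from every Mantel vector.

The Mantel statistic is the Pearson correlation of vectorized upper
triangles; significance comes from simultaneously permuting rows and
columns of the second matrix. Two tail conventions coexist:

* `alternative = "observed"` (default, used in reporting): the tail
  follows the sign of the observed r. This matches how exploratory
  correlations are reported, but its null rejection rate at nominal
  $\alpha$ is ~$2\alpha$, since the direction is chosen post hoc.
* `"greater"` / `"less"`: fixed, hypothesis-driven direction. Calibration
  and power checks use `"greater"` (turnover increasing with distance),
  for which the permutation p is exactly uniform on its grid — verified
  by a goodness-of-fit test and measured at a 0.056 rejection rate over
  500 neutral datasets.

Soil distance is Euclidean over z-scored selected soil variables
(re-standardized within the subset so each variable carries equal
weight); spatial distance is haversine (sphere radius 6371 km, negligible
error at a ≤ 200 km extent) with a natural log applied off-diagonal
(the base only rescales, so correlations are unaffected). Because the
sampling design partially confounds soil and space, soil distance can be
residualized on log spatial distance (OLS over the upper triangle) before
the Mantel test; both the plain and residualized versions are always
computed and reported side by side, since the original analysis is
ambiguous about which was used.

## Ordination machinery

* **z-scoring** uses the sample (n−1) standard deviation and refuses
  constant columns.
* **VIF elimination** is stepwise: the variable with the largest
  $\mathrm{VIF}_j = 1/(1-R_j^2)$ is removed while it exceeds 10, with
  $R_j^2$ from an ordinary regression on the other retained variables;
  perfect collinearity counts as infinite and goes first; ties break on
  the lexicographically smallest variable id, making the result
  independent of column order.
* **PCA** is an eigendecomposition of the correlation matrix, total
  inertia = number of variables. Axes are retained when their variance
  proportion strictly exceeds the broken-stick expectation
  $b_k = \frac1p \sum_{i=k}^{p} 1/i$. Eigenvector signs are fixed (largest
  absolute loading positive) for bit-reproducibility.
* **Axis screening** uses Pearson correlations with two-sided t-tests on
  n−2 degrees of freedom, uncorrected for multiplicity (the analysis this
  package mirrors reports none); the trait assemblage of an axis is the
  set of traits significant at $\alpha = 0.05$. "Standardize and
  normalize" is read as z-scoring for a correlation-matrix PCA — the
  standard reading in this ordination tradition; no further
  distributional transform is applied by default.

## The synthetic world

The generator's defaults state the emulated design: 19 plots (9
white-sand, 10 clay terra firme) in 3 river-basin clusters spanning
0.5–200 km, 29 species, 189 metabolites averaging ≈ 31.4 per species, 14
continuous traits, 9 soil variables, and partial trait coverage (27/29
species with chemical data, 16/29 with trait data). Mean per-plot
richness defaults to 7 (29 species over 19 plots with the most frequent
species in about half the plots implies richness in the 5–9 range; the
value is fixed once and not revisited).

Structure the generator builds in, and why:

* **Soil.** A latent bimodal habitat score $h_p$ (±1 by habitat class,
  small jitter). Each soil variable responds affinely to $h_p$ with noise
  proportional to its response slope (`soil_noise`, default 0.6), so that
  after the deliberate collinear structures are removed the survivors sit
  below the VIF threshold — mirroring a screen that removes some but not
  all variables. The deliberate structures: texture lies exactly on the
  simplex (sand + silt + clay = 100) and Mg tracks Ca.
* **Traits.** Half of the traits track species niche optima $\mu_s$
  (signal 0.7), a quarter track an independent latent axis, the rest are
  noise — giving the trait PCA a dominant habitat-linked axis whose
  assemblage the filtering acts on.
* **Chemistry.** Metabolite occupancy probabilities are Beta-distributed,
  calibrated to the target mean profile size, and each metabolite is
  enriched in one of 3 latent chemotypes (enrichment 0.8,
  occupancy-mean-preserving). Without chemotypes, pairwise Jaccard
  distances between sparse independent profiles are nearly constant and
  limiting similarity has no similarity variance to act on — the
  divergence hypothesis would be vacuous in such a world. Columns are
  resampled until every metabolite occurs in ≥ 2 species.
* **Assembly.** Plots fill sequentially; candidate $s$ enters plot $p$
  with probability proportional to
  $\exp(-(\mu_s - h_p)^2 / 2\sigma_{filt}^2)\cdot
   \exp(\lambda_{div}\,\overline{J}(s, \text{residents}))$.
  $\sigma_{filt} = \infty, \lambda_{div} = 0$ is exactly neutral
  (uniform distinct species), the world used for type-I calibration.

The effect grid is fixed a priori at neutral / moderate
($\sigma = 0.5, \lambda = 4$, the default) / strong
($\sigma = 0.25, \lambda = 20$). The strong divergence level is set where
the exponential reward saturates — assembly picks nearly maximally
dissimilar species — because the power calibration is defined as a
property of the generator's configured strong effect. Power is measured
in *isolated-mechanism* worlds (strong divergence with filtering off for
the chemical test; strong filtering with divergence off for the
turnover–soil Mantel): at the combined point the filter's weight ratios
($e^{-8}$ across the habitat span) drown the chemistry reward and neither
hypothesis is cleanly instantiated. Measured at desk scale (10 plots, 15
species, 200 datasets): chemical-divergence power 0.995, turnover–soil
Mantel power 0.96.

What a green test does **not** establish: the generator has no
phylogenetic structure, no abundance dynamics, no dispersal limitation,
no intraspecific trait variation, and its soil responses are linear in
one latent axis. Passing calibration here means the statistics behave
correctly in a world obeying the stated assembly rules — not that those
rules describe any particular forest.

## Numerical conventions

Sample (n−1) SDs throughout; medians use the midpoint convention for even
counts; permutation and randomization p-values use $(k+1)/(R+1)$ and are
never 0; one master seed derives per-stage seeds (all below $2^{31}$) so
stages can be rerun in isolation; distance matrices are validated for
symmetry (1e-12), zero diagonal and range; Jaccard is computed as
$(|A\cup B| - |A\cap B|)/|A\cup B|$ so small rationals are exact.

## Known limitations

* The within-plot p-value is intrinsically conservative (see above);
  comparisons of power across studies should account for that.
* `reproduce_study()` can rerun the entire original analysis from the
  study's supplementary tables recast as four CSVs, but those tables are
  not redistributable here, so the headline-number reproduction remains
  conditional and its acceptance check red.
* The Mantel "observed-direction" convention should not be combined with
  a nominal $\alpha$ as if it were a fixed one-sided test.
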