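---
title: "Models and methods: sand darkness, nesting indices and thermal reaction norms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: sand darkness, nesting indices and thermal reaction norms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestnorm)
```

# The scientific problem

Olive ridley sea turtles (*Lepidochelys olivacea*) nest along the Pacific
coast of Central America, where Holocene volcanism has left a mosaic of
light and dark sand beaches. Dark sand absorbs more solar radiation, runs
hotter, and incubation temperature controls both offspring sex (warmer
nests produce more females) and hatching success (which collapses above a
threshold). `nestnorm` implements the quantitative machinery needed to ask
whether nesting activity is structured by sand colour: scoring sand
darkness from imagery, building a comparable nesting-activity index from
sparse survey counts, fitting the two thermal reaction norms, and testing
the spatial and regression relationships among them.

# Sand-darkness scoring

A beach's colour is summarised by the per-channel modal RGB value of a
square pixel block (nominally 85 x 85 pixels) sampled at the centre of the
beach, where nest density is typically highest. Because images differ in
illumination and atmospheric conditions, the centre colour is standardized
against the lightest and darkest zones of the *same* image. With
$D_\ell$ and $D_d$ the Euclidean RGB distances from the centre mode to the
light and dark endpoint modes, the darkness index is

$$d = \frac{D_\ell}{D_\ell + D_d} \in [0, 1],$$

which anchors exactly at 0 for a beach matching the light endpoint and 1
for the dark endpoint. Only those two anchors are pinned down by the
problem statement; among the normalisations satisfying them we fixed the
ratio form above as the single canonical choice because it is symmetric in
the two endpoints and affine-free (adding a constant offset to all three
channels of all three colours leaves it unchanged along the grey axis).
Channel modes are deterministic: ties break toward the smaller (darker)
value. Distances between beaches use the haversine formula on a sphere of
radius 6371.0 km (the mean Earth radius); each beach is located at the
arithmetic midpoint of its two endpoints, adequate at regional scale and
consistent with the colour being sampled at the beach centre.

# The nesting-activity index

Survey effort in the region is sparse: most beach-by-year cells are never
counted, and the observed years differ between beaches, so raw counts are
not comparable across beaches. The model separates time from space. The
regional total in year $i$ follows one of three families:

* constant, $T_i = T$ (1 parameter);
* exponential, $T_i = T_0 e^{r i}$ with $i$ counted from 0 at the first
  year (2 parameters), so $T_0$ is the total at time zero;
* year-specific, free $T_1 \ldots T_Y$ ($Y$ parameters).

A time-constant proportion $p_j$ of each year's total nests on beach $j$
($\sum_j p_j = 1$, hence $K - 1$ free parameters), giving expectations
$E_{ij} = T_i\,p_j$. Observed counts are modelled as Gaussian with a
dispersion linear in the observed count, $S_{ij} = a N_{ij} + b$ with
$a, b > 0$, so large rookeries are allowed proportionally larger
inter-annual wobble while a zero count keeps a floor dispersion of $b$.
The likelihood is the product of these Gaussian densities over *observed*
cells only. Families are compared by
$\mathrm{AIC} = 2k - 2\ln L$ and Akaike weights
$w_m = e^{-\Delta_m/2} / \sum_m e^{-\Delta_m/2}$; the parameter count $k$
includes $a$ and $b$, since they are fitted (whether the original analysis
counted them is not documented; the choice shifts every model's AIC by the
same constant, so the $\Delta$s and weights are unaffected). The final
index keeps observations where they exist and imputes $E_{ij}$ elsewhere.

Numerical choices:

* **Simplex handling.** The $p_j$ are optimised through the
  additive-logistic (multinomial-logit) transform of $K-1$ unconstrained
  values, so every iterate is interior to the simplex and sums to one by
  construction.
* **Positivity.** Totals, $a$ and $b$ are optimised on the log scale.
* **Dispersion floor.** The likelihood as written is unbounded whenever
  some beach only ever shows zero counts: the optimiser can drive that
  beach's $p_j$ and $b$ jointly toward zero and spike the Gaussian
  density on every zero-count cell. The fit therefore enforces
  $b \ge b_{min}$ (default 0.5 nests, the rounding resolution of an
  integer count; configurable). The stated model only requires $b > 0$,
  so the floor restricts nothing scientifically meaningful.
* **Optimiser.** Nelder-Mead followed by BFGS polish, from a data-driven
  start (column means for $p$, rescaled row sums for $T_i$) plus jittered
  random restarts (default 10) under a caller seed; the best local optimum
  is reported with convergence codes attached. When several families are
  compared, each richer family additionally starts from the best simpler
  optimum embedded in its parameter space (constant is exponential at
  $r = 0$; exponential totals are year-specific totals), which guarantees
  the nested-likelihood ordering
  $-\ln L_{YS} \le -\ln L_{exp} \le -\ln L_{const}$ in practice and not
  just in theory.
* **Identifiability.** Real regional tables can have fewer observations
  than parameters; the fit proceeds but warns and flags the result.
* **Zeros.** Proportions below $10^{-12}$ are excluded from downstream
  log10 regressions and reported, rather than inventing pseudo-counts.

# Thermal reaction norms

Sex ratio at constant temperature $t$ follows the logistic

$$\mathrm{sr}(t) = \frac{1}{1 + e^{(P - t)/S}},$$

with pivotal temperature $P$ (°C, the 1:1 point) and shape $S$ (°C). The
transitional range of temperatures at level $l$ has the closed form
$\mathrm{TRT}(l) = 2|S|\ln\!\frac{1-l}{l}$, with limits
$P \mp |S|\ln\frac{1-l}{l}$; the default $l = 0.05$ gives the TRT 5%.
The closed form is verified against bisection inversion in the test
suite to $10^{-9}$ °C.

Hatching success is the double logistic

$$\mathrm{HS}(t) = \mathrm{MaxHS}
  \cdot \left[1 + e^{4(P_{low}-t)/S_{low}}\right]^{-1}
  \cdot \left[1 + e^{4(P_{low}+\Delta P-t)/S_{high}}\right]^{-1},$$

with $S_{low} > 0$ (rising limb), $S_{high} < 0$ (falling limb),
$\Delta P > 0$ separating the two midpoints, and the factor 4 making each
$S$ the slope of its transition at the midpoint. Each slope parameter
governs its own transition: $S_{low}$ appears only in the rising
denominator and $S_{high}$ only in the falling one, which is the only
assignment consistent with their signs and prior supports.

Both norms are fitted by binomial maximum likelihood: female counts
against sexed counts for the sex ratio, hatched counts against incubated
eggs for hatching success. Model probabilities are clamped to
$[10^{-12}, 1 - 10^{-12}]$ inside the log-likelihood so an observed
success at an extreme temperature cannot produce $-\infty$. L-BFGS-B runs
inside box bounds from a data-driven start plus uniform random restarts.

Credible intervals come from a random-walk Metropolis-Hastings sampler
with independent uniform priors on the same boxes: for hatching success
$P_{low} \sim U[20,40]$, $S_{low} \sim U[0,5]$,
$\mathrm{MaxHS} \sim U[0,1]$, $\Delta P \sim U[0,10]$,
$S_{high} \sim U[-5,0]$; for the sex ratio (whose priors are not
documented in the source analysis) we adopt $P \sim U[25,35]$,
$S \sim U[0.01,5]$, wide enough to span all reported turtle pivotal
temperatures. Updates are one parameter at a time with Gaussian
proposals; a proposal outside its support is rejected (the Metropolis
rule under a flat bounded prior). Proposal scales adapt toward a 0.2-0.5
acceptance rate during burn-in only and are frozen afterwards, so the
retained draws are a valid MH sample. Defaults are 10,000 burn-in and
40,000 retained draws, thin 1 — unstated in the source, chosen as
comfortable for these 2- and 5-parameter posteriors and fully
overridable. Intervals are equal-tailed quantiles (type-7 interpolation);
TRT intervals are obtained by pushing every retained draw through the
closed form.

# Spatial statistics

The Mantel test correlates the strictly-lower-triangle entries of two
distance matrices (geographic distance between beach midpoints; absolute
darkness differences) with Pearson's $r$, and builds the null by
permuting rows and columns of the second matrix simultaneously. The
p-value is the +1-corrected estimator
$p = (1 + \#\{r_\pi \ge r_{obs}\})/(1 + n_{perm})$, one-tailed toward
positive association (the scientific hypothesis is that nearby beaches
are more similar); 9999 permutations by default. An exhaustive
enumerator over all $n!$ relabelings serves as the exact reference for
$n \le 7$ and is cross-checked against the sampled version in the tests,
as is agreement with the community-ecology implementation in `vegan`.

The albedo regressions are ordinary Gaussian least squares through
`stats::lm`: `log10(p_j) ~ darkness`, with a per-km variant
`log10(p_j / length_km)` and an optional length covariate (the source
figure does not say which variant carried the covariate, so both are
exposed). The darkness-volcano relationship is assessed by AIC comparison
of `darkness ~ nearest_volcano_km` against an intercept-only model,
re-using the Akaike-weight machinery.

# What the synthetic generators emulate — and what they do not

The generators exist so the full pipeline can be exercised without the
two proprietary/third-party databases it was designed around. They
emulate the *statistical structure* the analysis assumes:

* `gen_beaches()`: beaches along a straight coastline segment; darkness
  as a logistic-squashed Gaussian random field with exponential spatial
  covariance (default correlation length 100 km), optionally darkened
  near volcanos with an exponentially decaying effect; endpoints from
  log-normal beach lengths (median 2 km).
* `gen_nest_counts()`: true proportions log-linear in darkness (default
  slope $-2$ per darkness unit), totals from the configured temporal
  family, Gaussian noise with sd $aE_{ij} + b$ truncated at zero and
  rounded, and an observation mask. Defaults are the study's conditions:
  90 beaches, 18 seasons, 169/1620 cells observed, $a = 0.1$, $b = 2$.
  Generation uses the latent expectation $E$ in the dispersion (there is
  no observed $N$ yet) while the estimator uses $N$ as specified; the
  mismatch is intentional and probes the estimator's robustness.
* `gen_incubation()`: binomial hatching and sexing outcomes at a grid of
  constant temperatures from true norms set to the study's point
  estimates ($P = 30.24$ °C, TRT 5% $= 3.84$ °C, $P_{low} = 24.83$ °C,
  $P_{low} + \Delta P = 33.57$ °C, $\mathrm{MaxHS} = 0.8$, unit slopes).

They do **not** emulate real-data features such as observer effort
correlated with rookery size, arribada mass-nesting overdispersion,
within-season phenology, sensor- or season-dependent colour calibration,
or temperature fluctuation inside natural nests. Passing recovery tests
on these generators therefore demonstrates that the estimators invert
their own assumed data-generating process at realistic sizes — not that
those assumptions hold on any particular real survey.

# Problem sizes used in the shipped checks

The test suite runs each recovery at the size that makes its claim
meaningful while staying quick on a laptop: proportion recovery on
5 beaches x 10 years at 70% observation over 20 seeds (mean absolute
error < 0.02); sex-ratio recovery on 17 temperatures x 20 sexed
hatchlings over 20 seeds (pivotal temperature within 0.2 °C in >= 90%);
hatching-midpoint recovery on 20 temperatures x 50 eggs (both midpoints
within 0.5 °C); MCMC validation against the analytic Beta posterior of a
binomial toy and a flat target; Mantel type-I error over 400 independent
fields at 999 permutations. The headline real-data quantities (the
published Mantel p = 0.02, the darkness-volcano $\Delta$AIC = 25.50, the
fitted norms) require the original databases and are deliberately out of
scope; the published temporal-model AIC table, which is fully determined
by its three printed AICs, is reproduced exactly.

# Known limitations

* The Gaussian count likelihood is a pragmatic choice inherited from the
  source analysis; a negative-binomial model would respect integer
  support but would not be comparable with the published AIC table.
* Time-constant $p_j$ is forced by data scarcity; beaches whose relative
  use trends over time will be mis-indexed.
* The year-specific family leaves $T_i$ for completely unobserved years
  unidentified; such totals are reported at their initialisation value
  and should not be interpreted.
* The Mantel test inherits the linearity assumptions of Pearson
  correlation; only the permutation p-value is robust.
* Beach midpoints in degree space ignore longitude convergence over a
  beach's own extent (metre-scale error at these latitudes).
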