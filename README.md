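# nestnorm

Quantitative tools for the thermal ecology of olive ridley sea turtle
(*Lepidochelys olivacea*) nesting on volcanic coastlines.

Sea turtle sex is set by incubation temperature — warm nests produce
females — and hatching success collapses when nests run too hot. Along
the Pacific coast of Central America, Holocene volcanism has produced
beaches ranging from white to nearly black sand, and dark sand incubates
hotter. `nestnorm` is aimed at marine-turtle biologists and spatial
ecologists who want to connect those pieces: score sand darkness from
imagery, turn sparse nest-count surveys into a comparable per-beach
nesting index, fit the thermal reaction norms that translate temperature
into sex ratio and hatching success, and test the spatial and regression
relationships among them. Seeded synthetic-data generators emulate the
survey and incubation databases so every stage can be validated end to
end by parameter recovery.

## The models at the core

**Sand darkness.** The modal RGB colour of a pixel block at the beach
centre is standardized against the lightest and darkest zones of the same
image: `d = D_light / (D_light + D_dark)` with `D` Euclidean distances in
RGB space, so `d = 0` is white sand and `d = 1` black. Spatial structure
is tested with a Mantel permutation test (Pearson r of lower-triangle
distances, simultaneous row/column permutations, one-tailed +1-corrected
p), and the volcanic origin hypothesis with an AIC comparison of
`darkness ~ distance to nearest Holocene volcano` against intercept-only.

**Nesting index.** Observed counts `N[i,j]` (year i, beach j) are modelled
as Gaussian around `E[i,j] = T_i * p_j` with sd `S[i,j] = a*N[i,j] + b`.
Annual totals `T_i` follow one of three families — constant `T`,
exponential `T_0*exp(r*i)`, or year-specific — while the beach shares
`p_j` (a simplex, `K − 1` free parameters) are constant over time.
Families are compared by AIC and Akaike weights
`w_m = exp(-Δ_m/2) / Σ exp(-Δ/2)`; unobserved cells are imputed with
`E[i,j]`, and `p_j` is the per-beach activity index regressed (log10) on
darkness.

**Thermal reaction norms.** Sex ratio follows the logistic
`sr(t) = 1/(1 + exp((P − t)/S))` with pivotal temperature `P`; the
transitional range of temperatures is `TRT(l) = 2|S| log((1−l)/l)`.
Hatching success follows the double logistic
`HS(t) = MaxHS * [1 + exp(4(P_low − t)/S_low)]^-1 *
[1 + exp(4(P_low + ΔP − t)/S_high)]^-1`. Both are fitted by binomial
maximum likelihood, with credible intervals from a random-walk
Metropolis–Hastings sampler under uniform priors.

## Worked example

A fully synthetic study on 60 beaches over 8 seasons, with about half the
beach–year cells surveyed:

```r
library(nestnorm)

cfg <- scenario_config(n_beaches = 60, n_years = 8, span_deg = 9,
                       obs_prob = 0.5, seed = 42)
survey <- gen_beaches(cfg)

mantel_test(pairwise_geo(survey$beaches),
            pairwise_absdiff(survey$beaches$darkness, survey$beaches$id),
            n_perm = 9999, seed = 42)
#> Mantel test: r = 0.2115, p = 0.0002 (9999 permutations, greater tail)
```

Nearby beaches have similar sand (the generator's darkness field has a
100 km correlation length, and the test detects it at p = 0.0002).

```r
counts <- gen_nest_counts(cfg, survey$beaches)
tab <- nest_count_table(counts$nests$beach_id, counts$nests$year,
                        counts$nests$nests, beaches = survey$beaches$id)
sel <- select_nesting_model(tab, n_restarts = 5, seed = 42)
sel
#> Model selection for temporal distribution of nesting activity
#>          model n_params negloglik      aic delta_aic  weight
#>       constant       62   598.622 1321.243    172.01 4.4e-38
#>    exponential       63   589.818 1305.635    156.41 1.1e-34
#>  year_specific       69   505.614 1149.229      0.00 1.0e+00
#> Selected: year_specific
```

The year-specific family wins decisively (Akaike weight ~1), as it
should: the generator drew independent annual totals. Regressing the
fitted log10 activity index on darkness recovers the generative slope:

```r
idx <- nesting_index(sel$best, tab)
fit_log10_activity(idx, survey$beaches)
#> log10 nesting proportion ~ darkness (n = 60, AIC = -68.36)
#> (Intercept)    darkness
#>     -1.2281     -1.9226
```

The darkness slope −1.92 recovers the −2 used to generate the
proportions: each unit of darkness costs almost two orders of magnitude
of nesting activity in this scenario. Finally, the sex-ratio norm from a
synthetic incubation experiment (17 constant temperatures, 50 eggs each):

```r
inc <- gen_incubation(scenario_config(seed = 42, eggs_per_temp = 50))
fit <- fit_norm(inc, "sex_ratio", seed = 42)
fit
#> Thermal reaction norm (sex_ratio), 17 records, -lnL = 22.530
#>       P       S
#> 30.3201  0.6611
#>   pivotal 30.32 C, TRT5% 3.89 C (28.37-32.27 C)
ch <- sample_norm_posterior(inc, "sex_ratio", fit = fit,
                            config = mcmc_config(n_iter = 20000,
                                                 burn_in = 5000,
                                                 seed = 42))
round(credible_interval(ch, "P"), 4)
#>   lower   upper
#> 30.1418 30.4950
round(trt_credible(ch)$width, 4)
#>  lower  upper
#> 3.3661 4.6078
```

The generating truth (pivotal 30.24 °C, TRT 5% width 3.84 °C) sits inside
both intervals.

A command-line front end wrapping the same functions ships in
`inst/scripts/nestnorm` with subcommands `simulate`, `color`, `index`,
`norms`, `mantel` and `regress`; see `nestnorm --help`.

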