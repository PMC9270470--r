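# cavorient

Directional ecology of woodpecker cavity orientation: circular statistics,
resampling null models, geographic/climatic gradient analyses, and harmonic
regression of reproductive success, with a calibrated synthetic-data
generator.

## What this package is for

Cavity-excavating birds such as the red-cockaded woodpecker (*Dryobates
borealis*) orient their cavity entrances non-randomly — strongly westward
across the species' range — and the question for evolutionary ecologists is
whether that orientation is an adaptive part of the extended phenotype.
`cavorient` implements the full analysis chain used to address that
question from population monitoring data:

1. **Circular description** (`circ_mean`, `rayleigh_test`,
   `bootstrap_mean_ci`, `circ_summary`). Bearings are unit vectors; their
   normalised vector sum gives the mean direction and the mean resultant
   length *r* ∈ [0, 1]. Uniformity is tested with the Rayleigh statistic
   *z* = *n r*² and its standard series p-value approximation.
2. **Stage-wise clustering null model** (`clustering_null_test`,
   `stagewise_tests`). Is a focal stage (completed cavities, cavity starts,
   nests) more or less directionally clustered than random same-size
   resamples (with replacement) of a reference pool? One-tailed
   *p* = (1 + *b*)/(iterations + 1), ties counting as extreme.
3. **Geographic and climatic gradients** (`latitude_regression`,
   `climate_pca`, `pc_regression`, `partial_mantel`, `sunset_azimuth`).
   OLS of population mean direction (linearised, valid because all means
   sit inside one narrow arc) on latitude or on climate PC1; a permutation
   partial Mantel test of climate distances controlling latitude distances;
   and a solar-geometry helper showing the sunset-azimuth gradient is an
   order of magnitude too small to explain the fitted slope.
4. **Harmonic success models** (`fit_fecundity`, `fit_rate_glmm`,
   `select_model`, `predict_success`). Nest direction θ enters Poisson
   (fledgling count) and binomial-logit (hatch, fledge rate) mixed models
   as paired sin(*k*θ), cos(*k*θ) terms for *k* = 1..4 cycles, with
   group-size (adults) main effects and interactions and a territory
   ("cluster") random intercept; top-down likelihood-ratio selection drops
   the least-supported term block until all remaining blocks are supported.
   Reporting is on the ratio scale (IRR/OR with Wald CIs), with
   τ₀₀, latent-scale ICC = τ₀₀/(τ₀₀ + π²/3), and Cox–Snell/Nagelkerke
   pseudo-R².
5. **Synthetic data** (`sim_config`, `simulate_dataset`, `rvonmises`, ...).
   A von Mises generative world reproducing the structure above, with a
   JSON sidecar of every generating parameter for recovery tests.

The package ships one real input: an 11-population panel of published mean
cavity orientations with coordinates (`table1_sites()`).

## Worked example

```r
library(cavorient)

# published panel: mean direction drifts north with latitude
latitude_regression(table1_sites())
#> OLS of mean direction on latitude
#>   slope = 4.3195 (SE 1.2044), intercept = 123.640
#>   t = 3.586, df = 9, p = 0.005871, R^2 = 0.588

# synthetic monitoring data, full pipeline
sim <- simulate_dataset("paper", seed = 7, out_dir = "simdata")
cav <- read_cavities("simdata/cavities.csv")
stagewise_tests(cav[cav$site == "S01", ], n_iter = 1000, seed = 1)$complete_vs_all
#> Clustering null test (tail = greater)
#>   observed r = 0.4766  null mean r = 0.3645
#>   n_subset = 460, n_pool = 860, iterations = 1000
#>   p = 0.000999

nests <- read_nests("simdata/nests.csv")
sel <- select_model(nests, "binomial_rate", "hatch")
sel$fit
#> Harmonic mixed model for hatch (binomial_rate)
#>         term    OR        ci       p
#>  (Intercept) 1.285 0.98-1.69 7.5e-02
#>       adults 1.205 1.11-1.31 4.4e-06
#>         sin2 0.332 0.23-0.48 7.0e-09
#>         cos2 1.292 0.88-1.89 1.9e-01
#>  adults:sin2 1.457 1.30-1.63 1.0e-10
#>  adults:cos2 0.948 0.85-1.06 3.4e-01
#> n = 702, logLik = -788.35, tau00 = 0.092, sigma2 = 3.29, ICC = 0.03
```

The slope of 4.32°/degree latitude means the average cavity swings from
WSW in Florida toward WNW in Kentucky; *r* = mean resultant length (1 =
perfectly aligned); odds ratios below/above 1 mean hatch odds fall/rise
with that harmonic component, and the significant `adults:sin2` term means
the directional effect strengthens with group size (two optima 180° apart).

## Command line

```sh
Rscript -e 'cavorient::run_cli()' simulate --preset paper --seed 7 --out d/
Rscript -e 'cavorient::run_cli()' summarize --cavities d/cavities.csv
Rscript -e 'cavorient::run_cli()' nulltest --cavities d/cavities.csv \
    --iterations 1000 --seed 1 --out null.csv
Rscript -e 'cavorient::run_cli()' nestmodel --nests d/nests.csv \
    --family binomial --response hatch --out fit.json
```

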