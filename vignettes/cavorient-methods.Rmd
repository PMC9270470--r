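---
title: "Methods: circular statistics, null models, and harmonic success models for cavity orientation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cavity-orientation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavorient)
```

This vignette documents the statistical models behind `cavorient`, the
assumptions they make, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open. It states no empirical
result that the package's tests and acceptance script do not themselves
compute.

## 1. Circular description

A compass bearing is stored in decimal degrees clockwise from north on the
half-open interval [0, 360); a single modulo-360 is applied on ingest
(360.0 becomes 0.0), and values at or beyond 720 before that modulo are
rejected as recording errors rather than silently wrapped. Each bearing is
a unit vector; the mean direction and the mean resultant length
*r* = ‖Σᵢ(cos θᵢ, sin θᵢ)‖ / *n* come from the normalised vector sum.
*r* = 1 means perfect alignment, *r* = 0 arises both from uniform spread
and from exact cancellation; below a tolerance of 1e−12 the mean direction
is reported as undefined rather than as an arbitrary `atan2` artefact.

The Rayleigh test of uniformity uses *z* = *n r*² with the second-order
series approximation

p = e^{−z} [1 + (2z − z²)/(4n) − (24z − 132z² + 76z³ − 9z⁴)/(288n²)],

clamped into [0, 1]. The approximation is standard for a unimodal
alternative; below *n* = 10 the function warns that it is crude, and exact
permutation p-values are deliberately out of scope. A property test checks
that p is monotone decreasing in *r* at fixed *n*.

**Bootstrap CI for the mean direction.** Percentile intervals are formed
on *angular deviations* of bootstrap-replicate means from the observed
mean, mapped through ((Δ + 180) mod 360) − 180, so an interval straddling
north is reported correctly (e.g. [352°, 7°]). Replicates with *r* = 0
(undefined mean) are redrawn and counted. The deviation-percentile scheme
was chosen because a naive percentile of raw bearings is meaningless on a
circle; coverage is verified by simulation (≈95% nominal) in the
acceptance suite.

## 2. The stage-wise clustering null model

The ecological claim is ordinal: cavity starts are the least, completed
cavities more, and nest cavities the most directionally concentrated
stage, because poorly aligned excavations tend to be abandoned. The test
asks whether the observed *r* of a focal subset (e.g. all completed
cavities at a site) could have arisen by drawing the same number of
bearings *with replacement* from a reference pool (all excavations at that
site). One tail is specified a priori: `greater` for completes-vs-all and
nests-vs-completes, `less` for starts-vs-all.

Numerical choices, each of which the spec left open:

* p = (1 + b)/(iterations + 1), so p is never zero and the test is valid
  at finite iterations; b counts null values at least as extreme, with
  ties counting as extreme (conservative). Tie detection uses a 1e−12
  epsilon because the resampled *r* of an identical multiset differs from
  the observed one by floating-point rounding.
* Nest cavities are completed cavities and therefore belong to both the
  "all excavations" pool and the completed-cavity pool of the nest test;
  `exclude_nests_from_pool = TRUE` exposes the alternative.
* Default 1000 iterations; a subset larger than its pool is permitted
  (sampling is with replacement) but logged.

Correctness is checked two ways: against full enumeration of all
pool^n resamples on tiny inputs, and by type-I calibration — under the
exchangeable null the rejection rate at α = 0.05 must sit in [0.03, 0.07].
With 199 resamples, α = 0.05 is exactly attainable under the (1 + b)
convention, which is why the calibration simulations use that count.

## 3. Gradients in mean direction

Population mean directions are treated as plain numbers for regression.
This linearisation is valid only when every mean lies inside one
contiguous arc narrower than 180°; the functions compute the minimal
enclosing arc and raise an error — never a silent re-centering — when the
condition fails, because an automatic shift could flip the sign of a
fitted slope without the analyst noticing. In the shipped 11-population
panel all means lie between 242° and 290°, so the condition holds with a
wide margin.

Climate enters as the 19 standard bioclim variables, centered and scaled
before PCA (equivalently, eigendecomposition of the correlation matrix),
so variance proportions are invariant to the variables' units.
Zero-variance columns are dropped with a warning because standardisation
is undefined for them. Component signs are fixed by requiring the
largest-magnitude loading of each component to be positive — PCA signs are
otherwise arbitrary and would break reproducibility of reported scores.
Altitude is deliberately not a predictor.

The partial Mantel test correlates the upper triangles of a response
distance matrix (pairwise absolute differences of mean direction) and a
climate distance matrix (Euclidean on the standardised variables),
controlling a latitude distance matrix, with significance from jointly
permuting rows and columns of the response matrix. Permuting the raw
response matrix is the default; residual permutation is available via
`method = "residual"`. The partial correlation is computed by the
closed-form three-correlation formula and cross-checked in tests against
the regress-and-correlate-residuals route. A covariate whose distances are
(numerically) collinear with the predictor's makes the partial correlation
undefined; the guard triggers below a denominator of 1e−6 because exact
zero is rarely reached in floating point.

**Sunset azimuth.** Solar declination is approximated by
δ = 23.44° · sin(2π(day − 80)/365.25) and the sunset azimuth by
A = 360° − arccos(sin δ / cos φ). This sinusoidal approximation is
accurate to a fraction of a degree — far more than needed, since its only
role is the order-of-magnitude contrast between the sunset-direction
gradient per degree of latitude and the fitted orientation gradient. The
day of year is an explicit argument; the packaged contrast uses day 135
(mid-May), inside the nesting season, where the gradient is roughly 0.2°
of azimuth per degree of latitude — an order of magnitude below the
fitted ~4.3°/degree slope. The conclusion is insensitive to any plausible
day choice within the breeding-to-excavation season.

## 4. Harmonic models of nesting success

Direction must enter a regression through periodic terms; sin(kθ) and
cos(kθ) pairs for k = 1..4 cycles form the basis, and a pair always enters
or leaves a model together (a lone sine fixes the phase arbitrarily).
Group size (adults, the raw count, minimum 2 for a breeding pair) enters
as a main effect and optionally through interactions with the
trigonometric pairs; an interaction pair requires its main-effect pair.
Responses:

* total fecundity — fledgling count, Poisson log link;
* hatch rate — hatchlings out of eggs, binomial logit;
* fledge rate — fledglings out of hatchlings, binomial logit.

Rates are aggregated per nest as (successes, failures) — the likelihood is
identical to per-egg rows with fewer records; nests with a zero
denominator carry no information about the rate and are excluded with a
logged notice. Repeated measures on the same territory enter through a
cluster random intercept estimated by Laplace-approximate maximum
likelihood (`lme4::glmer`); year is not a covariate. When the cluster
variance estimate falls below 1e−6 the fit is declared singular and the
fixed-effects-only model is refit and reported — the two have identical
fixed-effect estimates at that point, and reporting the GLM avoids a
spurious zero-variance random effect.

**Reporting.** Coefficients are exponentiated to incidence-rate ratios
(Poisson) or odds ratios (binomial) with Wald intervals on the link scale;
for logit models the latent residual variance is π²/3 ≈ 3.29, giving
ICC = τ₀₀/(τ₀₀ + π²/3). Pseudo-R² follows Cox–Snell,
1 − exp((2/n)(ll₀ − ll₁)), and Nagelkerke, the former divided by
1 − exp(2·ll₀/n).

**Top-down selection.** From the full model (cycles 1–4, adults, all
interactions, cluster intercept) the least-supported block is removed
repeatedly: at each step every currently droppable block (interaction
pairs first; a cycle pair only once its interaction is gone; adults only
once no interaction remains) is refit and the block with the largest
likelihood-ratio p is dropped if p > 0.05. An AIC criterion is available
behind `criterion = "AIC"`. The scan fits use `nAGQ = 0`
(penalised-least-squares approximation) for speed — on these data its
log-likelihoods differ from Laplace in the second decimal, far below the
chi-square thresholds involved — and the final and null models are refit
with the Laplace approximation for reporting. If the full model is
singular the entire selection path uses fixed-effects fits so that all
compared likelihoods are on the same footing. The full trace (block,
log-likelihoods, statistic, p, decision) is returned for audit.

Predictions over a direction grid are fixed-effects only (random intercept
at zero) with delta-method intervals on the link scale; a final model
containing only 2-cycle terms necessarily yields curves with period 180°,
i.e. two directional optima opposite one another.

## 5. The synthetic world

The generator states one fixed world (overridable via `sim_config`):

* **Sites.** 11 populations evenly spanning latitudes 28–36.8°, the first
  3 carrying detailed censuses (400 starts, 400 completes, 60 nests) and
  the rest panel-sized counts (40/60/12). Detailed-census sizes reflect
  that full site censuses of long-monitored populations run to hundreds of
  excavations; the panel sizes only need to yield stable site means.
* **Orientations.** von Mises with mean μ(L) = 245° + 4.8°·(L − L_min) —
  matching the observed span of population means (~242–290°) over ~9° of
  latitude — and concentrations κ_start = 0.55 ≤ κ_complete = 1.0 ≤
  κ_nest = 1.1, enforced as a config invariant. These imply expected *r*
  of about 0.26, 0.45, and 0.48, inside the published per-population range
  (0.27–0.55). Sampling uses the Best–Fisher (1979) rejection scheme,
  exact for all κ; κ = 0 falls back to the circular uniform. The Bessel
  ratio A(κ) = I₁(κ)/I₀(κ) and its numerical inverse are exported so
  tests can target an expected *r* directly.
* **Climate.** Each bioclim variable is an affine function of standardised
  latitude plus independent Gaussian noise (sd 0.3), temperature levels
  loading negatively and seasonality positively, so climate PC1 is
  strongly collinear with latitude by construction — reproducing the
  situation in which latitudinal and climatic explanations cannot be
  separated.
* **Nesting.** 702 first-brood records scattered with gaps over 80
  clusters × 13 years. Adults follow a distribution over 2–7 (mode 2–3,
  rare 6–7, plausible for a cooperative breeder with helpers); clutch size
  1–5 with mode 3–4. Hatchlings are binomial in eggs with logit
  probability β₀ + β_A·A + (β_s + β_sA·A)·sin 2θ + (β_c + β_cA·A)·cos 2θ
  + u_cluster, u ~ N(0, τ₀₀); fledglings are binomial in hatchlings with
  the analogous fledge-coefficient predictor and the same cluster effect.
  Default coefficients are the logs of the published ratio-scale
  estimates (hatch: 0.30, 0.16, −0.56, 0.17, 0.22, −0.03; fledge: 0.26,
  0.40, −0.43, 0.72, 0.14, −0.25) and τ₀₀ = 0.17; the construction makes
  fledglings ≤ hatchlings ≤ eggs hold row by row. A JSON sidecar stores
  every generating parameter, which is the contract that makes
  parameter-recovery testing possible. The logistic link keeps
  probabilities inside (0, 1) for any coefficients, so no clipping is ever
  needed.

**What the generator does not emulate** — and hence what a green test does
not establish: spatial point patterns of cavity trees, tree-level ecology
(resin wells, fungal communities, snake predation), multi-brood dynamics,
year effects or temporal autocorrelation, observation error in compass
bearings, and any real climate covariance structure beyond collinearity
with latitude. Passing tests certify the statistical machinery against
this stated world, not ecological truth.

## 6. Recovery properties and their limits

Two properties of the selection procedure bound what structure-recovery
tests can demand. First, sequential null tests at α = 0.05 across ~6
spurious blocks retain at least one spurious block with probability
roughly 1 − 0.95⁶ ≈ 0.26, so *exact* structure match cannot exceed ~75%
on average — recovery is therefore scored as the final model *containing*
the generating terms, with the exact-match rate reported alongside.
Second, the generating interaction pair is unbalanced (adults:sin2 strong
at 0.22, adults:cos2 near zero at −0.03), so the joint 2-df test of the
pair carries most of its signal in one coordinate; with n = 702 its power
is high but not 1, and replicates in which the pair (and then,
cascading, the main 2-cycle pair) is dropped are expected occasionally.
Both rates are measured, not assumed, by `tests/testthat/test-acceptance.R`
and `scripts/acceptance.R`. Similarly, with κ_nest/κ_complete = 1.1/1.0
the nests-vs-completes comparison is truly close to its null, so the
"nests not significantly more clustered" pattern reproduces in most but
not all site replicates — occasional significance at one of three sites
is a property of the stated world, not a defect.

## 7. Known limitations

* The Rayleigh p-value is an asymptotic series, not exact; axial
  (mod-180) statistics and second-order (mean-of-means) analyses are out
  of scope.
* The latitude and PC1 regressions inherit all OLS assumptions; with 11
  populations the t-based inference is fragile to influential sites, and
  no spatial autocorrelation structure is modelled.
* Wald intervals on the link scale can undercover for variance components
  near boundaries; τ₀₀ itself is reported without an interval.
* The CLI is a thin chaining surface: one subcommand per analysis stage,
  CSV/JSON payloads, seeds and input digests logged; it does no caching
  or dependency tracking between stages.
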