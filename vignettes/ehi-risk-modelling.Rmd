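---
title: "Modelling exertional heat illness risk in racehorses: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling exertional heat illness risk in racehorses: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Exertional heat illness (EHI) in Thoroughbred racehorses is a rare binary
outcome — on the order of 1 runner in 1,000 — observed on a large population
of runs with strong structure: the same horse runs repeatedly over its
career, runners are clustered in race meets that share a day's weather, and
the plausible risk factors mix smooth continuous effects (race distance,
heat load, acclimatisation, age) with categorical ones (going, year,
off-time band, previous incident). `ehirisk` implements an end-to-end,
reproducible pipeline for this setting: environmental covariate derivation,
exclusion filtering, rare-event binomial GAMM fitting on case-control
down-sampled data, cross-validated backward model selection, odds-ratio
effect extraction, probability recovery, and classification assessment —
plus a synthetic population generator with known ground truth so every stage
can be tested by parameter recovery.

## Environmental covariates

Racecourse heat load is summarised by an estimated wet bulb globe
temperature (WBGT). With only daily maximum air temperature $T$ (°C) and
relative humidity $H$ (%) available, the wet-bulb temperature is
approximated by Stull's arctangent formula (angles in radians, $H$ in
percent — the only convention under which the formula reproduces its
published values),

$$T_{wb} = T\,\mathrm{atan}[0.151977 (H + 8.313659)^{1/2}]
  + \mathrm{atan}(T+H) - \mathrm{atan}(H - 1.676331)
  + 0.00391838\,H^{3/2}\,\mathrm{atan}(0.023101 H) - 4.686035,$$

the black-globe temperature by the linear approximation
$T_g = 1.54\,T + 8.65$, and the index by
$\mathrm{WBGT} = 0.7\,T_{wb} + 0.3\,T_g$. These are deliberately exact
re-statements of the published estimation chain — no wind-speed or solar
term — so the covariate has the same meaning and the same limitations as in
the original analysis. Acclimatisation is summarised by the mean daily
maximum temperature over the five days strictly before the race day; an
incomplete window yields a missing value (and later exclusion) rather than a
silently shortened mean, which would bias the covariate for exactly the
courses with patchy weather records. Note one numerical quirk documented by
the tests: the wet-bulb approximation is very slightly non-monotone in
humidity below about 4 °C and 10 % RH, an edge of its validity domain.

## Preprocessing and exclusions

The ten official going categories collapse to five modelled levels (firm,
good, soft, heavy on turf; standard on all-weather); "standard to slow" is
accepted as a synonym of standard. Exclusions are applied in a fixed,
logged order: (1) rig horses, (2) all runners at all-weather meets run over
"fast" going, (3) rows with any missing model covariate. The
previous-incident flag is strictly prior: a run's own outcome never feeds
its own flag, so the flag is 0 up to and including a horse's first EHI and
1 after — preventing response leakage into a covariate. Two runs of one
horse at an identical date and off time make the ordering undefined and are
an error rather than an arbitrary tie-break. The 17:00 boundary itself is
assigned to the evening (post-5 p.m.) band.

## The model and the fitter

The response is modelled as a binomial GAMM with logit link:

$$\mathrm{logit}\,P(\mathrm{EHI}) = \alpha + f_1(\mathrm{dist}) +
 f_2(\mathrm{WBGT}) + f_3(\mathrm{prev5}) + f_4(\mathrm{age}) +
 \beta_{\mathrm{going}} + \beta_{\mathrm{prev}} + \beta_{\mathrm{year}} +
 \beta_{\mathrm{off}} + b_{\mathrm{horse}} + b_{\mathrm{meet}},$$

with each $f_j$ a penalized cubic regression spline with shrinkage (basis
`"cs"`, 10 knots by default; results vary only marginally with more), so a
smooth can be penalized all the way to the zero function, and
$b_{\mathrm{horse}}, b_{\mathrm{meet}}$ zero-mean random intercepts.

Because a down-sampled frame still contains thousands of distinct horses
and meets — most observed once — the coefficient vector has roughly 10,000
entries, nearly all of them random-intercept levels. Dense GAM fitting is
quadratic-to-cubic in that count; the package therefore fits the penalized
likelihood directly by IRLS on a *sparse* normal-equations representation:
the information matrix is assembled blockwise (dense smooth/parametric
block, diagonal random-effect blocks, sparse horse-by-meet cross-counts)
and factorised with a sparse Cholesky. Spline bases and penalties come from
`mgcv::smoothCon`, so fitted smooths live in the standard basis, and on
problems small enough for both, the fitter matches `mgcv::gam(method =
"REML")` to three or more decimals in coefficients, effective degrees of
freedom, and random-effect standard deviations (this equivalence is asserted
in the test suite, where mgcv serves as an independent oracle).

Smoothing parameters and random-effect precisions are chosen by
Fellner–Schall updates of the restricted marginal likelihood,
$\lambda_j \leftarrow (p_j - \lambda_j\,\mathrm{tr}(V S_j)) / (\hat\beta_j'
S_j \hat\beta_j)$ — a REML-type criterion, the default in modern GAM
practice. Traces over the large random-effect blocks use a Hutchinson
estimator with a fixed Rademacher probe matrix (20 probes by default; the
blocks are near-diagonal, so probe error is well under a percent, and the
fixed probes keep fits bit-reproducible). Exact traces are used for the
small smooth blocks. Numerical details: IRLS weights are floored at
1e-10, step-halving guards the penalized deviance, a scaled ridge of 1e-9
guards the unpenalized block against aliasing, coefficients beyond ±18 in
magnitude trigger a quasi-separation warning, and λ is clamped to
[1e-6, 1e8] with at most a tenfold move per update.

Prediction clamps smooth covariates to their training range (with a
warning) rather than extrapolating spline polynomials, and assigns zero
random intercepts to unseen horses or meets — the behaviour a test fold
needs. Unseen categorical levels are an error, not a silent reference-level
guess.

## Rare events: down-sampling and class adjustment

With ~0.1 % incidence, all cases are kept and controls are randomly
down-sampled at 10 controls per case, raising the fitted-data incidence to
about 9 %. Case-control sampling leaves non-intercept logistic coefficients
invariant (asserted empirically in the acceptance tests); only the
intercept, and hence absolute probabilities, shift. Absolute probabilities
are restored by the odds-scale prior correction
$\mathrm{odds}_{\mathrm{adj}} = \mathrm{odds}(p) \cdot \pi(1-q)/(q(1-\pi))$
with $q$ the sampled and $\pi$ the true case fraction — strictly increasing,
fixing 0 and 1, the identity when $q=\pi$. Calibration of the composed
procedure (down-sample, fit, adjust) is tested by logistic recalibration on
50,000 held-out rows, where the slope is 1 within ±0.1.

## Model selection

Candidate models are compared by 5-fold cross-validation. Folds are a
uniformly random row-level partition (sizes within one); for each fold the
*training* portion only is down-sampled, the model fitted, and the untouched
test fold — at the true incidence — predicted and class-adjusted. Scores are
the Brier score $BS = N^{-1}\sum_t (f_t - o_t)^2$ and a scaled version
against the reference score $BS_{max} = \bar p(1-\bar p)$ at the test fold's
observed outcome proportion $\bar p$. Two scalings are implemented: the
standard Brier skill score $1 - BS/BS_{max}$ (default; lives on a 0–1 scale,
~17 % for a useful rare-event model) and the ratio form $(1-BS)/BS_{max}$,
which at rare-event incidences is numerically enormous; both are strictly
decreasing in $BS$, so selection decisions agree under either. Backward
selection repeatedly removes the term whose removal gives the best mean
scaled score, accepting it if not worse than the incumbent by more than
0.05 scaled-percentage points — a removal that merely fails to *improve*
prediction does not justify keeping a term — and stops when no removal
qualifies. Random intercepts are never candidates. Every evaluated model is
recorded in a selection ledger.

## Effects and classification

Odds ratios of a smooth term are not constant, so they are reported for
stated covariate intervals: $\mathrm{OR} = \exp\{f(b) - f(a)\}$ with a
delta-method standard error $\sqrt{d'Vd}$ from the coefficient covariance
(the inverse penalized information matrix) and a 95 % Wald interval.
Categorical terms are compared pairwise at marginal means: all other terms
held at their mean fitted per-observation contribution over the training
data (closer to marginal-means semantics for smooths than plugging in
covariate means; random effects at zero), with single-step
multivariate-normal (Tukey-type) adjustment of the p-values over the full
contrast family — the same family-wise logic as `emmeans`' default, computed
from the joint normal law of the contrast statistics rather than the
studentized-range shortcut. Confidence intervals are reported unadjusted.

Classification uses the rule $p \ge t$ (ties positive). The threshold is
chosen by maximising the G-mean $\sqrt{\mathrm{TPR}(1-\mathrm{FPR})}$ over
the grid $t = 0, 0.01, \dots, 1$, returning the smallest maximiser —
favouring sensitivity, the right tie-break for a screening application.
AUC uses the Mann–Whitney tie convention and is invariant under the
(monotone) class adjustment; only the threshold value depends on the scale.
Race-level aggregation asks whether *any* runner in a race is flagged and
whether any presents with EHI, which trades false positives for coarser
spatial resolution. Both the pooled confusion matrix at the mean per-fold
threshold and per-fold medians are reported, since either convention is
defensible.

## The synthetic population generator

The generator emulates the analysed study population: ~620,000 runners over
July 2010 – April 2018 at 0.1 % EHI prevalence; ~45,000 horses with
negative-binomial career lengths (mean ≈ 14 runs) and ages advancing with
the calendar; 60 courses (15 % all-weather); meets of ~70 runners (6–8 races
at 35-minute intervals, afternoon or evening start) placed more densely in
summer; daily weather per course as a seasonal sinusoid (UK scale: winter
≈ 7 °C, summer ≈ 21 °C maxima) plus AR(1) noise, with humidity negatively
correlated with temperature; going driven by a wetness proxy of the same
weather. True effects enter on the log-odds scale. Categorical truths use the
published field estimates of the pairwise contrasts (going, year, off
time); the previous-incident log-odds is ln 18.59; random-intercept SDs are
0.3 (horse) and 0.2 (meet) — no field estimates of these exist, so they
encode the package's prior that unobserved heterogeneity beyond the
modelled covariates is modest once previous incidents and weather are
accounted for.

Smooth truths are piecewise-linear anchor tables (so the truth is
representable without reference to any spline library) whose pinned
two-point contrasts hold exactly: OR 5.66 for 3,520 vs 1,760 yd, 10.14 for
WBGT 30 vs 20 °C, 0.33 for a preceding 5-day average of 25 vs 15 °C, 1.34
for age 4 vs 2 and 0.82 for age 6 vs 4. Between and beyond the pinned
points the anchors lie on smooth, low-curvature curves — gradual slope ramps
for WBGT and distance, a single linear slope for the 5-day average, and for
age the exact parabola through the three pinned points with a mild linear
decline for veterans. This shape discipline is a design requirement, not a
nicety: penalized smoothers round sharp corners and redistribute their
curvature, so free-hand kinks in data-sparse regions would bias anchored
parameter recovery for reasons that say nothing about the pipeline under
test. Conversely, one attenuation is irreducible: the two pinned age
contrasts jointly fix the second difference (the peak curvature) of the age
effect, and REML shrinkage attenuates exactly that kind of local curvature
at the study's information level (~650 cases), so the recovered age 4-vs-2
odds ratio sits persistently 10–20 % below its anchor. The recovery tests
report this honestly rather than tuning around it.

Outcomes are drawn sequentially per horse in date order with a shared
uniform draw per run, so the previous-incident state updates after each
simulated EHI exactly as the preprocessing derives it. The intercept is
calibrated by bisection on the *exact* expected prevalence of this
sequential process (a per-horse recursion over no-event probabilities), not
on the first-run approximation.

What the generator does *not* emulate: real covariate joint distributions
(BHA field sizes, course geography, trainer effects), measurement error in
gridded weather, temporal drift in recording practice, or any horse-level
susceptibility beyond a Gaussian intercept. Passing recovery tests
therefore shows the pipeline estimates what the data-generating model
encodes — not that the printed estimates are externally correct.

## Problem sizes used in the tests

The automated suite runs at desk scale by design: calibration at ~120,000
runners (1 % prevalence, 50,000 held out); case-control invariance over 20
seeds at ~12,000 runners; anchored-OR recovery in the suite over 5 full
populations of ~620,000 (the acceptance script uses 10); selection
behaviour over 20 seeds at ~4,500 runners with ~150 cases each. Selection
at that case count is noise-limited — cross-validated score differences
between terms of genuinely different importance can invert — so its
pass-rate assertion is the most fragile in the suite; the scale was chosen
for the compute budget and is stated here so the trade-off is explicit.

## Known limitations

The fitter covers the model family this pipeline needs (binomial logit,
univariate `cs` smooths, categorical fixed effects, random intercepts) —
not tensor products, other families, or correlated random slopes; for
those, use mgcv directly at whatever scale it can bear. Fellner–Schall
updates converge to a REML stationary point but the random-effect precisions
of near-singleton grouping factors are weakly identified in any framework;
their λ values wander more than the smooth λs (the fits cap outer updates
rather than polishing them, which leaves interval odds ratios unchanged to
three decimals). P-value adjustment assumes the joint normal approximation
of the contrast statistics, as does every delta-method interval here.
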