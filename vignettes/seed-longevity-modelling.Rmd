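---
title: "Modelling seed longevity from germination time-series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling seed longevity from germination time-series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedspan)
```

## The model

Seed death in a stored lot is well described as a normal distribution of
individual lifespans. Consequently the germination percentage, transformed
to probit units, declines *linearly* with storage time:

$$ v = K_i - \frac{p}{\sigma} $$

where $v$ is viability in probit units after $p$ days, $K_i$ is the initial
viability of the lot (the intercept), and $\sigma$ — the standard deviation
of the distribution of seed deaths in time — is the number of days taken to
lose one probit of viability. `seedspan` uses the classical NED+5 probit
convention: $v = \Phi^{-1}(g/100) + 5$ for germination percentage $g$, so
50% germination corresponds to exactly 5 probits and the storage half-life
is

$$ P_{50} = \sigma\,(K_i - 5). $$

$P_{50}$ is the single number used to compare longevity across species and
storage regimes. A lot already below 50% germination at the start of
storage ($K_i < 5$) has $P_{50} = 0$ by convention, flagged
`below_50_at_start`; a $P_{50}$ beyond the last sampling time is reported
but flagged `extrapolated`.

Across storage environments, $\sigma$ itself follows the seed viability
equation

$$ \log_{10}\sigma = K_E - C_W\,\log_{10} MC - C_H\,T - C_Q\,T^2 $$

with $MC$ the seed moisture content in % fresh weight and $T$ the storage
temperature in °C. $K_E$ and $C_W$ are species-specific moisture constants;
$C_H$ and $C_Q$ are temperature constants. All logarithms in the package
are base 10, and moisture is carried on the fresh-weight basis throughout
(`convert_mc_basis()` moves between fresh and dry bases where needed). The
package ships **no default constants**: `viability_constants()` always takes
explicit values, because constants are species-specific and presenting any
particular set as a default would invite silent misuse. Examples in the
documentation use an illustrative set ($K_E = 9$, $C_W = 5$, $C_H = 0.033$,
$C_Q = 0.0005$) chosen to have the right orders of magnitude for orthodox
seeds.

## Two estimators of the viability line

`fit_viability_line()` is the classical workflow: one probit value per
sampling time (the replicate-mean germination percentage), ordinary least
squares against time. It matches how longevity plots are conventionally
drawn and fitted, and is exact on data lying on a probit line. Its
weakness is the probit transform's undefined value at 0% and 100%. Two
policies are offered through `correction`:

* `"exclude"` (default): 0%/100% points are dropped and recorded in
  `excluded_points`. Conservative — no information is invented — at the
  cost of discarding the extremes.
* `"bartlett"`: the pooled count $r$ of $n$ seeds is replaced by
  $(r + 0.5)/(n + 1)$, keeping the point. Requires the pooled seed count
  per time (`n_seeds`).

Independently of the policy, every all-zero time point *after the first
zero* is always excluded (reason `"dead-lot plateau"`): once the lot is
dead, further zeros carry no information about the slope and would only
distort a corrected fit.

`fit_viability_glm()` is the count-aware alternative: maximum-likelihood
binomial regression with a probit link on the raw replicate counts,
$\Phi^{-1}(p) = (K_i - 5) - t/\sigma$. It needs no 0/100% policy (the
binomial likelihood handles boundary counts), weights time points by their
information content, and reports the log-likelihood at the optimum. Because
the GLM maximises exactly the likelihood that `viability_loglik()`
evaluates, its log-likelihood always dominates the one obtained by plugging
in the least-squares parameters — a cross-estimator consistency check the
test suite and the acceptance script both exercise (100 random instances).
On noiseless probit-linear data the two estimators agree to better than
$10^{-3}$.

$K_i$ is always *estimated* as the intercept, never pinned to the observed
day-0 germination: the intercept of the fitted loss line is the model's
definition of initial viability, and the day-0 test is just one more noisy
point on that line.

Degenerate inputs are handled explicitly rather than numerically: a
non-declining series yields $\sigma = \infty$ with `p50()` raising an
error; complete separation in the GLM (an all-or-nothing step in time) is
flagged with estimates at the boundary the IRLS search reached; fewer than
two usable time points is an error that lists every exclusion and its
reason.

## Bootstrap intervals for P50, and their calibration

`bootstrap_p50_ci()` resamples replicates with replacement independently
within each sampling time, refits the probit least-squares line to the
resampled replicate means (the same closed-form fit as
`fit_viability_line()`, vectorised across resamples; the test suite checks
the two paths agree), and takes a percentile interval over the resampled
$P_{50}$ values. Resamples whose refitted line does not decline contribute
$P_{50} = +\infty$ — the honest statement that the resampled lot outlives
the record — rather than being discarded, which would bias the upper bound
downward. Only resamples with fewer than two usable time points count as
failures, and a failure rate above 20% aborts the interval.

A known limitation, which the acceptance script measures rather than hides:
with 5 replicates per time point the percentile interval under-covers. At
the reference design (true $K_i = 6.28$, $\sigma = 300$ d, sampling
{0, 90, 180, 270, 360} d, 5 × 20 seeds, $B = 1000$) the measured coverage
of the nominal 95% interval is about 88–91% over 500 simulated lots, with
the misses concentrated on intervals sitting entirely *above* the true
value. Both ingredients are textbook small-sample behaviour: $m$-of-$m$
resampling of $m = 5$ replicates deflates the bootstrap variance by
$(m-1)/m$, and the percentile interval follows the right skew of the
$P_{50}$ sampling distribution in the direction that hurts. We verified
that the shortfall is not an artefact of the refitting path: a GLM-refit
bootstrap measures *worse* (≈ 83%), and the Bartlett policy changes
nothing. Treat the interval as approximate at typical germination-test
sizes; the point estimators themselves are nearly unbiased (see below).

## Group comparison: ANOVA + Student–Newman–Keuls

Germination tables conventionally carry significance letters from a one-way
ANOVA on the replicate percentages followed by Student–Newman–Keuls (SNK)
pairwise comparisons at $\alpha = 0.05$. `compare_groups()` implements
exactly that: `stats::aov()` for the ANOVA, then the stepwise SNK procedure
on studentized-range quantiles (`stats::qtukey()`), testing the widest
ranges first and propagating non-significance inward, with the harmonic
mean of the pair's replicate counts for unbalanced groups. Percentages are
analysed untransformed — the convention for these tables — and no arcsine
or logit transform is applied. Normality (Shapiro–Wilk on residuals) and
variance homogeneity (Levene) are available as *diagnostics* that warn but
never gate the analysis (`diagnostics = TRUE`), because there is no
universally agreed fallback and silently switching tests would make tables
irreproducible. When every group has zero within-group variance the ANOVA
is undefined; the function warns and falls back to exact equality
comparison.

The empirical type-I error of the full pipeline, measured on 2000 null
simulations (two groups of 5 replicates from the same Binomial(20, 0.8)) by
the acceptance script, sits at 4.7–5.9% depending on the seed — consistent
with the nominal 5% despite the discreteness of count-derived percentages.

SNK letters answer "which groups differ from which"; the
`significant_vs_control` flag answers the narrower "which treatments differ
from the reference". Both groupings are reported because published tables
use sometimes one, sometimes the other, and the letter family (within a row
vs within a column of a table) is an editorial choice the data model should
not hard-code.

## Sorption isotherms and moisture bookkeeping

The viability equation consumes moisture on the fresh-weight basis; storage
protocols specify relative humidity. The bridge is the empirical water
sorption isotherm: equilibrium moisture content measured gravimetrically
(oven-drying, e.g. 103 °C for 17 h) at a series of water activities
$a_w = RH/100$. `build_isotherm()` averages replicates per $a_w$, sorts the
curve, and *flags* (never reorders) monotonicity violations — on a sound
isotherm, equilibrium moisture rises with water activity, so a decrease
signals a measurement problem the analyst must see. `interpolate_mc()` is
deliberately plain piecewise-linear interpolation in $a_w$, exact at the
measured points: no sorption model (GAB, D'Arcy–Watt) is fitted, because
the empirical curve is the deliverable and a model would smuggle in shape
assumptions. Extrapolation beyond the measured $a_w$ range is refused with
an error, never performed silently.

## Climate association

`join_p50_climate()` inner-joins per-lot $P_{50}$ estimates with a
user-supplied site-climate table (annual mean temperature, annual
precipitation, elevation) and lot metadata, recording unmatched lots.
`genus_grouped_association()` then computes, per genus and covariate, the
OLS slope and the squared Pearson correlation, skipping genus groups with
fewer than 3 lots. $P_{50}$ is regressed untransformed (days) by default —
matching how longevity–climate scatter plots are drawn — with a
`log10_response` option since half-lives are ratio-scaled and a log
treatment is equally defensible. An explicit `include` list restricts the
lots entering the regression, because published analyses sometimes use a
stated subset of the fitted lots; the package never guesses a subset.
Climate extraction from gridded databases is out of scope: covariates
arrive as a CSV, keeping the package download-free.

## The synthetic-data generators

Every estimator above is validated by parameter recovery on generated data,
so the generators are first-class, tested code.

`simulate_lot()` draws, for each scheduled day $t$ and replicate,
$n_{germ} \sim \mathrm{Binomial}(n_{sown},\ \Phi(K_i - t/\sigma - 5))$ —
binomial sampling around the exact probit line. Defaults are the standard
germination-test design: 5 replicates of 20 seeds. Pure binomial noise is
the default because it is the noise model the probit analysis itself
assumes; a beta-binomial `overdispersion` knob exists for robustness
studies. What the generator deliberately does **not** emulate: between-test
environmental drift, scorer effects, seed-lot heterogeneity beyond the
binomial, and dormancy — so passing recovery tests demonstrates estimator
correctness under the model's own assumptions, not robustness to field
messiness.

`simulate_climate_panel()` draws covariates uniformly over ranges chosen to
look like a small continental collection (8–14 °C, 60–930 mm,
100–2200 m a.s.l.) and sets the true half-life as a linear function of the
covariates plus normal lot-level noise, floored at 1 d to avoid
non-physical values. The defaults (a 6-lot panel, +210 d per °C, noise SD
150 d) give half-lives spanning roughly 200–1500 d, the order of magnitude
separating short- and long-lived lots in dry-room storage.

`simulate_isotherm()` uses a smooth monotone truth curve
$mc(a_w) = c_0 + c_1 a_w + c_3 a_w^3$ (defaults rising from ~3% at
$a_w = 0.15$ to ~26% above water, the typical shape for dry orthodox seeds)
with additive normal noise and 3 replicates per level.

Reproducibility is a hard contract: every generator is bit-identical given
its config seed, restores the caller's RNG state, and
`recovery_experiment()` derives per-lot substreams from its master seed by
a deterministic counter scheme, so enlarging an experiment never perturbs
the lots already drawn.

## Recovery performance at the reference design

The design used throughout for calibration — and recomputed from scratch by
`scripts/acceptance.R` — is 500 simulated lots with $K_i = 6.28$ (90%
initial germination), $\sigma = 300$ d/probit (true $P_{50} = 384$ d),
sampled at {0, 90, 180, 270, 360} d with 5 × 20 seeds. At seed 1 the GLM
estimator's median relative $P_{50}$ error is 5.7% and its relative RMSE
9.1%; the least-squares estimator is only slightly behind. These sizes keep
the whole acceptance run under a minute on one CPU while leaving the
Monte-Carlo error on each reported rate small (binomial SE ≈ 1–1.4
percentage points at 500–2000 draws).

## Known limitations

* The percentile bootstrap under-covers at 5 replicates (measured ~88–91%
  for nominal 95%; see above). A BCa or basic interval would likely correct
  the asymmetric misses but is not implemented.
* The least-squares path fits the probit of the replicate-*mean* percentage,
  which is not the mean of the replicate probits; at germination means near
  the extremes this transform bias is visible, and the GLM is preferred
  there.
* The SNK procedure controls the type-I error per step, not the familywise
  rate under all configurations — the known trade-off of SNK against Tukey
  HSD. It is implemented because it is the convention for germination
  tables.
* Isotherm interpolation is bounded by the measured $a_w$ range; no
  hysteresis (absorption vs desorption) handling.
* The climate module quantifies association in small panels (n of 6–8 lots
  per genus); with such n, a single lot can move $R^2$ substantially, which
  is why the lot `include` list is explicit and unmatched lots are always
  reported.
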