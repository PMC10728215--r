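---
title: "Modelling physiological fluctuation during awe: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling physiological fluctuation during awe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(awedyn)
```

This vignette is the package's account of its science: the models it fits,
the preprocessing rules it applies, what the synthetic-data generator does
and does not emulate, and the design decisions taken where the analysis
recipe left genuine freedom. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## 1. The scientific question

During a 2-minute emotional video, do skin conductance responses (SCRs),
pupil diameter, and a continuous joystick report of felt "invisible
presence" *fluctuate* more under awe than under amusement or neutral
viewing? Average levels cannot answer this: two conditions can share a mean
while one oscillates strongly around it. The package therefore quantifies
fluctuation as a model parameter of a structural time-series model, and
separately runs conventional hierarchical mean comparisons so both views
are available.

## 2. The smoothed-trend state-space model

Each 1-Hz group-level series $y_t$ ($t = 1, \dots, T$; $T = 120$ for pupil
and joystick, $110$ for SCR counts, which start after the 10-s onset
exclusion window) is modelled as

$$y_t = \mu_t + \epsilon_t, \qquad \epsilon_t \sim N(0, \sigma_\epsilon^2),$$
$$\mu_t = 2\mu_{t-1} - \mu_{t-2} + \zeta_t, \qquad \zeta_t \sim N(0, \sigma_\zeta^2).$$

The second difference of the trend is white noise: $\sigma_\zeta$ has the
units of the signal per second-squared step and measures how fast the
trend's *slope* changes. A noiseless quadratic has a constant second
difference; a locally linear trend has $\sigma_\zeta \approx 0$; a trend
that keeps changing direction has a large $\sigma_\zeta$. The initial
states $\mu_1, \mu_2$ are (approximately) diffuse — variance $10^7$ on the
standardized scale — so an overall level and linear drift are absorbed by
the initialization. Two invariances follow and are enforced by tests:
adding $a + bt$ to a series leaves the $\sigma_\zeta$ posterior unchanged
up to Monte-Carlo error, and multiplying the series by $k$ multiplies both
SD posteriors by $k$.

**One $\sigma_\zeta$ per series.** The trend disturbance is homoscedastic
within a series. A time-varying $\sigma_\zeta$ (stochastic volatility)
variant is deliberately out of scope; "fluctuation" here is a per-series
summary, compared across conditions.

**Priors.** Half-Normal$(0, s)$ on both $\sigma_\zeta$ and
$\sigma_\epsilon$, with $s = \max(\mathrm{sd}(\Delta^2 y), 10^{-3})$
computed from the (standardized) series' second differences. The second
difference of the data has variance $\sigma_\zeta^2 + 6\sigma_\epsilon^2$
under the model, so this scale is an upper bound on either SD —
weakly-informative by construction, and it adapts to the units of the
series. The $10^{-3}$ floor prevents a degenerate prior when the second
differences are exactly constant (the quadratic-trend limit). Initial
states are centred at $y_1$.

**Sampling.** The latent trend is integrated out with a Kalman filter
(state $(\mu_t, \mu_{t-1})$, all algebra 2x2), and an adaptive random-walk
Metropolis sampler moves on $(\log\sigma_\zeta, \log\sigma_\epsilon)$;
step size adapts toward 30% acceptance during warmup. This marginal
sampler mixes well even when $\sigma_\zeta$ is near zero, where samplers
that alternate between states and variances stall (the states then pin the
variances and vice versa). For each retained draw the trend is drawn
exactly by backward conditional sampling from the filtered moments, so
`fitted()`, `plot()` and trend credible bands reflect full posterior
uncertainty. The series is standardized internally (results are
back-transformed) for numerical stability of the filter.

Desk-scale default: 4 chains x 2,000 iterations with 1,000 warmup, about
0.2 s per series; `paper_scale = TRUE` switches to 4 x 20,000 with 12,000
warmup for publication-grade effective sample sizes. Convergence is
reported per parameter (rank-normalized split R-hat < 1.10, bulk and tail
ESS > 1,000 by default); failure flags the fit and propagates a warning
rather than failing silently, since a flagged fit is still informative for
diagnosis.

**Condition contrasts.** $\sigma_\zeta$ draws are averaged draw-wise
across each condition's two videos, and
$\sigma_{dif}(\text{awe} - \text{others})$ (and the amusement analogue)
summarize condition differences with equal-tailed 95% credible intervals.
Each of the six series is fitted independently with identical priors;
pairing independent posteriors draw-by-index is equivalent to treating
them as independent, which they are by construction here. A joint
multivariate fit could share information across series but would entangle
the per-series fluctuation estimates; independence keeps the estimand
clean and is the reading implemented.

## 3. SCR feature extraction

Raw electrodermal traces (250 Hz, microsiemens) are decimated to 25 Hz
with an anti-aliased moving average and high-pass filtered with a
zero-phase 2nd-order Butterworth filter. Two numerical findings shaped the
defaults, both measured on the package's own kernel (tests reproduce
them):

- **Cutoff 0.02 Hz.** SCRs occupy roughly 0.03–1 Hz. At a 0.05 Hz cutoff
  the filtered kernel's apparent half-recovery shortens by ~0.15 s and its
  amplitude drops ~6%; at 0.02 Hz all three features stay within two
  samples / a few percent of the analytic kernel while linear drift is
  still annihilated. The 1.0 Hz hardware high-pass sometimes quoted for
  acquisition amplifiers would destroy SCR morphology entirely and is
  treated as an acquisition description, not an analysis step.
- **Edge padding and rebound handling.** Zero-phase filtering at these
  cutoffs has edge transients spanning tens of seconds, so the signal is
  reflect-padded by one filter time constant before filtering. The filter
  also produces a slow positive rebound after each response (undershoot
  recovery); a maximum rise-time criterion (default 8 s — real SCRs rise
  in well under 5 s) rejects these, and the onset of each event is placed
  at the start of its steep rise (last sample below 25% of the event's
  maximal slope) rather than at the raw local minimum, which baseline
  recovery can drag far ahead of the response.

Detection then finds local maxima rising at least `min_amplitude` (default
0.01 microsiemens, a common non-specific SCR criterion; the original
detector's threshold is not stated anywhere authoritative) above their
onset. Amplitude is peak minus onset level; rise time onset-to-peak;
half-recovery the first time after the peak the signal falls to onset
level plus half the amplitude, searched until the next event's onset and
missing if not reached — events whose recovery is cut short by a successor
contribute to counts and amplitudes but not to recovery means. Light
pre-smoothing (120 ms) suppresses noise micro-peaks on realistic traces
and can be disabled for near-noiseless data.

Rules applied downstream, following the study's analysis recipe: events
with onset strictly before 10 s are excluded (boundary kept — "occurred
for less than 10 s" is read as onset-based); each raw measure is pooled
across the whole dataset, values outside mean ± 3 pooled SD are trimmed,
and the rest are natural-log transformed; per-second counts use half-open
1-s bins over [10 s, 120 s), giving the 110-point count series. Trimming
pools across all participants, videos and conditions (per-measure) — the
recipe is silent on the pool, and dataset-wide pooling avoids
condition-dependent trimming thresholds that would bias contrasts.

## 4. Pupil preprocessing

Samples that are missing, non-positive, or adjacent to diameter changes
faster than 10 mm/s are masked, with 50 ms padding on each side (blink
on/offsets distort the signal beyond the dropout). A participant is
excluded from *all* analyses when any video's masked fraction exceeds
10% — participant-level exclusion matches how the original cohort was
trimmed. Gaps are filled by linear interpolation (monotone and
artifact-free even for long gaps, unlike cubic alternatives), the trace is
smoothed with a 100-ms centered moving average (edges shrink the window),
and the 1-Hz analysis series takes within-bin means over half-open
1-second bins. "Moving averages per second" is thus read as a binned 1-Hz
summary rather than a rolling mean — the two differ only in edge behaviour
on this grid, and the binned version makes series lengths exact (120/110)
by construction.

## 5. Hierarchical mean comparisons

Per-trial outcomes (SCR count, mean log amplitude / rise / half-recovery,
mean pupil, mean joystick, ratings) are compared across conditions with

$$y_{pv} = x_{pv}'\beta + u_p + e_{pv}, \quad u_p \sim N(0, \tau^2), \quad
e_{pv} \sim N(0, \sigma^2),$$

with contrast coding awe $= (2/3, -1/3, -1/3)$ and amusement
$= (-1/3, 2/3, -1/3)$, centered temperature and humidity as
participant-constant covariates, and model variants adding (a) amusement
and fear ratings, (b) contrast x presentation-order interactions (first
$-1/2$, second $+1/2$), or (c) centered age and gender ($\pm 1/2$; the
coding is the package's choice, the recipe does not state one) with
awe-contrast interactions.

**A note on the estimand.** With *both* contrast columns in the model the
awe coefficient is algebraically the awe-minus-*neutral* mean difference,
not awe minus the average of the others; the single-contrast model gives
the awe-versus-others difference. Both are exposed (`contrasts = "both"`
is the default, matching the published model; `"awe"` gives the
versus-others estimand), and the balanced-design recovery checks use the
single-contrast form, whose closed-form estimand
($4 - (2+1)/2 = 2.5$ for true means $4, 2, 1$) makes the oracle exact.

Sampling is a blocked Gibbs sampler: conjugate multivariate-normal updates
for $\beta$ and the random intercepts, slice-sampler updates for
$\log\tau$ and $\log\sigma$ under half-Normal$(0, 2.5\,\mathrm{sd}(y))$
priors, $\beta \sim N(0, (10\,\mathrm{sd}(y))^2)$, plus a recentering move
along the $(\beta_0 + c,\ u - c)$ ridge drawn from its full conditional,
which removes the intercept/random-mean autocorrelation that otherwise
dominates mixing. In the balanced covariate-free case the posterior means
agree with the frequentist mixed-model estimates (lme4 is the cross-check
in the tests). Significance is "95% equal-tailed CI excludes zero"
throughout.

**Missing SCR cells** (a participant x video with no detected events has
no amplitude/rise/recovery) are handled by chained-equations multiple
imputation: each incomplete variable is visited in turn, its Bayesian
normal linear imputation model's coefficients and residual SD are drawn
from their posterior given the currently completed data (flat prior,
draw-then-predict), and missing entries are drawn from the predictive
distribution; 10 cycles per imputation, $m = 100$ data sets by default.
Analyses are pooled by stacking posterior draws across imputations, so the
pooled posterior carries both within- and between-imputation uncertainty;
with nothing missing the procedure reduces exactly to the complete-data
analysis. Per-condition regressions (outcome-on-outcome associations
within the awe condition, for instance) use the same machinery without the
random intercept.

## 6. The synthetic-data generator

The generator's defaults *are* the study conditions: 77 participants, six
2-minute videos (two per condition), EDA at 250 Hz, pupil at 120 fps,
joystick at 60 Hz. Where the study reports a condition mean, the default
is calibrated to it once:

| quantity | neutral | amusement | awe | source of calibration |
|---|---|---|---|---|
| SCR count / video (110 s) | 0.91 | 1.68 | 2.38 | event rates 0.50 / 0.92 / 1.30 per min |
| mean log SCR amplitude | −0.79 | −0.70 | −0.61 | log-normal amplitude meanlog |
| pupil baseline (mm) | 3.41 | 3.93 | 3.54 | trend start value |
| pupil $\sigma_\zeta$ (mm) | 0.015 | 0.02 | 0.07 | implies $\sigma_{dif}(\text{awe})\approx 0.05$, $\sigma_{dif}(\text{amus})\approx -0.02$ |
| joystick plateau | 0.03 | 0.04 | 0.19 | plateau level |
| ratings (6 scales + fear) | — | — | — | reported means per scale |

Within-condition SDs are *not* reported anywhere and are the package's own
choices, fixed once at field-realistic values: rating SD 1.0 with
participant random intercepts of SD 0.5, EDA noise 0.01 microsiemens with
tonic drift 0.001/s and a slow random walk, pupil noise 0.01 mm, joystick
jitter 0.01, blinks at 6/min lasting 100–400 ms, lab temperature
N(24, 1.5) degC and humidity N(50, 8)%.

Structural choices: SCR events are a Poisson process with
condition-dependent rate; the awe videos additionally get 3x rate bursts
in "scene-opening" windows (90–110 s in the first awe video, 10–30 s in
the second), with the baseline rescaled so the expected total count is
unchanged. The SCR kernel is bi-exponential,
$K(t) \propto e^{-t/\tau_d} - e^{-t/\tau_r}$ with $\tau_r = 0.75$ s,
$\tau_d = 2.5$ s, normalized to unit peak — physiologically typical and
analytically tractable (peak time and half-decay have closed forms used as
test oracles). Ratings are truncated-normal on 1–7. One master seed
derives per-participant x video x signal sub-seeds deterministically, so
sessions are byte-reproducible.

**One deliberate mismatch.** The pupil trend generator damps the slope
($\mu_t = \mu_{t-1} + \phi(\mu_{t-1} - \mu_{t-2}) + \zeta_t$ with
$\phi = 0.7$): an undamped integrated random walk at awe-level
$\sigma_\zeta$ wanders by tens of millimetres over two minutes, which no
pupil does. Damping keeps diameters physiologically bounded while
$\sigma_\zeta$ still controls fluctuation; the cost is that the fitted
(undamped) model sees a slightly inflated per-participant $\sigma_\zeta$
(the second-difference variance is $2/(1+\phi)$ times nominal) and group
averaging across $n$ participants shrinks it by $\sqrt{n}$. Recovery
checks that need the exact model therefore use `generate_trend_series()`
(the undamped twin, $\phi = 1$), while end-to-end checks assert the
*ordering and significance* of condition differences, which damping and
averaging preserve. What passing synthetic tests do **not** show: realism
of luminance responses, gaze-dependent artifacts, non-Gaussian rating
distributions, or serial dependence of SCR events — none of which the
detection and modelling stages rely on.

## 7. Numerical choices and degenerate inputs

- Kalman-filter likelihoods are computed on the standardized series; the
  approximately-diffuse initialization contributes a near-constant term
  that cancels in Metropolis ratios.
- $\log\sigma$ parameters are hard-bounded at $[e^{-16}, e^{7}]$ on the
  standardized scale; a constant (or exactly quadratic) series then
  concentrates $\sigma_\zeta$ near its floor instead of degenerating.
- Trimming with zero pooled SD (all values identical) trims nothing.
- An empty trace yields an empty event list; a trace with no valid pupil
  samples is rejected with a message rather than interpolated from
  nothing.
- Ties at signal plateaus: the first sample of a maximal plateau is the
  peak (plateau slopes count as rising).
- Written session tables carry 17 significant digits so a round trip
  through disk reproduces downstream MCMC bit-for-bit.
- R-hat with a single chain is split R-hat (the chain's halves are
  compared); this convention is stated in the diagnostics documentation.

## 8. Problem sizes used by the validation suite

The test suite and acceptance script size their simulations for a desk
run: 20 replicate series per $\sigma_\zeta \in \{0.005, 0.02, 0.05\}$ at
$T = 120$ for coverage (the package's own study-scale grid), $T = 10{,}000$
for the second-difference variance identity, 20 single-event plus 10
multi-event low-noise traces for detector accuracy, 20 participants for
balanced contrast recovery, and a 12-participant cohort with awe
$\sigma_\zeta = 3\times$ the others for the end-to-end discrimination
check. These sizes are the package's validation design, chosen so each
oracle is sharp at the stated tolerances; `--paper` scale sampling and the
full 77-participant default remain available through the same interfaces.

## 9. Known limitations

- The trend model assumes Gaussian observation noise; SCR count series are
  averages of small counts and only approximately Gaussian (group
  averaging across participants is what makes this workable).
- Fluctuation is a single per-series parameter; within-video *timing* of
  fluctuation changes is visible in the smoothed trend but not modelled.
- The imputation engine assumes approximately linear relations among the
  analysis variables with Gaussian errors — adequate for the SCR feature
  block it is used on, not a general-purpose imputer.
- Reproduction of the original study's numbers requires its deposited
  recordings reshaped to the documented table schema (`read_session()`);
  the package validates the machinery on synthetic sessions written in
  that schema.
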