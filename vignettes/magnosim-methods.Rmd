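---
title: "Simulating magnocellular training studies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating magnocellular training studies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magnosim)
```

`magnosim` simulates the computational skeleton of a two-group
longitudinal intervention study on visual magnocellular function in
children with reading difficulties: an adaptive coherent-motion threshold
test, the training-task engines, a synthetic cohort shaped like the study
design, and the mixed repeated-measures analysis applied to it. This
vignette explains the models, the tunable parameters and their defaults,
the numerical choices, and what the simulations can and cannot show.

## The weighted up-down staircase

The coherent-motion test presents two panels of moving dots; one contains
a proportion of coherently moving signal dots, the other only noise, and
the child reports which side looks coherent (two-alternative forced
choice, chance = 50%). Task difficulty lives on a dB attenuation scale
relative to full coherence. We use the amplitude convention

$$\text{coherence} = 100 \cdot 10^{-A/20},$$

so 0 dB is 100% coherence and 20 dB is 10%. The convention itself is a
free choice: every headline property below (in particular the 75%
equilibrium) is invariant to it, so we adopt the common psychophysical
amplitude form and expose both directions
(`attenuation_to_coherence()`, `coherence_to_attenuation()`).

After each correct answer the attenuation increases by `down_step_db`
(default 1 dB; the task gets harder), after each wrong answer it
decreases by `up_step_db` (default 3 dB; easier), clamped to
`[0, 40]` dB. A *reversal* is a change in the direction of the applied
step; the run stops at `stop_reversals = 8` reversals, with a
`max_trials = 500` safety cap because a simulated responder, unlike a
supervised child, can wander indefinitely. A step that is clamped at a
bound still counts in its attempted direction for reversal bookkeeping,
which preserves reversal semantics at the boundary.

For a weighted up-down rule the track drifts towards the level where the
expected step is zero:

$$p \cdot d = (1 - p) \cdot u \quad\Rightarrow\quad p = \frac{u}{u + d},$$

which for $d = 1$, $u = 3$ gives $p = 0.75$: the staircase equilibrates at
the observer's 75%-correct coherence, which is exactly how the threshold
is defined. The test suite measures this by running long staircases and
taking the fraction of correct responses after the track has settled; the
same zero-drift argument shows this fraction must approach
$u/(u+d)$ regardless of the observer's psychometric shape.

### Threshold estimation

The threshold estimator averages reversal levels. Two choices matter and
both are deliberate:

- **Averaging happens on the dB scale** (the scale the staircase steps
  on), and the mean attenuation is converted to coherence afterwards.
  Averaging coherences directly is biased upwards by convexity: the track
  oscillates symmetrically in dB, not in percent.
- **The first half of the reversals is discarded.** The track starts at
  0 dB (full coherence — giving children initial successes), so the early
  reversals still carry the approach to equilibrium; for a typical
  threshold near 10 dB the track is still drifting at the fourth
  reversal. Keeping the settled, even-count tail (reversals 5–8 of 8)
  removes most of that transient.

With these choices the mean estimate over 200+ runs is within ~3% of the
true 75% point for an observer at the cohort's baseline threshold (45%
coherence) and within ~10% at 30%. A single 8-reversal track remains
noisy (SD around 15 percentage points); that is a property of the short
clinical protocol, not of the estimator, and it is why the cohort
generator treats a staircase-produced threshold as a noisy measurement of
the latent sensitivity.

## Observers

`psychometric_observer()` is the closed-form participant: a Weibull
psychometric function under 2AFC,

$$p(c) = 0.5 + (0.5 - \lambda)\left(1 - e^{-(c/\tilde\alpha)^\beta}\right),$$

with the scale $\tilde\alpha$ solved analytically from
$(\alpha_{75}, \beta, \lambda)$ so that $p(\alpha_{75}) = 0.75$ holds
exactly. The anchor is the contract; the Weibull family is convention.
Defaults $\beta = 2$ and $\lambda = 0.02$ are typical for child coherence
psychophysics; the lapse is capped at 0.06 so the 75% point always
exists.

`mechanistic_observer()` assumes no psychometric function. It perturbs
every perceived dot heading with $\mathcal N(0, \sigma^2)$ angular noise
and picks the panel with the larger mean resultant length of displacement
unit vectors; ties fall to a fair coin. Its accuracy-versus-coherence
curve *emerges* from the stimulus, and `calibrate_alpha75()` measures its
75% point by Monte-Carlo bisection. One consequence worth noting: even a
noiseless resultant-vector observer has a nonzero threshold, because one
signal dot among $n$ noise dots shifts the pooled resultant by $\sim 1/n$
while the statistic's own sampling noise scales as $\sim n^{-1/2}$.
Perfect performance at a single signal dot would require a
dot-correspondence strategy this observer deliberately does not have.

## RDK stimulus

`generate_rdk_trial()` builds both panels: positions uniform in the unit
square, toroidal wrap (origin top-left, x rightward, y downward), and per
frame-step exactly `round_half_up(coherence/100 × n_dots)` signal dots in
the signal panel, re-drawn at random every step so no single dot can be
tracked across frames. Noise headings are independent uniform on the
circle. Dot count (100/panel), frame count (20) and step size are
declared defaults — the original protocol does not report them — and all
are configurable. No rendering is done; `rdk_trial_to_df()` exports the
geometry for plotting.

## Training-task engines

- **Digit counting** (`run_digit_session()`): 10 levels; presentation
  time interpolates linearly from 560 ms (level 1) to 190 ms (level 10)
  — only the endpoints are prescribed, and linearity is the simplest
  monotone rule (swappable in principle). Level moves +1 on a correct
  answer (capped at 10), −1 on a wrong one (floored at 1; the protocol
  does not say whether regression can pass below the first level, so the
  floor is assumed), and the session stops at 4 cumulative mistakes. Font
  size is metadata only: no quantitative sizes are reported.
- **Dot counting** (`run_dot_session()`): level 1 shows 9 dots in 9 s
  (the task's 7–9 range anchored at its top, making the level-1 interval
  exactly 1 s); each level adds 2 dots and multiplies the inter-dot
  interval by 0.75. Blocks of 10 trials make the 80% advancement
  criterion the integer 8/10. The 9 s window is treated as the total
  presentation time divided among the dots.
- **Feedback RDK** (`run_rdk_training()`): identical staircase dynamics
  with a per-trial feedback flag; stops after 4 cumulative wrong choices.
- **Saccade cycles** (`count_cycles()`): a left saccade followed by the
  next right saccade is one cycle; pairing is strict consumption (a
  second left does not stack, a trailing unmatched left is not a cycle),
  and the score is cycles per minute.

## The synthetic cohort

`generate_cohort()` draws 13 experimental and 11 control boys (ages
truncated-normal, mean 9.76, SD 0.59, range 9–11) across four sessions
(pre, mid-training, post-training, one-month follow-up) and seven
measures. Per measure, child $i$ in group $g$ at session $s$ has

$$y_{is} = \mu_{g}(s) + b_i + \varepsilon_{is},\qquad
b_i \sim \mathcal N(0, \sigma_B^2),\ \varepsilon_{is} \sim \mathcal N(0, \sigma_W^2),$$

i.e. a compound-symmetric within-child covariance — which is why the
sphericity machinery sees near-spherical data under the defaults.
Error-count measures use the same latent mean as a Poisson rate (floored
at 0.05). Both groups share baseline distributions (the design is
matched); the only systematic group difference is the trajectory.

The default `effects = "study"` configuration is a **scenario, not
data**: baselines are plausible values consistent with the inclusion
screen (RDK 45%, reading accuracy 60 points, 80 saccade cycles/min), and
the experimental group's session shifts equal the study's printed
within-group mean changes (RDK −14.15/−18.39/−17.08; saccades
+42.08/+58.23/+60.77; accuracy +13.58/+20.07/+21.82; comprehension
+5.77/+14.54/+17.25, with controls improving almost as much on
comprehension — the one measure where both groups moved together).
Between/within SDs were chosen once so that the between-group t
statistics at mid-test are of the same order as those printed (e.g. an
RDK group difference of ~14 points against a per-group SD of ~7).
`effects = "null"` flattens every trajectory for type-I-error
calibration.

`rdk_mode = "mechanistic"` replaces the direct Normal draw of each RDK
threshold with an actual staircase run against a psychometric observer
whose 75% point is the child-session latent value, so the measurement
noise is the staircase's own. The two modes agree in expectation up to
the estimator's small bias.

What the generator does **not** emulate: reading-test item content and
linguistic error coding, learning-to-the-test effects from repeated
identical texts, examiner unblinding, dropout, and any correlation
between measures beyond the shared group trajectories. Passing tests
therefore validate the *machinery* (the staircase targets 75%, the ANOVA
decomposes exactly, the interaction test holds its size, the scenario's
power pattern matches the qualitative published pattern); they say
nothing about real children.

`screen_inclusion()` applies the study's strict baseline cut-offs
(reading score `< 71`, RDK threshold `> 34`); both inequalities are
strict because the criteria are worded as "below" and "above".

## Mixed repeated-measures ANOVA

`mixed_anova()` computes the classical split-plot decomposition from
group-mean projections:

- between-subjects stratum: $SS_{group}$ (df $g-1$) tested against
  $SS_{subj(group)}$ (df $N-g$);
- within-subjects stratum: $SS_{session}$ (df $k-1$) and
  $SS_{group\times session}$ (df $(g-1)(k-1)$) tested against
  $SS_{session\times subj(group)}$ (df $(k-1)(N-g)$).

Sums of squares always add to $SS_{total}$ (tested to machine
precision), and each effect's partial eta squared is
$SS_{effect}/(SS_{effect}+SS_{error})$, equivalently
$F\,df_1/(F\,df_1+df_2)$ — the identity the package also exposes as
`partial_eta_sq_from_f()` for recovering effect sizes from printed
statistics.

Sphericity is assessed on the pooled within-group covariance of the
repeated measures, projected onto an orthonormal contrast basis $C$:
$S_c = C^\top S C$ with $S$ estimated on $N - g$ error df. Mauchly's
$W = \det S_c / (\operatorname{tr} S_c/(k-1))^{k-1}$ uses the standard
chi-square approximation with multiplier
$n' - (2p^2+p+2)/(6p)$, $p = k-1$, $n' = N-g$; Greenhouse–Geisser
$\hat\epsilon = \operatorname{tr}(S_c)^2/((k-1)\operatorname{tr}(S_c^2))$
is bounded in $[1/(k-1), 1]$ and multiplies both within-subject dfs.
Degenerate inputs (singular contrast covariance, $n' < k-1$) raise
errors rather than silently producing numbers, and with $k = 2$
sphericity holds trivially ($W = 1$).

**Correction policy.** The protocol's own wording on when the correction
was applied is internally inconsistent with its reported fractional dfs
(which show corrections in use), so the package makes the standard policy
explicit and configurable: when Mauchly's p falls below
`sphericity_alpha` (default 0.05) the reported p-values use the
ε-corrected dfs; both corrected and uncorrected p-values are always
present in the output table.

Follow-up tests: paired t within groups (`pairwise_within()`, reporting
first-minus-second mean differences, unadjusted and Bonferroni-adjusted
p); pooled-variance independent t (`independent_t()`) — pooled, not
Welch, so 13 + 11 children give the design's df = 22; and Mann–Whitney U
(`mann_whitney_u()`), exact by full enumeration of the rank distribution
for small tie-free samples and a tie-corrected normal approximation
otherwise. Degenerate zero-variance cases report their edge values
($t = \pm\infty$, $p = 0$ or $t = 0$, $p = 1$) explicitly.

## Reproducibility and problem sizes

Every stochastic entry point takes a `seed`; seeding is implemented so
the caller's RNG stream is saved and restored, and the pipeline derives
per-stage seeds from the master seed through named streams
(`seed_stream()`), so adding a stage never perturbs existing ones. Fixed
seed implies byte-identical CSV/JSON artifacts.

The package's simulation-based checks use deliberately moderate sizes —
200–500 staircases or simulated cohorts per property, 2,000–5,000
Monte-Carlo trials per probed coherence, small dot panels in
mechanistic-observer tests — chosen so each property's Monte-Carlo error
is several times smaller than the tolerance it is tested against while
the whole suite stays fast enough to run routinely.

## Known limitations

- The staircase estimator retains a small positive bias (a few percent of
  the true threshold) that grows for very sensitive observers with
  shallow psychometric slopes; an 8-reversal track is simply short.
- The mechanistic observer's resultant-vector statistic is one of many
  plausible motion-integration rules; its calibrated thresholds depend on
  panel size and frame count and are not comparable across stimulus
  configurations.
- The cohort scenario encodes published group-level changes as fixed
  trajectory shifts; it cannot, and does not try to, recover
  individual-level treatment-effect heterogeneity.
- Only Greenhouse–Geisser ε is implemented (no Huynh–Feldt), matching the
  analysis it mirrors.
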