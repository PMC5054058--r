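---
title: "Detecting additional HRV reductions: model, conventions, and what the synthetic tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting additional HRV reductions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(addhrvr)
```

## The model

Vagally mediated heart rate variability, indexed here by RMSSD over 30-s
epochs of interbeat intervals, falls with rising metabolic demand. To tell
metabolically expected reductions apart from *additional* ones, the
detector fits, per person, an inverse calibration model over a scripted
activity session:

$$\mathrm{E}[\mathrm{RMSSD}_j] = b_0 + \frac{b_1}{\mathrm{Acceleration}_j}$$

where acceleration is the 30-s mean movement magnitude in g. The model is
linear in the transformed predictor $x_j = 1/\max(a_j, a_{\min})$ and is
fitted by ordinary least squares. An ambulatory epoch is flagged when its
actual RMSSD lies strictly below the expectation minus $k$ error units:

$$\mathrm{RMSSD}_j < b_0 + b_1 x_j - k \cdot SE,$$

and an *AddHRVr episode* is a maximal run of at least `min_run`
consecutive flagged epochs. With the defaults (30-s epochs, `min_run = 15`)
an episode is at least 7.5 minutes of continuous suppression — long enough
to exclude transient orienting responses and isolated noisy epochs.

Assumptions worth stating plainly:

* within a person, movement is the dominant determinant of expected RMSSD
  over the day, and the calibration session spans the relevant movement
  range (sedentary through stair climbing);
* the inverse form is adequate — it is checked per person via the
  explained-variance gate rather than assumed;
* posture, respiration and circadian effects are not modelled; they end up
  in the residual noise and are one reason thresholds are person-specific
  and conservative (2 error units plus a 7.5-min persistence criterion).

One published description of the threshold prints it as "Actual RMSSD −
2 × SE". Taken literally that would flag *every* epoch (every value is
below itself plus noise); the surrounding definition — actual RMSSD two
times the SE below the *expected* level — fixes the intent, and this
package implements `threshold = expected − k × SE`.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `epoch_length` | 30 | s | epoch grid for RMSSD and acceleration |
| `k` | 2 | error units | threshold depth below expectation |
| `min_run` | 15 | epochs | minimum episode length (7.5 min) |
| `accel_floor` | 0.005 | g | predictor floor before inversion |
| `error_quantity` | `"sem"` | — | definition of SE (see below) |
| `max_gap` | 0 | epochs | invalid/unflagged epochs bridgeable inside a run |
| `hour_attribution` | `"overlap"` | — | which hours an episode credits |
| `ibi_min`, `ibi_max` | 300, 2000 | ms | physiological IBI bounds |
| `max_rel_diff` | 0.30 | — | max relative jump between retained IBIs |
| `min_epoch_coverage` | 0.8 | — | retained-IBI time needed per epoch |
| `min_beats_per_epoch` | 10 | beats | beats needed per epoch |

**The error quantity.** The default follows the method's wording exactly:
SE is the standard error of the mean of calibration RMSSD,
$sd/\sqrt{n}$. Note what this implies: the quantity shrinks with session
length, so a long calibration yields a threshold hugging the expectation
and, with realistic epoch-to-epoch RMSSD noise (several ms), isolated
epochs will cross it often while 15-epoch runs remain rare. Because the
wording plausibly understates what was intended, `error_quantity` can be
switched to `"sd"` (the calibration RMSSD standard deviation) or
`"residual_se"` (the regression residual standard error) for sensitivity
analyses; all downstream arithmetic is unchanged.

**The acceleration floor.** The inverse predictor is unbounded as
movement approaches zero, and truly zero acceleration is common in
sedentary epochs. Flooring at 0.005 g (an order of magnitude below typical
sedentary means of 0.05–0.06 g) caps the expected RMSSD at
`b0 + b1/0.005` without affecting epochs with measurable movement.

**Exclusion gates.** A calibration is unusable when explained variance is
below 25 %, the movement–RMSSD relation is not significant (two-sided
t-test on $b_1$, $\alpha = 0.05$), or the curve is not inverse
($b_1 \le 0$, or no variance in the transformed predictor). Gates are
checked in that order; a perfectly flat response (undefined $R^2$ and
p-value) is classified as no-relation rather than low-variance. Exclusions
are data, not errors: they are recorded in the model table, and detection
refuses to run on an excluded model.

## Numerical conventions

* **Half-open windows everywhere.** Epochs are $[t, t+30)$, phases and
  hours likewise; a sample belongs to exactly one window, so nothing is
  double-counted at boundaries.
* **Strict inequality at the threshold.** An epoch equal to the threshold
  is not flagged. Ties are measure-zero on real data but the convention
  must be fixed for the generator's exact-depth plants (below).
* **Missing breaks runs.** An invalid epoch (artifact-dominated, too few
  beats, no acceleration) has a missing flag and terminates any run;
  continuity is never fabricated across gaps unless `max_gap > 0` is set
  explicitly, in which case bridged epochs count toward the episode span
  but an episode still starts and ends on flagged epochs.
* **Maximal runs.** A 40-epoch run is one episode, not 26 overlapping
  15-epoch windows.
* **Hour attribution.** By default an episode credits every hour its span
  intersects; `"completion"` credits only the hour containing the
  `min_run`-th epoch, i.e. where the criterion was first met. Boundary
  hours of a recording are coded like any other.
* **Missing values are never zero.** File formats encode missingness as
  empty fields; zero RMSSD and zero acceleration are meaningful values.
* **Artifact rule.** The conventional range (300–2000 ms) plus
  relative-jump (30 % against the previous retained beat) rule, applied in
  a single forward pass, marking rather than deleting samples so epoch
  coverage stays computable. The pass is idempotent. Devices with their own
  artifact handling can pass marks through the `valid` column.

## The synthetic world

The generator emulates the regime ambulatory calibration studies report:
population law `Expected RMSSD = 21.56 + 0.471 / acceleration` (person
coefficients drawn around it, SD 3 ms and 0.1 ms·g), Gaussian epoch noise
of 5 ms, calibration acceleration ranges per phase spanning roughly
0.01–0.4 g so calibration means land near 45 ms RMSSD and 0.05–0.1 g,
12-h days with a two-state quiet/bout movement process (per-epoch bout
start probability 0.02, mean bout 3 min, intensities 0.1–0.4 g), worry
reports on ~16 % and stress reports on ~7 % of hours.

**Plants.** Ground-truth suppression windows pin RMSSD at exactly
`depth × SE` below the generating law, with epoch noise suppressed inside
the window. This makes depth exact in the detector's own units: a depth-`k`
plant sits exactly at the threshold (and by the strict-inequality rule is
*not* flagged), depth above `k` is flagged up to fit error, and power
against a 20-epoch depth-4 plant is essentially the probability that the
fitted calibration is accurate — measured at ≥ 95 % over 200 seeded
replicates in the acceptance suite. Had noise been left additive inside
plants, depth would lose its threshold interpretation: per-epoch flag
probability would be $\Phi((\mathrm{depth}-k)\,SE/\sigma)$ (about 0.8 at
default settings) and a 15-of-20 consecutive run would be a rare event, so
no realistic noise level could meet a high-power criterion. The
deterministic plant is the semantics under which the depth parameter means
what it says.

**Exposure variation.** Each planned plant is instantiated per person with
probability `plant_prob` (default 0.6). With the default two-plant plan
this leaves ~16 % of persons with no plant and a mean near 2
plant-affected hours per person — matching the reported regime in which a
quarter of participants never showed an episode and the mean was 2 flagged
hours. Setting `plant_prob = 1` (as the power tests do) guarantees every
plant.

**What the generator does *not* emulate:** posture changes and respiratory
influences on RMSSD at constant movement; circadian drift; autocorrelated
movement beyond bout structure; device-specific artifact patterns (day
epochs are all valid unless `invalid_prob > 0`); real plants are not
rectangular. A green synthetic suite establishes that the *pipeline
arithmetic* is right — calibration recovery, thresholding, run detection,
hour coding, decomposition — not that the method separates stress from
confounds in real data.

**False-positive regression value.** With no plants, default noise and
`k = 2`, the hour-level false-positive rate is frozen at exactly 0: a
chance run of 15 consecutive sub-threshold epochs has probability around
$0.2^{15}$ per position, i.e. never at study scale. This is a regression
anchor, not a claim about real data, where autocorrelated confounds (e.g.
sustained quiet sitting after exercise) can produce genuine long runs.

## Design choices where the design was open

* **Decomposition variable.** The within/between split defaults to the 0/1
  hour code, matching the binary independent variable used in the
  hour-level models; hourly episode counts are available via
  `value = "n_episodes"` since summaries of "the number of episodes" can be
  read either way.
* **All session phases enter the fit.** Whether variable-duration stair
  epochs were part of the original fits is unstated; excluding them would
  discard exactly the high-movement epochs that identify $b_1$.
* **Minimum six valid epochs to fit** (two parameters plus degrees of
  freedom for the t-test); real sessions yield ~30.
* **12-h default day** (an hourly prompting window such as 10:00–22:00)
  rather than 24 h: detection across sleep involves posture and circadian
  effects the calibration does not cover, and hourly self-reports only
  exist in the waking window.
* **File dialect.** Plain CSV with seconds-from-start timestamps; no
  attempt to mimic any proprietary sensor container, keeping the tool
  device-agnostic. Epoch tables can come from any source that provides
  30-s RMSSD and mean acceleration.

## Known limitations

* The SEM-based default threshold depends on calibration length; compare
  persons only under a common protocol, or switch `error_quantity`.
* With large error quantities (`"sd"`) the threshold can go negative at
  high movement, where no epoch can be flagged — RMSSD cannot be negative.
  This is a property of the method, not of the implementation.
* Single inverse law per person: no time-of-day or posture terms.
* Pearson summaries are given for person-level aggregates only; hour-level
  inference should use a mixed model on the decomposition output, which is
  written in a directly consumable long format.
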