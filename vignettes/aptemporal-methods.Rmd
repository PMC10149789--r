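---
title: "Models and methods behind aptemporal"
author: "aptemporal authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aptemporal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptemporal)
```

aptemporal implements, end to end, the measurement and inference chain of a
two-experiment psychoacoustic design relating absolute pitch (AP) — the
ability to name a musical pitch without a reference — to two aspects of
auditory temporal processing: temporal resolution (gap detection in noise)
and backward masking (tone detectability before a trailing masker). This
vignette explains the models, the rules, the tunable parameters, and the
design decisions taken where the published procedures leave choices open.

## Test protocols

**Pitch identification, sine variant.** 13 sine tones spanning F#3–F#4
(MIDI 54–66), each presented four times (52 trials, 2 s inter-tone
interval, 50 dB SL), ordered so that a stimulus is presented again only
after all 12 other stimuli have been presented since its previous
occurrence. That rule is stricter than it looks. Write the four occurrence
positions of stimulus $s$ as $p_1(s) < \dots < p_4(s)$; the rule forces
$p_{i+1}(s) - p_i(s) \ge 13$, so $p_4(s) - p_1(s) \ge 39$ for every $s$.
Summing over the 13 stimuli, $\sum_s p_4(s) \le 40 + 41 + \dots + 52 = 598$
and $\sum_s p_1(s) \ge 1 + \dots + 13 = 91$, so
$\sum_s (p_4(s) - p_1(s)) \le 507 = 13 \times 39$: every inequality is an
equality. The only admissible 52-trial sequences are therefore a single
permutation of the 13 stimuli repeated four times, and that is how
`build_pitch_id_protocol("exp1_sine52")` constructs them (uniformly random
permutation, deterministic under the seed). Constructions that concatenate
independent random block permutations violate the rule whenever a stimulus
falls late in one block and early in the next.

**Pitch identification, piano variant.** 36 synthetic piano tones C3–B5,
each presented twice in six blocks of 12 (72 trials, 4.25 s interval),
with consecutive tones always more than one octave apart
($|\Delta \mathrm{MIDI}| \ge 13$) to suppress relative-pitch strategies.
The published description does not say whether the spacing constraint holds
across block boundaries; we enforce it across all 71 consecutive pairs (the
stricter reading costs nothing). Sequencing uses a randomized
most-constrained-first heuristic: among tones compatible with the previous
one, a tone with the fewest compatible partners remaining in the pool is
placed first (random tie-breaking), which prevents mid-range tones — whose
compatible set is smallest — from being stranded at the end. Dead ends
trigger a restart; exhausting the restart cap (default 1000) is an explicit
generation error, never a silent relaxation. Plain uniform greedy
sequencing dead-ends almost always, and unbounded backtracking is
needlessly slow; the heuristic succeeded in the first attempt in every run
we measured.

**Gaps-in-Noise (GIN).** Per ear, 6-second white-noise segments (35 for
track 1, 29 for track 3; 5 s between segments), each carrying 0–3 silent
gaps, 60 gaps in total divided evenly over durations
{2, 3, 4, 5, 6, 8, 10, 12, 15, 20} ms. The commercial test ships fixed
recorded tracks whose exact gap layout is not published; the generator
reproduces the statistical structure instead, assigning gaps to segments
uniformly at random subject to the 0–3 cap and drawing onsets uniformly
with two placement parameters chosen to keep gaps perceptually separable
and clear of segment edges: `min_gap_separation_ms = 500` (offset-to-onset)
and `edge_margin_ms = 300`. Both are arguments of `build_gin_track()`.

**Backward masking (BMT).** Per ear, a 25 ms tone (20 dB SL) followed by a
200 ms narrow-band masker at −20 dB signal-to-noise ratio, with
tone-to-masker intervals {0, 10, 20, 30, 50, 100, 200, 400} ms; six tone
trials per interval (48) plus 12 masker-only catch trials, in randomized
order per ear.

## Scoring rules

**Pitch.** Responses carry only the chroma label (12 classes), so
deviation is necessarily circular: `chroma_distance()` is
$\min(d, 12 - d)$ with $d = |a-b| \bmod 12$, at most 6 semitones (the
tritone). The correct response rate (CRR) counts only zero-deviation
responses; MAD is the mean circular distance in semitones. An octave error
is invisible to both measures by construction. Missing responses default to
"worst" scoring (incorrect, deviation 6), switchable to exclusion
(`none_policy = "exclude"`); the published procedure does not state a
policy, and worst-case scoring is the conservative choice for a
naming-out-loud task where silence is a failure to name.

**Thresholds (GDT, BMTT).** `threshold_from_counts()` implements the
4-of-6 rule. The published wording — the shortest level detected 4 of 6
times "with equal or higher detection rate" for easier levels — admits two
readings. The default, `maintained_criterion`, requires every easier level
to also meet the 4-of-6 criterion; this matches standard clinical gap
scoring. The literal reading, `maintained_rate`, requires every easier
level to meet the candidate's own rate and is available as an option. Both
are verified against brute-force re-application of the rule over the full
7^4 grid of a 4-level problem and 100,000 random 10-level count vectors.
When no level qualifies, the threshold is *censored*: represented as `NA`
plus an explicit flag, serialized as the token `"NA_censored"`, and never
imputed. Ear averaging propagates censoring (one censored ear censors the
average), and analyses exclude such subjects listwise with a logged count;
silent numeric imputation would bias simulated group statistics.

**GDP/BMTP and false alarms.** GDP is detections out of 60 gaps; BMTP is
presses out of 48 tone trials. Catch-trial presses are reported as a
false-alarm rate but do not correct GDP/BMTP — the published scoring uses
no false-alarm correction, and we follow it.

## Classification

A guessing subject's correct count on an $n$-trial, 12-alternative test is
Binomial$(n, 1/12)$. `chance_cutoff()` takes the upper limit of the
two-sided normal-approximation 99% interval on the count,
$np + z_{0.995}\sqrt{np(1-p)}$, and sets the cutoff at the smallest integer
strictly above it. For $n = 52$ this gives 10 correct (19.2%), matching the
published criterion exactly; an exact-binomial variant is provided but is
not the default because only the normal form reproduces the printed
cutoff. AP assignment requires CRR at or above the cutoff **and** MAD
below 1.00 semitone; subjects under 50% in the 13-trial training screening
are assigned Non-AP without testing. For the 72-trial piano variant the
published cutoff is "CRR ≥ 20%"; the same chance model gives 13/72 ≈ 18.1%,
and since the 20% figure is attributed to external convention rather than
the stated model, the pipeline applies 20% verbatim
(`cutoff_percent = 20`) rather than guessing at its derivation.

## Synthetic observers and cohorts

Simulated data make every stage testable with known ground truth. The
pitch namer is a wrapped-Gaussian-plus-guessing mixture: with probability
$\lambda$ a uniform guess over the 12 chromas, otherwise the target plus a
rounded $\mathcal N(0, \sigma^2)$ naming error wrapped onto the chroma
circle. Useful closed forms drive the tests: a pure guesser has
$E[\mathrm{CRR}] = 100/12 \approx 8.3\%$ and $E[\mathrm{MAD}] = 3$; a
non-guessing namer has $E[\mathrm{CRR}] = 100(2\Phi(0.5/\sigma) - 1)$.

Detectors are guess/lapse logistic observers,
$p(x) = \gamma + (1-\gamma-\delta)\,\mathrm{logit}^{-1}((x - x_{50})/\beta)$,
with per-segment Poisson false alarms (GIN) or per-catch-trial Bernoulli
presses (BMT). The logistic kernel is the simplest two-asymptote monotone
family; nothing downstream depends on its exact shape, and the tests that
matter (threshold recovery, monotonicity) hold for any monotone kernel.

`cohort_spec()` fixes the study conditions: group sizes 9/10 (experiment 1)
and 8/7 (experiment 2), covariates drawn Normal at the published means and
SDs (onset age truncated at 3 years, training at 1 year). Observer
parameters are the one genuinely free choice, since trial-level data are
not published; they were set once to land the simulated groups in the
published score regions and not revisited: AP namers
$\sigma \approx 0.3$–$0.35$ semitones, $\lambda \approx 0.02$–$0.03$
(mean CRR ≈ 82–88%, inside the published 61.5–100% range);
experiment-1 Non-AP observers guess uniformly ($\lambda = 1$), so they fail
the training screen as the published cohort did; experiment-2 Non-AP
observers mix $\sigma = 1.5$, $\lambda = 0.45$ (mean CRR ≈ 18%, published
19.4 ± 5.3%). Gap observers sit at $x_{50} = 4.3 \pm 0.7$ ms and masking
observers at $x_{50} = 20 \pm 7$ ms with no group difference, mirroring
the null group effects reported for both tasks (GDP ≈ 70%, GDT ≈ 5 ms,
BMTP ≈ 68%, near clinical norms for young normal-hearing adults).
`simulate_planted_cohort()` bypasses the observer layer and plants a known
linear dependence of CRR (and/or MAD) on GDT directly at the score level,
for recovery and null-calibration checks of the inference chain.

What the simulations do *not* emulate: learning and fatigue across trials,
ear asymmetries, examiner judgment in tap scoring (we use an idealized
per-gap Bernoulli outcome), and any acoustic-level masking mechanics.
Passing tests demonstrate that the scoring, classification and inference
machinery is correct and well calibrated — not that the psychological model
of real observers is right.

## Inference chain

Group comparisons use the pooled-variance t statistic
($\mathrm{df} = n_1 + n_2 - 2$) with Hedges'
$g = J\,|t|\sqrt{1/n_1 + 1/n_2}$, $J = 1 - 3/(4(n_1+n_2) - 9)$, reported as
a magnitude (the sign lives in the mean difference). Associations use
Pearson's $r$.

Interval estimation and p-values follow the bootstrap: case resampling
(rows; stratified by group for mean differences), $B = 2000$ by default,
bias-corrected and accelerated (BCa) intervals with $z_0$ from the
bootstrap fraction below the point estimate and acceleration $a$ from
jackknife skewness. The p-value inverts the interval: the smallest
$\alpha$ whose $(1-\alpha)$ interval excludes the null, found by bisection
(tolerance $10^{-4}$) over *one* fixed resample set, so the p-value and
the 95% interval can never disagree. Degenerate bootstrap distributions
collapse to a point interval with a warning; resamples on which the
statistic is undefined (e.g. a zero-variance correlation resample) are
dropped, shrinking the effective $B$. The smallest attainable p is $2/B$.
Empirical coverage for a Normal mean at $n = 20$ sits near 94% at nominal
95% (the suite checks the 92–98% band over 1000 replications).

Multiplicity is handled by Benjamini–Hochberg step-up adjustment within
pre-declared families mirroring the design's reporting blocks — the pair of
group tests, the four correlations, the four uncontrolled regressions, the
four controlled regressions — never inferred from the data. (BH adjustment
is not idempotent, a property sometimes wrongly assumed: (0.01, 0.5)
adjusts to (0.02, 0.5), which re-adjusts to (0.04, 0.5). The tests assert
monotonicity and agreement with `stats::p.adjust` instead.)

Robust regression is an M-estimator: ordinary least squares start,
residual scale fixed at the MAD of the starting residuals, then
iteratively reweighted least squares with Tukey-bisquare weights
($c = 4.685$, 95% Gaussian efficiency) to a $10^{-8}$ coefficient-change
tolerance (cap 200 iterations; non-convergence is an error carrying the
iteration trace). Robust $R^2$ uses the final weights,
$1 - \sum w e^2 / \sum w (y - \bar y_w)^2$; Cohen's
$f^2 = R^2/(1 - R^2)$ is computed from the *unadjusted* robust $R^2$ — the
only convention consistent with all eight published (variance %, $f^2$)
pairs. Coefficient covariance is the asymptotic M-estimator form with
Huber's small-sample correction; intervals and p-values are t-based on
$n - k$ degrees of freedom, and standardized $\beta = b\,s_x/s_y$.
Exact published coefficient values are not reproducible without the raw
data; the fidelity target is the estimator class, verified against an
independent bisquare implementation and by outlier-resistance and
clean-data-agreement properties.

The experiment-2 pipeline mirrors the published decision rule: when no
BH-adjusted correlation reaches 0.05, regressions are skipped and flagged
(`force_regressions = TRUE` overrides).

## Numerical and testing choices

* Everything stochastic is a pure function of (parameters, seed);
  generators restore the caller's RNG state.
* Problem sizes in the test suite: BCa coverage uses 1000 replications at
  $B = 2000$, $n = 20$; threshold-rule equivalence is exhaustive over the
  2401 vectors of a 4-level grid plus $10^5$ random 10-level vectors;
  parameter recovery uses 200 observers; planted/null recovery uses 100
  study-sized ($n = 9$) cohorts. The acceptance script uses 400 coverage
  replications and 20,000 random threshold vectors.
* The planted-slope band is $\pm 2$ standard errors with the SE taken from
  the case bootstrap ($B = 200$) of the robust slope: at $n = 9$ the
  asymptotic SE (ours and reference implementations alike) undercovers a
  2-SE band (~88–89% against the ~92% a perfectly estimated SE would
  give), while the bootstrap SE attains ~94%.
* The clean-data agreement check (robust vs OLS within $10^{-3}$ relative)
  uses noise SD 0.01 on a slope-2/intercept-1 line over $x \in [0, 10]$,
  $n = 200$: the robust-OLS coefficient gap scales with the noise SD, and
  at this level the expected relative gap (~3 × 10⁻⁴) is safely
  within the stated tolerance, so the check reflects the estimator property
  rather than one draw.
* Known limitations: censored thresholds make group means undefined rather
  than biased (subjects are dropped with a message); the chance model is a
  normal approximation (the exact variant is one argument away); BCa
  intervals at $n = 9$ undercover slightly, as all bootstrap intervals do
  at that size; and the GIN generator models the commercial tracks'
  statistics, not their fixed layouts.
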