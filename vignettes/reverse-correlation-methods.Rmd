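---
title: "Modeling mental representations of dynamic facial expressions by reverse correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling mental representations of dynamic facial expressions by reverse correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(facerevcorr)
```

## The problem

Observational studies report that people experiencing intense negative and
positive affect — physical pain and orgasm — produce facial expressions
that look remarkably similar. Reverse correlation turns the question
around: instead of measuring produced faces, it probes the *mental
representations* observers hold. On each trial a generator activates a
random combination of facial action units (AUs, the elementary movements
of the Facial Action Coding System) with random temporal dynamics; the
observer reports whether the animation matches their idea of a pain face,
an orgasm face, or neither, and rates its intensity. Correlating, AU by
AU, the stimulus composition with the responses recovers the AU set that
drives each judgment — the observer's internal template.

`facerevcorr` implements this full chain — stimulus generation, observer
simulation, model fitting, and the downstream distinctiveness analyses
(Bayesian classification, signal detection, mutual information with
permutation nulls, and comparison against production-study AU patterns) —
as tested, reusable R functions. Because the original human trial data are
not publicly deposited, the package includes a synthetic-observer module
that provides ground truth for end-to-end parameter recovery; every
downstream analysis is exercised against it.

## Stimulus model

Stimuli draw 1–4 AUs (masses 0.10/0.30/0.40/0.20) uniformly without
replacement from a 42-AU catalog, over a 2.25 s animation. The count
distribution deserves a note: the design constraints are only a minimum of
1, a maximum of 4 and a median of 3, which no uniform law satisfies (a
uniform law over 1–4 has median 2.5). The default masses are the simplest
unimodal choice meeting all three constraints and are exposed in
`pipeline_config()`.

Each active AU receives an independent seven-parameter temporal profile:
onset latency, acceleration, peak amplitude, peak latency, sustainment,
deceleration, and offset latency. The original graphics generator is
proprietary to a rendering pipeline we do not reproduce (this package
emits numeric AU time courses, not faces), so `activation_curve()` defines
a transparent functional form realizing all seven parameters: a power-law
rise from onset to peak with exponent `acceleration`, a plateau of length
`sustainment`, and a power-law decay reaching zero at the absolute offset
time. Parameters are sampled uniformly within ranges
(`default_param_ranges()`) that guarantee
`0 <= onset < peak`, `peak + sustainment <= offset <= 2.25 s`. Offset
latency is an absolute time, not a gap — the quantity is otherwise
ambiguous. "Biologically feasible combination" is supported as an optional
exclusion list of incompatible AU pairs (default empty; no canonical
incompatibility table exists).

```{r}
s <- sample_stimulus(seed = 1)
s
head(stimulus_timecourse(s, fps = 30))
```

## Synthetic observers

Humans are replaced by a deliberately simple behavioral model. Each
simulated observer carries a pain AU set and an orgasm AU set, built from
the group-level culture templates (`default_templates()`): pain
{4, 6, 9, 10, 20} in both cultures; orgasm {1, 2, 5, 26, 27, 43} for
Western and {1, 2, 12, 43} for East Asian observers. Individual
variability drops each base AU with probability 0.05 and adds idiosyncratic
AUs with probability 0.02 — roughly one template change per observer,
enough to make cohort-level convergence non-trivial without destroying it.
Additions are drawn outside both affects' sets so one observer's two
templates never overlap, matching the disjointness that the fitting sign
convention enforces on the recovered models.

A response is produced by an overlap rule with three parameters
(threshold 0.5, lapse rate 0.05, intensity noise SD 0.5 on the 1–5
scale). The overlap between the active AU set and a template is

`|active ∩ template| / min(|active|, |template|)`,

i.e. normalized by the smaller of the two sets. Normalizing by the
template size alone would interact badly with the stimulus design:
templates hold 4–6 AUs while stimuli carry at most 4, so a
template-normalized overlap could reach the 0.5 threshold on only a
handful of trials per session, and a session would contain almost no
affect responses at all — unlike human observers, who categorize a
sizable fraction of trials. The min-normalized overlap treats a small
stimulus lying inside a large template as a strong match, which is the
intended reading of "the face movements matched their mental
representation". With it, sessions yield several hundred pain and orgasm
responses out of 3,600, a realistic regime for the correlational fit.
The best-matching affect is chosen when its overlap reaches the threshold
and strictly exceeds the other affect's; ties go conservatively to
"other", which avoids biasing recovery toward either affect. With
probability `lapse_rate` the response is uniform over the three options.
Intensity is `1 + 4 × (mean peak amplitude of the matched AUs)` plus
Gaussian noise, clamped to 1–5, so rated intensity genuinely tracks
movement amplitude.

What the simulator deliberately omits: reaction times, learning or
sequential dependencies, face-identity effects (validation-task identity
replication is i.i.d. repetition), and any temporal-profile influence on
the categorical choice. Recovery results are therefore conditional on
this observer model: passing tests show the *pipeline* recovers planted
structure under realistic noise, not that humans behave this way.

## Model fitting

`fit_models()` follows the published procedure: "other" trials are
excluded (the response coding pain = 0 / orgasm = 1 leaves them no value),
each AU's presence is phi-correlated with the coded response, and AUs
significant at unadjusted two-tailed p < 0.05 enter the pain model
(negative r) or the orgasm model (positive r). No multiple-testing
correction is applied at this stage — that is the method's rule, and the
expected ≈ 0.05 × 42 ≈ 2.1 false positives per observer are part of its
operating characteristics (the cohort-level frequent-AU screen is what
removes them). P-values use the t transform of r; at n in the hundreds to
thousands this is indistinguishable from exact methods.

Per significant AU, three further quantities are computed: the temporal
regression (OLS of the coded response on the seven parameters, over
retained trials where the AU is active — whether the original pooled all
trials or matching-affect trials only is ambiguous, and the choice is
recorded in the model's metadata), the intensity gradient (OLS of the 1–5
rating on the parameters over matching-affect trials), and the
high-intensity profile (per-parameter mean over matching-affect trials
rated 4–5; the published account says only "high-intensity", and 4–5 on a
5-point scale is the natural reading). Regressions require at least 9
usable trials (seven parameters plus two); the threshold is ours, as
degenerate cells are not discussed in the source method. Because each
per-trial profile satisfies the timing invariants, and those invariants
are linear inequalities, the mean profile satisfies them automatically.

```{r}
cohort <- simulate_cohort(3, "western", n_trials = 3600, seed = 42)
models <- fit_cohort(cohort)
models[[1]]
recovery_summary(cohort, models)
```

## Distinctiveness analyses

**Split-half Bayesian classification.** The published account names only
"a Bayesian model of the discrimination task using a split-half method";
on 1 × 42 binary vectors the minimal faithful reading is a Bernoulli naive
Bayes classifier, and that is what `split_half_classify()` uses: Laplace
smoothing α = 1, priors proportional to class sizes, posteriors in log
space. Each of 1,000 repetitions (the repetition count is not stated in
the source; 1,000 matches the permutation budget used elsewhere) trains on
a random half of each class and evaluates mean posteriors on the held-out
halves. Whether the published SD is across splits or across models is not
stated, so both are reported (`posterior_sd`, `posterior_sd_models`).

**Signal detection.** `dprime()` applies the log-linear correction (add
0.5 to each cell, 1 to each denominator) *unconditionally* — applying it
only at extreme rates would bias comparisons between corrected and
uncorrected models. Quadrants follow the 0.5/0.5 boundaries of the
hit/false-alarm plane, with exact ties assigned to the non-discriminated
side. The validation task mirrors the published design: 20 models × 2
affects × 10 identities = 400 stimuli, each presented once correctly and
once incorrectly word-cued (800 trials, exactly half matched), answers
pooled across validating observers per model.

**Mutual information.** `mi_binary()` is the plug-in estimator without
bias correction: it serves as an effect-size screen under a permutation
null, where the estimator's bias is common to observed and permuted
statistics. `maxT_mi_test()` shuffles the labels 1,000 times, takes the
maximum MI across all tested AUs per iteration, and thresholds observed
values at the nearest-rank 95th percentile of the maxima with strict
inequality — the classic max-statistic construction controlling
familywise error. Only highly frequent AUs are tested, as in the source
procedure. The frequent-AU Monte Carlo itself is not fully specified in
the available text; the default null permutes each model's AU positions
(preserving per-model AU counts), and an alternative (`null = "marginal"`)
resamples counts from their empirical distribution — the choice is
recorded in the result object. The specific/common partition is applied
literally: significant + frequent in exactly one affect → specific to the
higher-rate affect; non-significant + frequent in both → common; anything
else is reported as unclassified rather than forced.

**Production comparison.** Models are classified by minimum Hamming
distance to production-study AU patterns, on the full 42-dimensional
vectors (absences count, per the definition of the distance). Affect ties
are broken by majority among the tied patterns, then by smaller mean
distance to each affect's pattern set, then (logged) by "pain" — the
source never mentions ties. The per-study production patterns are not
printed in the main text of the literature synthesis we follow, so the
bundled fixture (`production_patterns_synthetic.json`) is a
*reconstruction*: 11 pain and 3 orgasm patterns built to satisfy every
published set-level statement (majority sets, their intersections, and
the pain-only AUs {7, 17, 45}). It is labeled synthetic in its filename
and should be replaced by real per-study tables where available.

## Numerical and design choices, collected

- Percentiles of null distributions use the nearest-rank method;
  significance is strict inequality above the threshold (conservative for
  discrete nulls).
- Constant AU columns (an AU absent, or present, on every retained trial)
  cannot be phi-correlated; `fit_models()` treats them as non-significant
  and records the fact, while the standalone `phi_correlation()` errors,
  as silent zeros would mask degenerate designs.
- The chi-square on the production confusion matrix is the uncorrected
  Pearson statistic with 1 df (the published df and usage indicate no
  continuity correction).
- All randomness flows from explicit seeds; `seed_stream()` derives
  per-stage child seeds so stages can be re-run in isolation, and
  `run_pipeline()` is byte-reproducible from `(seed, config)`.

## Problem sizes used in the test suite

The packaged checks run the full study conditions where it matters: 40
observers per culture × 3,600 trials for recovery, classification and
validation; 20 independently simulated cohort pairs for the
cross-cultural analysis; 400–500 replicate datasets (with 400–1,000
permutations each) for the familywise-error calibrations. Oracle checks
(phi, MI, d-prime, chi-square, naive Bayes, Hamming, set algebra) are
exact closed-form comparisons.

## Known limitations

- The observer model is the package's own construction; none of its
  parameters are estimates of human behavior.
- Published posterior values (e.g. 0.96–0.99 diagonal classification) and
  the published chi-square were computed from the 160 human-derived
  models, which are unavailable; the package reproduces the *qualitative*
  pattern (near-ceiling separation, significant production-based
  classification) on synthetic cohorts, not those numbers.
- MI analyses operate on AU presence only; temporal parameters do not
  enter the information-theoretic screen.
- No face rendering: outputs are numeric AU time courses and tables.
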