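---
title: "Circular-shift responsiveness testing and valence/salience classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circular-shift responsiveness testing and valence/salience classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perishift)
```

## The problem

Single-cell calcium imaging during Pavlovian conditioning yields, for every
neuron, a stack of trial-aligned fluorescence traces around each conditioned
stimulus (CS) presentation: here, 10 s auditory tones predicting either a
food pellet or a foot shock, with the unconditioned stimulus (US) delivered
3 s after tone offset (13 s after CS onset), traces spanning −30 s to +30 s
around CS onset at 10 Hz. Two questions follow:

1. Which neurons respond significantly — excited or inhibited — to a given
   stimulus (CS, food, shock)?
2. Among neurons registered across both the appetitive and the fear session,
   which encode *salience* (same-direction responses to both USs), which
   encode *valence* (opposite-direction or one-sided responses), and which
   neither?

The statistical difficulty in question 1 is that calcium transients are
strongly autocorrelated: adjacent samples are far from independent, so
p-values from tests that assume independence (t-test, a single rank-sum test
across pooled samples) are wildly anti-conservative.

## The circular-shift permutation test

`test_population()` implements a permutation test that respects the
dependence structure.

**Statistic.** For neuron $i$, trial $j$, the trace is restricted to an
*isolation window* and the Wilcoxon rank-sum statistic $W_{i,j}$ is computed
between the pre-stimulus and post-stimulus samples (midranks under ties; the
raw post-sample rank sum, no normal approximation). The neuron's summary
statistic is the sum across trials,
$\widetilde W_i^{obs} = \sum_j W_{i,j}$.

**Null distribution.** `build_null_repository()` repeats $B$ times (default
$B = 500$): draw one neuron uniformly from the session's full population;
circularly shift each of its trials by an independent uniform shift
$s \in \{1, \dots, N\}$ inside the isolation window; compute and sum the
per-trial rank-sum statistics. Circular shifting preserves each transient's
shape and the trace's autocorrelation while destroying its alignment to task
events, so the $B$ summed statistics $\{W^*_b\}$ sample the null hypothesis
"pre and post come from the same process". Pooling draws from the *entire*
recorded population (rather than only the tested neuron) lets the null
capture the heterogeneity of transient shapes; the tested neuron itself is
part of the pool.

**P-values.** With add-one empirical tails,
$p^+ = (\#\{W^*_b \ge \widetilde W^{obs}\} + 1)/(B+1)$,
$p^- = (\#\{W^*_b \le \widetilde W^{obs}\} + 1)/(B+1)$, and the two-sided
p-value is $\min(1,\, 2\min(p^+, p^-))$. At $\alpha = 0.05$ a neuron is
*excited* when significant with $p^+ < p^-$ and *inhibited* when significant
with $p^- < p^+$. The smallest attainable two-sided p-value is $2/(B+1)$
(≈ 0.004 at $B = 500$); under heavy ties the formula can exceed 1, hence the
cap. An exact tie $p^+ = p^-$ is never called significant.

### Analysis windows

All windows are half-open `[start, end)` in seconds relative to CS onset and
map to samples by `floor(t × rate)`, so a window of length L at rate r always
contains `round(L·r)` samples:

| stimulus | isolation | pre | post |
|---|---|---|---|
| cs | [−30, 10) | [−20, 0) | [0, 10) |
| food | [−30, 30) | [−5, 13) | [13, 30) |
| shock | [−30, 30) | [−5, 13) | [13, 18) |

The shift range is the full $\{1, \dots, N\}$ of the isolation window;
$s = N$ is the identity shift. This follows the method's formal definition;
the probability of a near-identity draw is $O(1/N)$ and immaterial at
$N = 400$–$600$.

### Design choices worth knowing

- **One repository per session × window set.** All neurons of a session
  share a single null repository, which is what makes the test cheap
  ($B + n$ statistic evaluations rather than $B \cdot n$). Consequence:
  rejections across neurons of one session are positively correlated; the
  type-I calibration property below is checked at the population level.
- **Raw per-neuron α.** No multiplicity correction by default, matching the
  method's standard use; `adjust = "BH"` switches the labelling to
  Benjamini–Hochberg-adjusted p-values.
- **Population pooling is not free.** Because the null pool contains the
  truly responsive neurons (shifted), a session dominated by strong
  excitation widens and slightly raises the null, which can make clean
  neurons look marginally inhibited and costs some power. This is inherent
  to the pooled design; with the default simulator settings the effect is
  small (the category-recovery test bounds it), but on real data with very
  high responder fractions it is worth remembering.
- **Determinism.** The B neuron draws and all per-trial shifts come from one
  seeded stream in repetition-major, trial-minor order; `(session, windows,
  B, seed)` fixes every p-value exactly.

### The sign-rank alternative

`signrank_responsiveness()` implements the conventional comparator: per
trial, a one-sample Wilcoxon signed-rank test of the post-window samples
against the trial's pre-window median, one-sided in each direction at
`per_trial_alpha/2`; a neuron is labelled when the number of individually
significant trials in one direction reaches a cutoff. The cutoff is the
smallest $k$ with $P(\mathrm{Binom}(n_{trials}, \alpha/2) \ge k) \le 0.05$
(3 of 20 appetitive trials, 2 of 10 fear trials at the defaults) — i.e. a
trial count that would itself be surprising if every trial were null. The
per-trial test ignores autocorrelation *within* a trial, but requiring
replication across trials restores stringency. On simulated populations the
two methods agree on well over 80% of neurons (see the acceptance suite).
Both directions reaching the cutoff simultaneously is resolved to
`not_significant`.

## Encoding classification

`build_encoding_table()` joins the per-session labels of registered neurons
(registration is an *input* — this package never computes it) and
`classify_encoding()` maps each ordered label pair:

- both excited or both inhibited → **salience**;
- both `not_significant` → **not significant**;
- the remaining six cells → **valence** (opposite responses, or a
  significant response to exactly one stimulus).

Subtypes are ordered pairs (appetitive stimulus first), so food-excited-only
and shock-excited-only are distinct. Counts are the normative output;
percentages are rounded half away from zero and attached for display.
`chi_square_independence()` applies the uncorrected Pearson test (the form
whose values match the published contingency comparisons), and
`compare_order_groups()` builds the 2 × 3 group-by-category tables for
conditioning-order contrasts.

## Peri-event z-scoring and metrics

`zscore_session()` standardizes each neuron × trial against its own baseline
window, default `[−10, 0)` s before the alignment event. The baseline window
is a package choice — peri-event normalization conventions are rarely stated
in imaging papers — and is configurable; z-scores are invariant to affine
rescaling of the raw trace, so the choice of fluorescence units is
immaterial. Zero-variance baselines are flagged and zero-filled (with a
warning) rather than erroring, so population summaries proceed.

`auc()` integrates the **trial-averaged** z trace by trapezoids (with
trapezoids, averaging before or after integration coincides by linearity).
The half-open window `[a, b)` contributes samples `a, a+1/r, …, b−1/r`, so a
constant z = 1 over `[0, 5)` at 10 Hz yields exactly 4.9 z·s. Whether such
an AUC should be z·s or mean z is a genuine convention fork; z·s is chosen
and documented as normative for this package. A corollary of the half-open
convention: adjacent windows omit the bridging trapezoid across their shared
boundary, so `auc([a,c))` equals `auc([a,b)) + auc([b,c))` *plus* that
bridge term — the test suite asserts exactly this identity. `time_to_peak()`
resolves ties to the earliest sample; `split_trials()` defaults to a
first-half/second-half split (the early/late split used in
learning-trajectory figures is rarely specified; half-splitting is the
neutral default).

## The synthetic-data generator

`simulate_paired_sessions()` produces the paired study design: 20 appetitive
trials and 10 fear trials per neuron, −30 to +30 s at 10 Hz, 10 s CS, US at
13 s. Traces are Poisson-like events (exponential amplitudes, mean 1)
convolved with a peak-normalized difference-of-exponentials kernel
($\tau_{rise} = 0.2$ s, $\tau_{decay} = 1.5$ s, GCaMP6m-like), plus Gaussian
noise (sd 0.2) and a slow sinusoidal drift (amplitude 0.1, period 40 s) whose
phase is redrawn every trial — trials fall at arbitrary times relative to
slow drift, so drift is incoherent across trials. Traces are ΔF/F-like
(unconstrained sign).

Ground-truth response categories are drawn per neuron from a 3 × 3 joint
(food, shock) distribution whose default matches the observed registered-
population proportions of the study design this emulates; CS responses are
direction-matched to the US response with probability
`cs_response_given_us` (default 0.25 — a stand-in, as is the lognormal
head-entry latency: neither distribution is available from published data).
*Excited* neurons gain extra events (1.5 Hz, amplitude `effect_size` × noise
sd, default 6) inside the response window with uniform per-trial latency
jitter on [0, 0.3] s; *inhibited* neurons have baseline events
multiplicatively suppressed there (default: complete), because event rates
cannot go negative. Response durations are per-stimulus: 15 s for food
(sustained consummatory response — the reason the food analysis window
extends to +30 s), 4 s for shock (brief), 8 s for the CS. Each neuron
consumes an RNG substream derived from the master seed, so enlarging the
population never perturbs existing neurons; the generator uses R's default
Mersenne-Twister with the R ≥ 3.6 `sample()` algorithm.

What the simulator deliberately does **not** emulate: biophysical calcium
dynamics and spike inference, imaging noise (photon statistics, PSF,
motion), cross-neuron correlations, session-long nonstationarity beyond the
sinusoidal drift, and behavioral feedback (head-entry-locked activity).
Passing tests on this synthetic population therefore demonstrate
*statistical* correctness of the pipeline — calibration, power, recovery of
known categories — not robustness to every artifact of real miniscope data.

## Problem sizes and runtime

The validation suite runs at sizes chosen to keep the full check fast while
preserving the study geometry: type-I calibration on 3 × 200
stimulus-independent neurons (20 trials, B = 500) against the exact
binomial 99% band around α = 0.05; category recovery on 300 registered
neurons with the default joint distribution; method agreement on 150
neurons across four stimulus tests; oracle (naive-loop) equivalence on 20
neurons, bit-exact. A full 300-neuron paired simulation plus all four
responsiveness tests completes in well under a minute on a single core.

## A worked example

```{r example, eval = FALSE}
spec <- population_spec(n_registered = 60, seed = 7)
sim <- simulate_paired_sessions(spec)

res_food  <- test_population(sim$appetitive, analysis_windows("food"),  seed = 11)
res_shock <- test_population(sim$fear,       analysis_windows("shock"), seed = 12)

enc <- build_encoding_table(res_food, res_shock, sim$registration)
category_counts(enc)
chi_square_independence(rbind(us = category_counts(enc)[1, ],
                              truth = table(factor(sim$ground_truth$us_category,
                                c("salience", "valence", "not_significant")))))
```

`run_pipeline()` wires all of the above together (simulate or load, test all
four stimulus conditions, classify, compute metrics, write CSV/JSON
reports) under a single master seed; `make_fixtures()` writes a small
deterministic dataset covering all nine response subtypes.

## Known limitations

- Power in the fear session is intrinsically lower (10 trials, 5 s shock
  window); with the default effect size a noticeable fraction of true shock
  responses is missed, which is visible in the method-agreement numbers.
- The pooled null's mild bias under extreme responder fractions (above).
- `signrank_responsiveness()`'s trial-count cutoff is this package's
  construction; published uses of the comparator do not quantify their
  cutoff.
- The hdf5 schema stores the trace tensor in one dataset; sessions large
  enough to need chunked/streamed access are out of scope.
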