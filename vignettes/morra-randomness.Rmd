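---
title: "Methods: randomness indices, synthetic agents, and the 2x2 comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: randomness indices, synthetic agents, and the 2x2 comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morrarand)
```

## The measurement problem

Morra players must produce an unpredictable stream of hand numbers (1–5)
while simultaneously calling sums, tracking the score and reading the
opponent — a random number generation task under heavy concurrent load.
`morrarand` measures how far such sequences deviate from iid-uniform
responding and compares expert and beginner players across the game and an
isolated generation task. This vignette documents the models, the numerical
conventions, and the choices made where more than one defensible convention
exists.

## Game engine

A play is a pair `(hand, call)` with `hand` in 1–5 and `call` in 2–10; it is
valid iff `1 <= call - hand <= 5` (the opponent must be able to supply the
difference). This leaves exactly 25 valid plays; the three characteristic
beginner errors (call above `hand + 5`, call equal to the hand, call below
the hand) get distinct reason codes from `validate_play()`. A round is won
by the player whose call equals the sum of hands while the opponent's does
not; if both or neither call the sum, nobody scores.

Two conventions are not fixed by the traditional rules and are implementation
choices here:

* **Simultaneous correct calls** score for neither side and play simply
  continues (logged as a tie round); no replay rule is imposed.
* **Team substitution**: after a scored round the scorer stays on and the
  losing side swaps its active player. A benched player re-enters with its
  own response history intact — agent state is per player, not per seat —
  because a human's sequence memory does not reset on the bench.

Invalid plays from custom agents are rejected and resampled by default (with
a counter), so beginner-like agents cannot corrupt adjudication; `abort` is
available for strict pipelines.

## The five randomness indices

All indices operate on a single sequence over an alphabet of size `a`
(default `1:5`), with singlet counts `n_i` and adjacent ordered-pair counts
`n_ij` (`sum(n_i) = n`, `sum(n_ij) = n - 1`). Conventions:

* **Logarithm base 2 throughout.** The FPR ratio is base-invariant;
  redundancy is not (`H_max = log2 a`), so the base matters and is fixed.
* **Redundancy** `R = 100 (1 - H / log2 a)` with
  `H = log2 n - (1/n) sum n_i log2 n_i`. Floating-point cancellation can
  produce values like `-1e-14` for perfectly equidistributed sequences, so
  the result is clamped to `[0, 100]`.
* **FPR** `= sum n_ij log2 n_ij / sum n_i log2 n_i`, terms with count <= 1
  contributing zero. Because digram counts refine singlet counts, the value
  lies in `[0, 1]`. The index is undefined when no single response repeats
  (denominator zero) — impossible for `n > a` by pigeonhole.
* **NSQ** uses denominator `a^2 - 1 = 24`: the maximum achievable null
  score, attained by a constant sequence (which still produces one digram).
  The alternative `a^2` normalization would make 100% unattainable and is
  rejected for that reason; the constant is isolated in one place.
* **Coupon score** scans left to right in non-overlapping segments with a
  hard restart after each completion, discarding an incomplete tail. This
  (rather than a sliding window) is required for the perfect cycling
  sequence `1,2,3,4,5,...` to score exactly 5, the definitional floor.
* **Repetition gap** is the positional difference between successive
  occurrences of the same value (adjacent repeat = 1), averaged over *all*
  recurrences, not only first repeats. Perfect cycling attains 5; note this
  is the mean attained by perfect cycling, not a bound on individual gaps
  (a single gap of 9 is easily constructed in a 57-long sequence).
* **Undefined indices are never silently zeroed**: the single-index
  functions raise a classed condition, and `randomness_profile()` converts
  it into an `NA` plus an entry in the `flags` column. Any length-57
  sequence over five symbols has all five indices defined.

### Finite-length behaviour of coupon and repetition gap

For unbounded iid-uniform sequences the coupon mean is
`5 (1 + 1/2 + ... + 1/5) = 11.4167` and the recurrence distance is geometric
with mean 5. At the study's standard length of 57 the sequence end truncates
both: the coupon mean is essentially unaffected (simulation puts it within
Monte-Carlo error of the closed form), but the repetition-gap mean is
noticeably biased downward — long gaps are right-censored by the end of the
sequence — to about 4.62 (SD about 0.19 across sequences), as the test suite
measures. Empirical values near 4.8 for human RNGT sequences therefore sit
*above* the finite-length iid expectation, consistent with deliberate
repetition avoidance, and 5.0 should not be used as a finite-length
reference point. The package reports the index as defined; users comparing
against the geometric mean of 5 must account for this truncation themselves.

## Preprocessing

Sequences of at least 57 responses are truncated to their first 57; shorter
ones are excluded and recorded (id, length, reason) rather than erroring.
The filter is applied per extracted player sequence, because that is the
unit on which the indices are computed. The threshold is a configuration
knob (`standard_length`) with default 57 so the length-versus-sample-size
tradeoff can be re-explored; standardization is idempotent. Positions are
1-based in files and contiguous internally.

## The memory score

The subjective-vs-actual frequency comparison is the Spearman footrule on
rank positions: for each hand number, the absolute difference between its
position in the player's believed frequency ranking and in the observed one;
the per-rank displacements are reported in subjective-rank order, their sum
is the total distance (always even; at most `floor(25/2) = 12` for five
items), and the percentage of maximum uses half-up rounding to integer
percent (16.67 -> 17, 83.33 -> 83), matching the conventional presentation.
Ties in actual frequencies — possible in real 57-long sequences — break by
ascending face value and are flagged so tied cases can be excluded. Where a
published worked example's per-cell values are internally inconsistent with
its own printed rankings, the implementation follows the formula; it never
special-cases particular inputs to force agreement with a printed table.

## Synthetic agents

The generator is a first-order Markov family: response `j` follows the
previous response `i` with probability proportional to
`w_j^(1+lambda*) * mu^(1+lambda*)` if `j = i`, and `w_j^(1+lambda*)`
otherwise, with `lambda* = lambda_load` under concurrent load and 0
otherwise. This is the minimal structure that can move all five indices
(zeroth-order bias moves redundancy; the first-order term moves FPR, NSQ,
coupon and gap); higher-order dependence is out of scope. Load enters as a
single exponent sharpening both preference and perseveration.

The default configurations are calibration constants — the study they
emulate reports no generative parameters — chosen once so that replicate
synthetic studies reproduce the published *ordinal* pattern (beginners worst
under load on every index; the two groups nearly equivalent off load, with
a between-group off-load difference smaller than the beginners' load
penalty):

* expert: `w` uniform, `mu = 0.9`, `lambda = 0.1` — near-iid with slight
  repetition avoidance and almost no load cost;
* beginner: `w = (1.3, 1.15, 1.0, 0.9, 0.8)`, `mu = 1.15`, `lambda = 3` —
  mild favourite-number bias and perseveration at baseline, strongly
  amplified by load.

The beginner values deliberately keep the *no-load* condition close to the
expert distribution: most of the beginner deficit must come through the load
exponent, otherwise the off-load equivalence that defines the design cannot
hold. Stronger baseline bias (e.g. weights spanning 1.5 to 0.7 with
`mu = 1.8`) makes beginners almost as non-random off load as on load and
destroys the pattern; that regime was rejected at calibration time. Whether
real beginners perseverate (`mu > 1`) or avoid repetition (`mu < 1`) cannot
be settled from cell means alone; the defaults encode mild perseveration and
are assumptions, not estimates.

A default study is 9 participants per group, each contributing one loaded
sequence of length 57 (the game condition) and one unloaded sequence of
length 100 (the isolated task, later standardized to 57 by the preprocessing
step, mirroring the data pipeline). Per-participant, per-task sub-seeds are
derived deterministically from the master seed, so a study replays exactly
from its design file (`write_design()` / `read_design()`).

What the generator does *not* emulate: the closed-loop coupling between
opponents in a real game (each agent's transition law ignores the other
player), drift and fatigue over a match, call-number strategy, and
measurement/transcription noise. Passing pattern-recovery tests therefore
shows that the analysis pipeline detects the designed structure, not that
the parameter values describe real players.

## Comparison report

The group analysis is deliberately descriptive: per-cell means and sample
SDs, a non-parametric overlap effect size, and permutation contrasts. (The
original analysis fits multivariate Bayesian mixed models with MCMC and
compares them by information criteria; refitting those is a call to an
off-the-shelf sampler and is out of scope here, while the overlap index and
the permutation machinery are implementable and testable in full.) The four
contrasts are the design's: beginner vs expert within each task, and game
vs isolated task within each group.

* **Overlap index (OV)**: the integral of the pointwise minimum of two
  Gaussian kernel density estimates. KDE settings are fixed because no
  canonical ones exist for this statistic: Silverman's rule-of-thumb
  bandwidth per sample, a common 512-point grid spanning the pooled range
  padded by three bandwidths, trapezoidal integration, result clamped to
  `[0, 1]`. For two unit-variance normals two SDs apart the closed form is
  `2 * pnorm(-1) = 0.3173`, which the tests recover. Zero-variance samples
  (possible for index columns with no spread) fall back to discrete mass
  overlap, flagged via the `method` attribute. OV here operates on raw
  per-sequence index values, not on posterior model estimates, so published
  model-based OV values are comparable only qualitatively.
* **Permutation contrast**: two-sided label permutation of the mean
  difference with the add-one estimator
  `p = (1 + #{|perm| >= |obs|}) / (n_perm + 1)`, valid (mildly
  conservative) under exchangeability; default 999 permutations.
* **Correlations** between indices use the product-moment form by default
  (`method = "spearman"` available); constant columns yield flagged `NA`s.

## Problem sizes and test design

The suite checks every index against independent naive-loop oracles on
1,000 random length-20 sequences (tolerance 1e-9), metric properties of the
footrule exhaustively over all 120 permutations of five items (including
all 120^3 triangle-inequality triples via the distance matrix), the payoff
matrix against an independently transcribed fixture of the printed winning
combinations, Monte-Carlo calibration of the neutral generator at 2,000 to
4,000 replicates, and pattern recovery over 200 replicate synthetic studies
at the default parameters. These sizes give comfortable Monte-Carlo margins
for every asserted property while keeping the full suite fast enough to run
routinely.

## Known limitations

* The five indices are the analysis battery used here; other RNGT measures
  (turning-point index, phase length, adjacency, runs tests) are not
  implemented.
* The repetition-gap mean carries the finite-length truncation bias
  described above; cross-length comparisons of that index are not
  interpretable without correction.
* The agent family is first-order; human sequences show longer-range
  structure the generator cannot express.
* OV on small samples (9 per cell) is noisy; it is an effect-size summary,
  not a test statistic.
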