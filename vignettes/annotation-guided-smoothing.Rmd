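---
title: "Annotation-guided selection of copy number smoothing models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation-guided selection of copy number smoothing models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segtrain)
```

## The model and its assumptions

A copy number profile is a collection of noisy logratio measurements
$x \in \mathbb{R}^m$ at positions $p_1 < \dots < p_m$ on each chromosome.
All smoothers here assume the underlying signal is piecewise constant with
additive, roughly homoscedastic noise, and they are scored only through the
breakpoints of their output: a smoothed signal $\hat x^\lambda$ predicts a
breakpoint at every inter-probe midpoint $(p_j + p_{j+1})/2$ where
$\hat x_j^\lambda \ne \hat x_{j+1}^\lambda$.

Supervision comes from annotated regions. An annotation is a closed
base-pair interval $r$ plus an expected breakpoint count interval
$a = [a_{lo}, a_{hi}]$; the three named labels are $[0,0]$, $[1,1]$ and
$[1,\infty)$. The loss per region is zero-one: 0 when the predicted count
$|\hat b^\lambda \cap r|$ lies inside $a$, 1 otherwise, decomposed into a
false positive (count too high) or a false negative (count too low). False
positives and false negatives get equal weight; if your application
penalizes one side more, this package does not re-weight them.

Key consequences of these definitions, which the test suite asserts:
$[1,\infty)$ regions can never produce a false positive, $[0,0]$ regions
never a false negative, and a $[1,1]$ region belongs to *both* the
positive set (denominator of TPR) and the negative set (denominator of
FPR). Rates with an empty denominator are reported as errors rather than
silently set to 0.

## The smoothers

**`cghseg.k` / `pelt.n`.** `segment_dp()` computes the exact least-squares
segmentation $\mu^k$ for every $k = 1..k_{max}$ by $O(k_{max} m^2)$
dynamic programming. We deliberately use the plain quadratic DP rather
than a pruned variant: at the profile sizes this package targets the
pruning is a constant-factor optimization of the *same* estimator, and the
unpruned recursion is directly checkable against exhaustive enumeration
(which the acceptance suite does at $m \le 12$). The two selection rules,

$$k^*(\lambda) = \arg\min_k \ \lambda k + \tfrac1m RSS(k)
\qquad\text{and}\qquad
k^*(\beta) = \arg\min_k \ \beta (k-1) + RSS(k),$$

are equivalent when $\beta = \lambda m$ (the criteria differ by the
constant $-\beta$ and the factor $m$), and `pelt.n` is defined with this
per-chromosome $\beta$ precisely so the equivalence is exact; both ties
break toward the smallest $k$ (fewest segments, fewest false positives).
Both models share one `segment_dp()` call per chromosome across the whole
λ grid, and both search $k \le k_{max} = 20$ (clipped to $m$) — the
default any segmentation user of this family will recognize. A chromosome
with more than 19 true breakpoints would saturate this; raise `kmax` if
your data look like that.

**`flsa` / `flsa.norm`.** `fused_lasso_1d()` returns the exact minimizer
of $\tfrac12\sum_i (x_i-\mu_i)^2 + \lambda_2 \sum_i |\mu_i - \mu_{i+1}|$
(no sparsity term: the $\ell_1$ penalty on the values themselves is set to
zero, since shrinking logratios toward 0 is not wanted for breakpoint
detection). The solver is Condat's direct non-iterative algorithm; its
output satisfies the subgradient conditions to ~1e-13 on random inputs.
One numerical guard matters: for $\lambda_2$ at or beyond the saturation
threshold $\max_i |\sum_{j\le i}(x_j - \bar x)|$ the constant solution is
returned analytically, because running the scan with $\lambda_2$ many
orders of magnitude above the data scale loses precision to cancellation.
`flsa.norm` rescales $\lambda_2 = \lambda m 10^6 / l$ with $l$ the
chromosome length in base pairs, so that one unit of λ means the same
penalty per probe per megabase regardless of probe density — this is the
only place the chromosome length enters, and it defaults to the last probe
position when the data format does not carry it.

Because fused-lasso output is computed in floating point, adjacent fitted
values are declared equal when they differ by at most
$10^{-9}(1 + \max|x|)$; without this fusion tolerance, float noise would
manufacture spurious breakpoints. The DP models need no tolerance — their
segment structure is explicit.

## Training and tie-breaking

`train_global()`/`train_local()` minimize the global/local error curve
over a finite λ grid (defaults: 100 log-spaced values, $[10^{-8},10^4]$
for the penalized models — endpoints wide enough to span the constant fit
to the saturated fit on logratio-scale data — and $[10^{-5},10^{12}]$ for
the fused lasso, whose normalized variant needs the large upper end).
λ is assumed monotonic in the number of predicted breakpoints, which holds
for all four built-in models (asserted on synthetic data in the acceptance
suite).

Local training sets are small, so plateaus of minimizers are the rule, not
the exception. The argmin set is ordered from most to fewest predicted
breakpoints (breakpoint counts, not λ, define the order; exact count ties
fall back to λ) and resolved by three rules: middle of an interior
plateau; fewest-breakpoints minimizer when the plateau touches the
most-breakpoints end (protects FPR); most-breakpoints minimizer when it
touches the fewest-breakpoints end (protects FNR). Two conventions were
genuinely open and are fixed here: a plateau touching *both* ends (a
constant curve) takes the middle, and a non-contiguous argmin set applies
the rules to the ordered argmin list as a whole. Even-length plateaus take
the element at position ⌈n/2⌉. Global training reuses the same rules —
the global curve usually has a unique minimizer, but nothing guarantees
it. Both trainers are deterministic.

## Cross-validation protocols

`loocv_annotation()` holds out one annotation per profile uniformly at
random, trains λ on the rest (globally and per profile), counts errors on
the held-out regions only, and averages over `V = 10` repetitions.
Profiles with a single annotation cannot participate (no training
annotation would remain); their annotation stays in the global training
set and they are excluded from the holdout, with a message. This protocol
compares the *training scopes*: a local model always fits its own training
annotations at least as well as the global λ̂ — an inequality the
acceptance suite asserts per profile — but may generalize worse.

`nt_fold_cv()` answers "how many profiles must I annotate?": profiles are
shuffled (seeded) into ⌊n/t⌋ folds of ~t profiles (remainder spread one
per fold from the first), each fold in turn is the **training** set for a
global λ̂, and error is measured on all annotations of the other folds.
Note the deliberate inversion of conventional CV — the small part trains.

Both protocols are driven entirely by one integer seed and restore the
caller's RNG state; rerunning with the same seed is bit-identical. Both
accept a precomputed `evaluate_models()` object, since the expensive part
(smoothing every profile over the grid) does not depend on the partition,
and a "default-style" external model with a single grid value passes
through unchanged (training is then vacuous and both scopes coincide).

## What the synthetic generator emulates — and what it does not

`simulate_profiles()` draws, per chromosome: a probe count uniform in a
range, probe positions uniform over the chromosome (sorted, deduplicated),
a segment count, segment boundaries at distinct inter-probe gaps, segment
means whose adjacent differences are at least `jump_min` (magnitudes
uniform in `[jump_min, 2 jump_min]`, random signs), and Gaussian noise.
True breakpoint positions are recorded as inter-probe midpoints, the same
convention the scorer uses, so a perfect smoother can recover them
exactly. `annotate_from_truth()` emulates both labeling protocols: the
*systematic* protocol labels the same fixed, evenly spaced regions on
every profile with 0/>0 labels only (mimicking a spreadsheet over a fixed
region set); the *any* protocol places non-overlapping regions at random
per profile and can label exact single-breakpoint counts `[1,1]`.

The shipped benchmark (`synthetic_benchmark()`): 50 profiles, 4
chromosomes, probe counts uniform in 150–250 (nominally 200 — drawn from
a range because heterogeneous probe counts are a stated feature of real
arrays), 1–4 segments per chromosome, `jump_min = 1.0` logratio,
`noise_sd = 0.25`, 6 systematic regions (2,2,1,1 across the chromosomes,
width 8% of the chromosome) plus 4 any-protocol regions per profile.

What it does *not* emulate: GC waves and other spatial trends, outlier
probes, heavy-tailed or heteroscedastic noise (a Student-t option exists
behind `heavy_tails` for exploration but no shipped test uses it), probe
chemistry differences, or copy-number-dependent variance. Consequently a
green acceptance run establishes that the estimators, trainers and
protocols are implemented correctly and behave as the theory predicts on
well-specified piecewise-constant-plus-Gaussian data; it says nothing
about which smoother wins on any real tumor series. On this benchmark's
signal-to-noise ratio (jump four times the noise sd, ~50 probes per
segment) a globally trained `cghseg.k` reaches zero held-out error already
with t = 2 training profiles, so the "more training profiles never hurt"
curve is flat at zero rather than decreasing — the stated world is simply
easy enough to saturate immediately.

## Degenerate inputs and numerical conventions

Single-probe chromosomes have no adjacent pair, hence never any
breakpoint. Missing logratios are dropped on read (with a count), not
imputed. Region bounds are closed and coordinates 1-based; since predicted
breakpoints are half-integer midpoints, boundary collisions are rare, and
the closed convention makes membership deterministic. bedGraph input is
0-based half-open per that standard and probes are placed at interval
midpoints; BED-like segment output is 0-based half-open with adjacent
segments sharing the breakpoint coordinate. Floating-point RSS values are
clamped at zero; argmin ties over k break to the smallest k. The CLI
serializes every run's resolved configuration as JSON (chosen over YAML to
avoid a dependency) so a run is reproducible from its config file and
seed alone.

## Known limitations

- The quadratic-time DP is comfortable to ~10⁴ probes per chromosome;
  beyond that a pruned implementation would be needed.
- Annotation error is unweighted; class-imbalanced region sets (many more
  negative than positive labels, as in real databases) make the error rate
  lean on false positives.
- No per-chromosome λ: one λ per profile (local) or per data set (global).
- The external-model adapter identifies a λ value by its numeric text in
  the breakpoint table; λ values at which a model predicts no breakpoints
  anywhere are indistinguishable from λ values never run.
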