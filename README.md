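# segtrain

Annotation-guided training of copy number profile smoothing models.

## The problem

Array CGH and SNP microarrays measure a noisy logratio per probe that is
proportional to DNA copy number. Detecting copy number alterations means
detecting the *breakpoints* of the underlying piecewise-constant signal,
and every smoothing model has a smoothness parameter λ that controls how
many breakpoints it reports. Default values rarely transfer between data
sets, and the mathematical assumptions behind automatic criteria cannot be
verified on real microarray noise.

`segtrain` takes the opposite route: an expert's visual interpretation is
the gold standard. The expert labels genomic regions with an
interval-valued expected breakpoint count — `0breakpoints` = [0,0],
`1breakpoint` = [1,1], `>0breakpoints` = [1,∞) — and the smoothness
parameter is *trained* by minimizing the disagreement between predicted
breakpoints and these annotations. The package is aimed at analysts who
have (or are willing to create) a few dozen such labels and want a
quantitative, reproducible way to pick a model and its λ.

## The model

For probes at positions p₁ < … < pₘ on one chromosome with smoothed values
x̂λ, the predicted breakpoints are the inter-probe midpoints of the jumps:

    b̂λ = { (pⱼ+pⱼ₊₁)/2 : x̂ⱼλ ≠ x̂ⱼ₊₁λ }

Each annotated region r with interval a = [a̲, ā] is scored with the
zero-one loss e(b̂λ, r, a) = FP + FN, where FP = 1 iff |b̂λ ∩ r| > ā and
FN = 1 iff |b̂λ ∩ r| < a̲. Summing over one profile gives the local error
Eᵢ(λ); over all profiles, the global error E(λ). Training minimizes either
curve — one shared λ̂ (global model) or a per-profile λ̂ᵢ (local model) —
with explicit tie-breaking rules on error plateaus, and TPR/FPR over the
positive/negative annotation subsets give ROC curves.

Four exact smoothers are built in:

| model      | smoothing                              | selection                          |
|------------|----------------------------------------|------------------------------------|
| `cghseg.k` | least-squares segmentation (exact DP)  | argmin_k λk + RSS(k)/m             |
| `pelt.n`   | same μᵏ                                | argmin_k β(k−1) + RSS(k), β = λm   |
| `flsa`     | exact 1-D fused lasso / TV denoising   | λ₂ = λ                             |
| `flsa.norm`| exact 1-D fused lasso                  | λ₂ = λ·m·10⁶/l (probe density)     |

`cghseg.k` and `pelt.n` are mathematically equivalent parameterizations and
the package verifies they return identical breakpoints. External models can
be plugged in as per-λ breakpoint tables (`evaluate_breakpoints()`, or
`--external-breakpoints` on the CLI) and trained/cross-validated
identically.

Two cross-validation protocols estimate breakpoint-detection error of the
trained models: leave-one-annotation-out per profile (comparing global vs
local training), and ⌊n/t⌋-fold CV where each fold of ~t profiles is the
*training* set, estimating how few annotated profiles suffice.

## Worked example

```r
library(segtrain)

bench <- synthetic_benchmark(seed = 1)   # 50 profiles, known breakpoints,
                                         # 500 annotations, both protocols
ev <- evaluate_models(bench$profiles, bench$annotations,
                      model = "cghseg.k", grid = default_grid("cghseg.k"))

train_global(segtrain:::curve_from_rows(ev))
#> trained_smoothness (global): lambda = 0.01149757, error = 0, |argmin| = 9

loo <- loocv_annotation(ev, V = 10, seed = 7)
loo$global
#> cv_result [loo_annotation/global]: mean error 0.0000 (sd 0.0000), fp 0.0000, fn 0.0000
loo$local
#> cv_result [loo_annotation/local]: mean error 0.0260 (sd 0.0212), fp 0.0260, fn 0.0000

nt_fold_cv(ev, t = 10, seed = 7)
#> cv_result [nt_fold/global]: mean error 0.0000 (sd 0.0000), fp 0.0000, fn 0.0000
```

On this benchmark a globally trained `cghseg.k` reaches zero held-out
annotation error, while per-profile training overfits slightly (2.6% test
error, all false positives) — locally trained models fit their own
annotations at least as well but generalize no better, which is exactly the
comparison the leave-one-out protocol is designed to expose.

The same pipeline is available from the shell:

```sh
Rscript inst/cli/segtrain.R simulate --n 50 --seed 1 \
    --out profiles.csv --annotations-out ann.csv --truth-out truth.csv
Rscript inst/cli/segtrain.R cv --profiles profiles.csv --annotations ann.csv \
    --model cghseg.k --protocol ntfold --t 10 --seed 1 --out folds.csv
```

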