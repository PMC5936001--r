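---
title: "Ensemble model-based outlier detection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble model-based outlier detection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the statistical model behind `rpoutliers`, the
numerical choices made in implementing it, and the places where the design
was genuinely open. It states no empirical result beyond what the test suite
and `scripts/acceptance.R` themselves compute.

## Model and procedure

The object of inference is the *outlierness* of each observation in a
two-class, high-dimensional (n << p) expression dataset. Outlierness is
defined relative to a model: an observation is outlying when its observed
label is improbable given its covariates under a fitted classifier.
Because different dimension-reduction strategies expose different
observations, the package never trusts a single model. The pipeline is:

1. Fit k classifiers to (X, y). The default members are elastic-net
   logistic regression, SPLS-DA, and SGPLS — one penalized-likelihood
   variable selector and two latent-variable projections, deliberately
   heterogeneous.
2. For each model j and observation i compute the one-step Cook's distance
   `D_ij = r_ij^2 h_ij / (1 - h_ij)` from the standardized Pearson residual
   and the logistic leverage `h = diag(V^{1/2} X (X'VX)^{-1} X' V^{1/2})`,
   `V = diag(p(1-p))`.
3. Rank observations within each model by decreasing `D` (rank 1 = most
   outlying) and combine: `RP_i = prod_j R_ij`.
4. Convert `RP_i` to a p-value under the null hypothesis that all k rankings
   are independent uniform permutations, adjust by Benjamini-Hochberg, and
   flag observations with `q < 0.05`.

The key assumption of step 4 — *independent* rankings — is discussed under
Limitations; it is an approximation whenever the k models are fitted to the
same data.

### Effective designs for Cook's distance

The hat-matrix formula above is exact for an unpenalized logistic fit, so
each member contributes a design on which that formula is literally valid:

- **LOGIT-EN**: intercept plus the selected (nonzero-coefficient) genes,
  with an unpenalized logistic refit on that support supplying fitted
  probabilities and weights. When the support reaches the sample size or the
  refit separates, the penalized fit is kept and the curvature is
  ridge-augmented by `n * lambda * (1 - alpha)` (the elastic net's own l2
  term), with a warning. Both routes are exposed; the refit is the default
  because the hat matrix has no penalty term.
- **SPLS-DA / SGPLS**: intercept plus the L latent scores, with the stage-2
  logistic (respectively final-IRLS) weights. Leverage in score space is the
  natural analogue, since the latent projection *is* the model's design.

Observations absent from a member's training set (the random-patients
ensemble) still get leverages: `h_i = v_i x_i' (X_t' V_t X_t)^{-1} x_i` with
the training-set information matrix and the held-out observation's own
predicted weight. This is a deliberate extrapolation: such samples enter
through their predicted probability, and their "influence" is the influence
they *would* exert at their covariate position.

## Null p-values for the Rank Product

Three engines are provided; `rp_test(pvalue_mode = "auto")` picks by
feasibility:

- **Exact** (default): `P(RP <= rp) = C_k(rp) / n^k`, where
  `C_k(rho) = #{r in {1..n}^k : prod r_j <= rho}` follows the recursion
  `C_k(rho) = sum_r C_{k-1}(floor(rho/r))` evaluated with divisor blocking
  (runs of r sharing `floor(rho/r)` are collapsed) and memoisation, in C++.
  All counts are integers below 2^53, hence exact in doubles; the engine
  refuses (n, k) beyond that range and carries an operation budget so `auto`
  can fall back rather than stall.
- **Recursive bounds with geometric-mean approximation**: replacing the sum
  over integer ranks by integrals brackets the count between the volume of
  `{x in [0,n]^k : prod x <= rho}` (upper; closed form, the regularized
  upper incomplete gamma `P(Gamma(k) >= k log n - log rho)`) and the volume
  of `{x in [1, n+1]^k : prod x <= rho}` (lower; inclusion-exclusion over
  the box, evaluated in log space with an all-positive series for the
  simplex integral). The reported approximation is `sqrt(lower * upper)`.
  The alternating inclusion-exclusion sum loses precision when `k` is large
  and the product sits mid-range; the implementation detects the
  cancellation (headroom below ~1e-6 relative) and falls back to the crude
  but valid count bound `min(n, floor(rp)) / n^k` for the lower end.
- **Convolution bracketing** (large k, e.g. 100-run resampling ensembles):
  `log RP = sum_j log R_ij` is a sum of k i.i.d. discrete variables, so the
  null CDF is a k-fold convolution, computed by FFT after rounding the
  support of `log rank` down (upper bound on p) or up (lower bound) to a
  grid of width `min(0.05/k, 1e-3)`. FFT noise limits absolute accuracy to
  roughly 1e-11; below 1e-9 the reported p-value switches to the continuous
  gamma upper bound, which is conservative (it can only make an already
  extreme observation less significant — it is flagged either way at any
  reasonable q threshold).

Ranks are ordinal with ties broken by ascending sample index, never
midranks: rank products must stay exact integers for the exact engine, and
the tie-break keeps the whole pipeline deterministic. For k where
`n^k >= 2^53` the stored `rp` column is no longer an exact integer; `log_rp`
is carried alongside and all p-values are computed from the ranks.

Multiple-testing adjustment is plain Benjamini-Hochberg step-up (via
`p.adjust`), with the package validating p-values in (0, 1]. Published
q-value tables for this procedure are not always monotone in p, which plain
BH cannot produce; BH is used here as the identifiable, standard choice.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `alpha` (LOGIT-EN) | 0.9 | elastic-net mixing; near-LASSO sparsity with a small grouping term for correlated genes |
| `lambda` | `"cv"` | penalty strength; 10-fold CV over 50 log-spaced values spanning 4 decades below the smallest all-zero lambda |
| `alpha_sparsity` (SPLS-DA / SGPLS) | 0.8 / 0.7 | soft-threshold fraction of the largest covariance entry; 0 is dense PLS, values near 1 keep single genes |
| `L` | 4 | latent components for the PLS members |
| `q_threshold` | 0.05 | FDR level for the outlier flag: 5% of flagged observations expected false |
| `selection_freq_threshold` | 0.75 | consensus gene cutoff across resampling runs |
| `runs`, `fraction`, `n_features` | 100, 0.8, 1000 | resampling ensemble sizes |
| SGPLS `max_iter`, `tol` | 50, 1e-4 | IRLS iteration cap and relative coefficient-change tolerance |

Member defaults mirror the TNBC analysis that motivated the package;
cross-validation (`lambda = "cv"`, or `cv_select()` over alpha and L) is the
recommended route for new data.

## Numerical choices

- Fitted probabilities are clipped to `[1e-10, 1 - 1e-10]` before residuals
  (and to `[1e-5, 1 - 1e-5]` inside the SGPLS IRLS weights) so that
  separated fits yield large-but-finite Cook's distances instead of NaN.
- The SGPLS IRLS loop guards against active-set cycling with step halving on
  the deviance; after convergence the coefficient vector is re-expressed
  exactly as `W* gamma` in score space so that predictions, stored scores
  and stage-2 coefficients are mutually consistent. Non-convergence returns
  the last iterate with `converged = FALSE` and a warning.
- SPLS direction vectors are the soft-thresholded leading eigenvectors of
  `M = X'YY'X` (threshold = `alpha_sparsity * max |entry|`), renormalized to
  unit norm; predictors are deflated by regression on each score. When the
  response covariance is exhausted before L components (the PLS fit already
  equals least squares), extraction stops early rather than erroring.
- Rank-deficient weighted designs in the leverage computation are detected
  by a relative Cholesky-pivot threshold (1e-7) and ridge-stabilized with a
  warning naming the condition number.
- The expression loader rejects files with missing or non-numeric cells
  (naming row and column) — no imputation anywhere in the package.
- Log transform is `log2(x + 1)`: the offset keeps zeros at zero and is the
  standard pseudo-count for FPKM data.
- Master seed -> per-run seeds via a fixed affine hash (`derive_seed`), so
  individual resampling runs are reproducible in isolation, and all internal
  RNG use restores the caller's RNG state.

## TNBC label construction

`y = 1` (triple negative) iff ER, PR and the resolved HER2 call are all
negative; any positive call gives `y = 0`. The HER2 call prefers a
determinate FISH result over the IHC status — FISH is the more accurate
assay — but an equivocal or indeterminate FISH falls back to IHC status
rather than erasing it. IHC *status* is preferred over IHC *level* (the
status is available for more samples; the level maps 0/1+ to negative, 2+ to
indeterminate, 3+ to positive and is used only for discordance flagging).
Samples with no positive call and at least one missing receptor are
unresolvable: they are excluded and listed, never guessed. These precedence
and exclusion rules are design choices the underlying clinical coding does
not fully determine.

## The synthetic benchmark

`simulate_two_class()` draws class-conditional Gaussians: genes in blocks of
50 with exchangeable within-block correlation `rho = 0.3` (a one-factor
model per block emulating co-expression), informative genes mean-shifted by
`delta` in class 1; `inject_label_flips()` flips a uniformly chosen subset
of labels, unstratified by class. Defaults are 500 observations per class
and p = 5000 genes with 5% flips. The scaled benchmark used by the tests
and acceptance script is n = 300, p = 500, 30 informative genes,
`delta = 1.5` — sized so ten-seed replications run in minutes while staying
in the n << p regime.

What the generator does *not* emulate: heavy-tailed and zero-inflated
expression, mean-variance coupling of counts, batch structure, and
covariate-dependent label noise. Passing the planted-flip recovery tests
therefore demonstrates the machinery (influence, ranking, consensus,
calibration) rather than clinical performance on real RNA-Seq data.

## Limitations

- **Rank dependence.** The RP null assumes independent rankings. Ensemble
  members fitted to the same data are correlated, and 100 resampled models
  on 80% patient draws are *strongly* correlated: any observation
  consistently ranked in the top quarter can reach a tiny p-value, so the
  resampling ensembles flag substantially more observations than the
  three-member ensemble at the same q threshold — on clean Gaussian
  benchmarks, several times more. Flagged sets from `run_random_patients()`
  should be read as a robustness cross-check on the *top* of the ranking,
  not as a calibrated discovery set, and overlap statistics between the two
  analyses can be small even when every planted outlier is recovered by
  both.
- The one-step Cook's distance is a quadratic approximation, not a
  case-deletion refit; no DFBETAS/DFFITS variants are provided.
- With replacement vs without: patient resampling draws **without**
  replacement (80% subsamples), which is the procedure the methods text of
  the motivating analysis describes.
- The penalty `lambda` for the resampling ensembles is selected once on the
  full data and reused across runs, keeping runs comparable and cheap;
  re-selecting per run would add model diversity at ~10x the cost.
- Exact p-values require `n^k < 2^53` and a bounded DP cost; beyond that the
  bound/convolution engines take over automatically, and deep-tail p-values
  under the convolution engine are conservative upper bounds.
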