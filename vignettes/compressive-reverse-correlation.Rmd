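---
title: "Compressive sensing for reverse correlation: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressive sensing for reverse correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revcorrcs)
```

## The problem

Reverse correlation infers a latent perceptual template — a
*classification image* — from many yes/no answers to random noise
stimuli. An observer carrying an internal template $x$ (an $m$-pixel
grayscale image) sees binary noise images $\phi_i$ and reports whether
each "contains" the target. Averaging the stimuli by response class
recovers a blurry portrait of $x$, but conventionally needs on the order
of $10^4$ trials per observer, which is why classification-image studies
rarely exceed a handful of participants.

This package implements that conventional estimator alongside a
closed-form *one-bit compressive sensing* estimator which assumes only
that the template is sparse in the two-dimensional discrete cosine (DCT)
basis. Under the simulated study conditions shipped with the package, the
sparse estimator reaches the reconstruction quality of full-sample
reverse correlation from roughly a tenth of the trials — the quantity the
acceptance script (`scripts/acceptance.R`) recomputes end to end.

## Response model

Responses are modeled as the sign of a noisy match between stimulus and
template:

$$ y_i = \mathrm{sign}\big( (\phi_i - \tfrac12)\cdot(x - \bar x) + \varepsilon_i \big), $$

with $y_i \in \{-1, +1\}$ ("yes"/"no"; files using the $\{1, 0\}$ coding
are converted on load).

**Centering is essential and deliberate.** With raw $\{0,1\}$ stimuli and
a nonnegative template, $\phi_i \cdot x$ is strictly positive on every
trial and the observer would answer "yes" always — a regression test
asserts exactly this. Subtracting the stimulus-ensemble mean (exactly
$1/2$ per pixel for equiprobable binary noise) and the template mean
makes the decision variable symmetric about zero and the yes/no classes
balanced, which is what the paradigm requires. Exact ties
($z_i = 0$) resolve to $+1$, a fixed tie-break so that noiseless
responses are a deterministic function of (template, stimuli).

**Observer noise** comes in two mechanisms, chosen via `noise_spec()`:

* `flip` (default): noiseless responses are computed first and each is
  independently negated with probability $\sigma/100$. Here $\sigma$ *is*
  the expected percent of incorrect responses, and the number of flips is
  Binomial$(l, \sigma/100)$ — a testable calibration.
* `additive_gaussian`: $\varepsilon_i \sim N(0, \cdot)$ on the decision
  variable, the classical internal-noise model. By default the scale is
  calibrated against the realized decision variables so the expected
  error rate is $\sigma$ percent (attainable only up to 50%). With
  `calibrate = FALSE`, $\sigma$ is used literally as the noise
  *variance*.

The distinction matters at heavy noise. A flat 50% flip makes responses
statistically independent of the stimuli — no estimator can recover
anything, and comparisons between estimators at that setting are
meaningless. Additive noise of fixed variance instead concentrates errors
on trials with weak evidence, so the responses stay partially informative
at any variance. The noise-robustness tests in this package therefore use
the literal mechanism (`calibrate = FALSE`) for their heavy-noise
condition; the percent-flip mechanism remains the default because its
$\sigma$ has a direct behavioral meaning.

## Estimators

### Reverse correlation

`revcorr_reconstruct()` computes the difference of class means of the
centered stimuli,
$\hat x = \overline{\phi_c}^{\,\mathrm{yes}} - \overline{\phi_c}^{\,\mathrm{no}}$,
the behavioral analogue of the spike-triggered average. The unnormalized
cross-correlation $\Phi_c^T y / l$ and the full pseudoinverse regression
$(\Phi_c^T\Phi_c)^+\Phi_c^T y$ are available behind the `form` argument;
both quality metrics used here (squared correlation and sign prediction)
are invariant to positive rescaling, so the normalizing scalar is
immaterial and the cheap forms are preferred. If all responses share one
sign the class-mean difference is undefined; the function warns and falls
back to the cross-correlation form.

### One-bit compressive sensing

`cs_reconstruct()` assumes $x = \Psi s$ with $s$ sparse, where $\Psi$ is
the orthonormal 2D DCT basis (`basis_spec()`; type-II DCT with
orthonormal scaling in each dimension, basis images ordered row-major by
frequency pair, pixels vectorized row-major). The estimate is the
analytic minimizer of the penalized one-bit objective:

$$ \hat s = \zeta^{-1}\, P_\gamma\!\big( m^{-1} \Theta^T y \big),
   \qquad \hat x = \Psi \hat s, $$

where $\Theta = \Phi_c \Psi$, $P_\gamma$ keeps the $\gamma$ coefficients
of largest magnitude, and $\zeta$ normalizes $\hat s$ to unit Euclidean
norm. No iterative solver is involved, and $\Theta$ is never formed:
$\Theta^T y$ is the fast separable DCT of the reverse-correlation image
$\Phi_c^T y$, so one fit costs one reverse-correlation pass plus two
small matrix products. The $m^{-1}$ factor (and any other positive
scalar) cancels in the $\zeta$-normalization — asserted numerically in
the tests.

**Soft versus hard thresholding.** Two variants of $P_\gamma$ are
implemented (`soft_threshold_topk()`):

* `soft` (default): survivors are shrunk toward zero by
  $\lambda$ = the $(\gamma{+}1)$-th largest magnitude, the smallest
  threshold that makes the solution exactly $\gamma$-sparse. This is the
  true analytic solution of the $\ell_1$-penalized objective; $\lambda$
  is always derived from $\gamma$, never set directly.
* `hard`: survivors are kept at full amplitude (pure selection).

The choice is consequential and genuinely open. Shrinkage behaves like a
nonlinear denoiser: it is what delivers the ten-fold trial saving at
small samples, because the retained-but-noisy coefficients near the
threshold are damped rather than trusted. Its flip side is that with
many trials, retaining *more* shrunken coefficients keeps helping, so the
prediction-optimal sparsity level drifts upward: the held-out grid search
at the canonical noiseless 10,000-trial condition selects $\gamma = 512$
under shrinkage (the acceptance script reports this), whereas pure
selection pays an increasing price for every unshrunk noise coefficient
and tops out near $\gamma = 64$ — at the cost of markedly worse
small-sample reconstructions. We ship shrinkage as the default because it
is the analytic solution of the stated objective and dominates on
reconstruction quality across sample sizes; `mode = "hard"` is a
one-argument switch, and the structural identity that ties the two
estimators together — at $\gamma = m$ with hard thresholding, CS is
exactly reverse correlation up to norm — is asserted in the tests with
hard mode, where it holds by $\Psi\Psi^T = I$.

Degenerate inputs (an all-zero back-projection, or all retained
coefficients zero after shrinkage) raise errors rather than returning a
zero estimate, since the unit-norm contract would be unsatisfiable.

### Sparse logistic baseline

`glm_reconstruct()` is the comparator: an $\ell_1$-penalized logistic
regression of the responses on the DCT-transformed centered stimuli,

$$ \hat s = \arg\min_s \textstyle\sum_i \log\!\big(1 + e^{-y_i(\Theta s)_i}\big)
   + \lambda \lVert s\rVert_1, $$

fit by proximal gradient descent (ISTA) with backtracking line search —
the objective decreases monotonically by construction, which the tests
assert. Convergence is declared at a relative objective change below
`tol` (default $10^{-6}$, cap 5000 iterations; non-convergence is flagged
on the returned fit, not fatal). The estimator regresses responses on the
transformed stimuli only — no auxiliary nuisance regressors — and returns
a unit-normalized pixel estimate for comparability. $\lambda$ has no
closed-form sparsity correspondence here, so it is selected by the same
held-out accuracy protocol used for $\gamma$
(`select_lambda_heldout()`), over a log-spaced grid by default.

## Assessing reconstructions

Two metrics (`evaluate` functions):

* `template_r2()` — squared Pearson correlation between reconstruction
  and ground-truth template, available only in simulation. Affine
  invariant; a sign-flipped reconstruction scores 1 with the signed
  correlation reported as an attribute.
* `balanced_accuracy()` of `predict_responses()` — the mean of
  sensitivity and specificity of the responses predicted by using the
  reconstruction *as if it were the template*. Predictions use the
  noiseless sign rule ($\varepsilon = 0$): injecting prediction noise
  would deflate all methods equally while adding variance, so the
  deterministic rule is used even when the data are noisy.

`kfold_prediction_cv()` is the protocol for data whose template is
unknown: fit on $k-1$ folds, predict the held-out fold, pool all held-out
predictions, and compute one balanced accuracy on the pool (pooling
rather than averaging per-fold accuracies, so small folds do not get
outsized weight; per-fold values are also reported, with single-class
folds flagged as `NA` but still contributing predictions to the pool).
Folds are a seeded random partition by default, contiguous blocks by
flag.

## Choosing the sparsity level

Two protocols mirror the two data regimes:

* **Simulation** (`select_gamma_heldout()`): fit CS once per candidate
  $\gamma$ on one training set; score each fit's balanced prediction
  accuracy on eight freshly simulated stimulus–response sets from the
  same template and noise model; pick the $\gamma$ with the best mean.
  Held-out sets default to the training-set size, so accuracy estimates
  are comparably tight at every condition. One fit per $\gamma$
  (evaluated on all held-out sets) rather than a refit per set: the fit
  does not depend on the held-out data, so refitting would only add cost.
* **Real observers** (`select_gamma_nested_cv()`): ten slices; per
  rotation, train on 8/10, select $\gamma$ on a 1/10 validation slice,
  score the winner on the untouched 1/10 test slice; the final $\gamma$
  is the modal per-fold winner. Test responses are never consulted during
  selection — the `.trace` instrumentation hook exposes every data access
  so the tests audit this directly. The default grid for observer data is
  $\{2, \dots, 1024\}$; simulations search $\{2, \dots, 2048\}$.

Ties — between grid points, and in the mode — resolve toward the smaller
(more parsimonious) $\gamma$. A $\gamma$ whose fit is degenerate is
recorded as failed and excluded from the argmax rather than scored zero.

## The simulation experiments

`experiment_config()` / `run_grid()` script the full study: methods
$\times$ trial counts $\times$ noise levels $\times$ replicates, each
cell scored by template $r^2$ and by balanced prediction accuracy on a
freshly simulated test set (2000 trials by default), with Student-$t$
95% confidence intervals over replicates in `summarize_grid()`. The
canonical conditions are the 50$\times$50 letter template, trial counts
$\{1250, 2500, 5000, 10000, 20000\}$, $\sigma \in \{0, 25, 50\}$ and 10
replicates; tests exercise the machinery at reduced sizes (hundreds of
trials, $\le 12\times12$ pixel images) chosen to keep the default suite
fast while leaving every code path covered. Fresh stimulus sets are drawn
per cell and replicate (seeded as `seed + 1000*cell + replicate`), not
nested across trial counts. `run_subsample_comparison()` implements the
efficiency headline: reverse correlation on all pairs versus CS on a
seeded uniform subsample, reporting both $r^2$ values and their ratio; a
subsample that happens to contain a single response class is redrawn with
an incremented seed and the redraw count reported.

## What the generator does and does not emulate

The synthetic observer reproduces the structure the estimators assume:
i.i.d. equiprobable binary pixels, a fixed template, a linear match
followed by a sign, and stationary noise. Real observers violate all of
this in ways the simulations cannot certify: response criteria drift over
sessions, errors are not independent of recent history, templates may be
non-stationary or non-sparse, and the effective "template" may be a
nonlinear functional of the stimulus. Passing tests therefore demonstrate
correctness of the estimators under the stated model and the relative
efficiency of the sparse estimator *within* it — not that ten-fold trial
savings will transfer to any particular behavioral experiment. The
sparsity assumption itself biases estimates toward sparse structure; for
templates that are genuinely dense in the DCT basis (an impulse/dot is
the canonical example, available as `make_dot_template()`), the GLM
baseline or plain reverse correlation can be preferable.

The canonical 50$\times$50 lowercase "s" ships as a fixed text raster
(`inst/extdata/template_s_50x50.csv`, rasterized once from a generic
sans-serif face and stretched to fill the square) so results do not
depend on the fonts installed at run time; other letters and sizes are
rasterized through the local graphics device at call time.

## Numerical conventions

* Images are vectorized row-major everywhere; basis columns are ordered
  row-major by (vertical, horizontal) frequency pair.
* $\mathrm{sign}(0) = +1$, fixed.
* Thresholding ties at the cut magnitude keep the lower index.
* Basis orthonormality, round-trips and the fast-versus-dense transform
  agreement are held to $10^{-8}$ (exact to $10^{-12}$ at tiny sizes).
* Every stochastic step takes an integer seed; replicate $r$ of a run
  seeded $s$ uses $s + r$ (or the documented cell formula in `run_grid`),
  and seeded functions restore the caller's RNG state.

## Known limitations

* The $\gamma = 64$-versus-512 tension above is the visible symptom of a
  deeper ambiguity: with shrinkage, prediction accuracy is remarkably
  flat across $\gamma \in [64, 1024]$ at large $n$ (differences of a few
  thousandths), so the selected $\gamma$ is sensitive to the evaluation
  noise of the held-out sets. Treat the selected value as "a sparsity in
  the right decade", not a sharp optimum.
* The calibrated additive-Gaussian mechanism cannot realize error rates
  above 50% (no symmetric additive noise can); use `flip` for more
  destructive noise, with the caveat that at 50% flips nothing is
  recoverable by any method.
* The GLM baseline is a plain $\ell_1$ logistic fit; it makes no attempt
  to reproduce any particular legacy implementation's auxiliary terms or
  fixed-point solver.
* `"generalized_inverse"` reverse correlation is $O(m^3)$ and intended
  for small images only.

## A worked example

```{r example, eval = FALSE}
library(revcorrcs)

template <- make_letter_template("S", c(50, 50))
stimuli <- generate_stimuli(10000, c(50, 50), seed = 1)
responses <- simulate_responses(template, stimuli, noise_spec(0), seed = 1)

rc <- revcorr_reconstruct(stimuli, responses)
cs <- cs_reconstruct(stimuli, responses, gamma = 64)$reconstruction
template_r2(rc, template)
template_r2(cs, template)

# the efficiency claim: CS from 10% of the trials
run_subsample_comparison(template, n_full = 10000, fraction = 0.1,
                         gamma = 64, seed = 1)
```
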