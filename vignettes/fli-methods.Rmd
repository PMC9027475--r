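---
title: "Constrained least-squares imputation for expression profiles: methods and design"
author: "fliImpute"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained least-squares imputation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

High-dimensional expression measurements — miRNA panels, bulk and
single-cell RNA profiles — routinely arrive with missing entries: technical
zeros from limited sequencing depth, probes absent from one platform but
present on another, dropped measurements. A classifier trained on complete
reference data cannot be applied directly to such profiles, and retraining
for every missingness pattern is impractical. Imputation fills the gaps so
that one model, fit once on the full feature panel, keeps working.

Because expression features are strongly inter-correlated, a test profile is
well approximated by a combination of complete reference profiles, and the
known entries suffice to estimate the combination.

## The model

Let $A \in \mathbb{R}^{k \times n}$ hold the $n$ complete training profiles
restricted to the test profile's $k$ known features (one column per training
sample), and let $b \in \mathbb{R}^k$ be the known test values. FLI (fast
linear imputation) solves

$$
\min_{w \ge 0,\; \sum_i w_i = 1} \; \| A w - b \|_2^2 ,
$$

and fills each missing feature $j$ with $\sum_i w_i X_{ij}$, where $X$ is
the full training matrix. The simplex constraint is the point of the method:

* **Nonnegativity + sum-to-one** make the completion a convex combination of
  training profiles, so every imputed value lies within the per-feature
  min–max range of the training data. Unconstrained regression has no such
  guarantee and visibly overfits once most features are missing.
* The method is **nonparametric in use**: no neighbourhood size, no penalty
  to tune, no clustering step. The two literature-style comparators shipped
  here (`viper_like`, `scimpute_like`) each need one tuned hyperparameter.

Known entries are never altered: the completion passes them through
bit-for-bit.

## The solver

The sum-to-one constraint is embedded in the objective by augmenting the
system with a stiff penalty row — a row of constant $c$ appended to $A$ and
$c$ appended to $b$ — so that a plain nonnegative least-squares routine
carries out regression and weight normalisation simultaneously. The scale
$c = 10^3 \times$ (largest column norm of $A$) makes the sum deviation of
the penalised optimum below $10^{-6}$.

`nncgls()` solves the nonnegative problem by active-set restarted conjugate
gradient on the normal equations:

* CG runs on the currently free coordinates; active (zero) coordinates are
  masked out of the search direction.
* When a step would cross zero, the full step projected onto the orthant is
  tried first and accepted if it decreases the residual — this retires many
  coordinates per restart, in the manner of gradient-projection CG methods
  from image reconstruction; otherwise the step is truncated at the first
  crossing. Either way CG restarts on the reduced face.
* After each segment the projected-gradient KKT conditions are checked;
  active coordinates with negative gradient are released.
* The start is the uniform vector $(1/n, \dots, 1/n)$ — feasible for the
  simplex and giving the guarantee that the returned objective never exceeds
  the uniform-weight objective. The residual norm is non-increasing along
  the whole trajectory (recorded in `residualTrace`).

Since $n$ (training samples) is much smaller than $k$ (known features), the
Gram matrix $A'A$ and $A'b$ are formed once and every CG iteration works on
an $n \times n$ in-cache system; callers imputing many profiles against one
training matrix can share the full-feature Gram and update it per profile by
subtracting the masked block (`batchImpute()` does this).

**Exact refinement.** Expression matrices produce severely ill-conditioned
Grams (near-duplicate profiles), on which CG resolves the last digits of the
constrained optimum slowly, while the stiff penalty row dominates the
gradient scale. `fliImpute()` therefore uses a short CG warm start (30
iterations) to identify the support, then solves the equality-constrained
KKT system on that face exactly, by block principal pivoting: all negative
primal coordinates leave the face and the most infeasible dual coordinates
enter at once, falling back to safeguarded single exchanges whenever the
total infeasibility count stops decreasing. The refined weights satisfy the
KKT conditions of the original constrained problem to machine precision —
the weight sum is exact, not approximate — and the unit tests verify the
objective against an exhaustive-enumeration QP oracle on small instances.
The same refinement backs the plain-NNLS solves of the spectral-clustering
comparator. If the face systems are too degenerate to solve, the warm-start
CG weights are returned unchanged.

Stopping parameters: warm start 30 CG iterations; KKT tolerance $10^{-10}$
relative to $\|A'b\|$ (tight because the penalty row inflates that
reference); pivoting capped at 400 face solves. These are fixed internal
defaults — the user-facing operation takes no tuning parameters.

Degenerate inputs: an all-missing profile falls back to mean imputation with
a warning; a single-sample training matrix copies that sample; a profile
with nothing missing is returned as-is. Duplicate training rows are allowed;
the optimum is then non-unique and any minimiser is acceptable (tests
compare objectives, never weights).

## Baselines and comparators

* `zeroImpute()` — fills with 0 (no imputation); the degradation reference.
* `meanImpute()` — training column means.
* `regressionImpute()` — unconstrained minimum-norm least squares (SVD
  pseudoinverse, relative cutoff $10^{-10}$). Deliberately unregularised:
  its overfitting at high missingness is part of the comparison.
* `viperLikeImpute()` — lasso selection of neighbouring training samples
  (coordinate descent via glmnet, no intercept) followed by least squares
  with each weight box-constrained to $[0,1]$ (L-BFGS-B). The default
  penalty is chosen by 5-fold cross validation with deterministic folds;
  inside `runSweep()` the penalty is selected once per missing fraction on
  the first masked profile and reused across profiles at that fraction,
  since per-profile cross validation would dominate the runtime without
  changing the comparison.
* `scimputeLikeImpute()` — spectral clustering of the training samples
  (Gaussian affinity with median-distance bandwidth, symmetric normalised
  Laplacian, k-means with fixed seed 0), assignment of each profile to the
  nearest cluster centroid on its known features, then plain nonnegative
  least squares over the cluster members.

Both comparators are simplifications faithful to the published descriptions
of the corresponding methods, not ports of the original codebases — hence
the `_like` names. Their role is the relative comparison in the evaluation
harness; both reduce to plain box-constrained/nonnegative regression in
their degenerate hyperparameter limits, and the tests pin those limits.

## Synthetic data

`genDigits()` renders 28×28 grayscale digit images from hand-coded stroke
templates (one polyline/arc set per digit), with per-image random affine
jitter and Gaussian pixel noise, flattened to 784 features. The defaults —
rotation up to 5°, translation up to 1 px, scale ±5%, noise sd 0.05 —
emulate machine-rendered digit sets on which a linear softmax classifier is
essentially perfect on clean data (held-out accuracy ≈ 1 at these settings);
that near-perfect baseline is the premise of the retention experiments, and
pushing the jitter towards its documented upper bounds (15°, 2 px, ±10%)
breaks linear separability long before it breaks the imputation, which would
confound the two effects. Templates are hand-coded so the package has zero
data dependencies; the claim carried by this generator is
retention-of-accuracy behaviour, not pixel-level equality with any
particular digit set.

`genMVN()` draws correlated multivariate-normal "expression" data:
block-diagonal equicorrelation (defaults $p = 200$, blocks of 20,
$\rho = 0.8$, chosen to emulate strongly inter-correlated expression
panels), an optional per-class mean shift on a class-specific feature
subset, and final scaling of each column to unit variance (no centring, so
the class signal survives).

`applyMissingness()` masks each sample independently: exactly
$\lfloor f p + 0.5 \rfloor$ features (round half away from zero), uniformly
without replacement, reproducible from the seed. Nonuniform,
expression-dependent dropout is out of scope.

What the generators do *not* emulate: batch effects, heavy-tailed count
noise, zero inflation, and expression-dependent dropout. Passing tests on
this synthetic data therefore demonstrate the solver's correctness and the
relative behaviour of the methods under uniform missingness — not
performance on any particular clinical cohort.

## Evaluation harness

`trainSoftmax()` fits multinomial logistic regression on standardised
features (training-set mean/sd; zero-variance features get scale 1) with a
small fixed ridge penalty ($\lambda = 0.01$) so the fit is deterministic and
well-posed at $p > n$. `classificationMetrics()` reports AUC, accuracy and
F1: binary tasks use the standard ROC AUC and positive-class F1; multiclass
tasks use macro one-vs-rest AUC and macro F1 (classes absent from the scored
data are excluded with a warning; an empty-denominator per-class F1 scores
0).

`imputationErrors()` uses the relative Euclidean error per test sample over
the full feature vector, $\epsilon_i = \|\hat x_i - x_i\| / \|x_i\|$, and
reports the mean, population standard deviation and maximum over samples.
On column-standardised data, zero imputation of a fraction $f$ of the
dimensions gives $\epsilon \approx \sqrt f$, so the mean over the default
fraction grid (5%–95%, step 5%) is $\approx 0.673$ — a closed-form anchor
that the tests verify and that pins down both the error definition and the
grid.

`runSweep()` trains the classifier once on the complete training split,
then for each fraction masks the test set (one derived seed per fraction),
imputes with each method, and records classification metrics, error
statistics and per-profile wall times. `summarizeSweep()` reports per-method
unweighted means over the fraction grid, with timing statistics pooled over
all individual imputations.

Problem sizes used by the shipped experiments: 500 digit images (50 per
class), 70/30 stratified split, the 19-point fraction grid, seeds 0–2 —
enough for the retention ordering of the six methods to be stable across
seeds while keeping a full run on a single CPU in the minutes range.

## Numerical and design choices

* Sum-to-one via a stiff penalty row, finished by an exact face solve: the
  combination keeps the solver a plain NNLS routine (the two steps "carried
  out simultaneously") yet delivers an exactly feasible optimum.
* Rounding of mask cardinality: half away from zero; documented because any
  fixed rule works but reproducibility requires naming one.
* Ties in `max.col` classification are broken by first index;
  deterministic.
* No data transformation inside the imputers: imputation runs on the scale
  given. Standardisation exists only inside the classifier.
* No randomness anywhere in the imputers; identical inputs give identical
  outputs. All generator randomness is seed-controlled, and sweep masks
  derive one seed per fraction from the master seed.
* The spectral-clustering comparator fixes its k-means seed (0) as part of
  the method definition, so batch results are reproducible.

## Known limitations

* The training matrix must be complete; missing entries there are an error
  by design.
* Uniform missingness only; expression-dependent dropout is future work.
* The digit generator supports the premise of near-perfect clean
  classification; it is not a substitute for benchmarking on real cohorts
  with batch effects.
* `regressionImpute()` is intentionally unregularised and should not be
  used as an actual imputer; it exists as the overfitting baseline.
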