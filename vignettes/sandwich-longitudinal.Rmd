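---
title: "Robust marginal models for longitudinal data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust marginal models for longitudinal data: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longswe)
```

## The model and its assumptions

`longswe` fits the marginal (population-averaged) linear model for repeated
measures: for subject $i$ with $n_i$ observations,
$y_i = X_i \beta + \epsilon_i$, $\mathrm{cov}(\epsilon_i) = V_i$, with the
$V_i$ left completely unstructured and treated as a nuisance. Coefficients
are estimated by ordinary least squares (working independence), which is
unbiased regardless of $V_i$; all covariance modelling is deferred to the
covariance of $\hat\beta$, estimated by the sandwich form
$S = (X'X)^{-1}\bigl[\sum_i X_i' \hat V_i X_i\bigr](X'X)^{-1}$.

The assumptions are therefore weak: independent subjects, a correctly
specified mean, and enough subjects for the law of large numbers to act on
the meat term. There are no random-effects choices to get wrong, no
iterative fit, and no convergence failures — which is what makes the method
practical when the same model must be fitted at hundreds of thousands of
voxels.

Two plug-ins for $\hat V_i$ are provided:

* **Heterogeneous** (`variant = "het"`): $\hat V_i = e_i e_i'$, each
  subject's own residual outer product. Fully general but noisy — each
  subject's covariance is "estimated" from one vector.
* **Homogeneous** (`variant = "hom"`, default): subjects within a group are
  assumed exchangeable, sharing a common covariance $V_{0g}$ over visit
  categories. Its diagonal is the mean squared residual over the subjects
  observed at that visit ($1/m_{gkk}$ normalisation — deliberately without
  the $m-1$ correction, because small-sample bias is handled separately by
  the residual adjustments); off-diagonals combine a correlation estimated
  from the subjects observed at *both* visits with the marginal standard
  deviations. Under missing data different cells are estimated from
  different subject subsets, so the assembled matrix can be indefinite; a
  spectral repair (negative eigenvalues clamped to zero) is applied
  unconditionally — it is idempotent and leaves PSD inputs untouched, so
  applying it always (not only under missingness) changes nothing on
  complete data while simplifying the code path. With one subject per
  group the homogeneous variant reduces *exactly* to the heterogeneous one,
  a property the test suite asserts for all adjustments.

Visit categories are user-supplied labels, not inferred from times: pooling
across subjects requires knowing which observations are "the same visit",
and only the study design knows that. Times are carried separately and are
used for covariance generation and polynomial bases.

## Small-sample residual adjustments

OLS residuals are shrunk toward zero by the hat matrix, so raw residual
cross-products underestimate $V_i$. The adjustments are the standard
HC-family rescalings, applied to the residuals before either covariance
plug-in: `S0` none, `S1` the global factor $\sqrt{n/(n-p)}$, `S2`
$e_j/(1-h_j)^{1/2}$, `S3` $e_j/(1-h_j)$, with $h_j$ the scalar diagonal of
$X(X'X)^{-1}X'$ (not a per-subject block leverage). `S2` with independent
single-observation subjects reproduces the textbook HC2 estimator exactly —
the test suite verifies this against the independent `sandwich`
implementation. The residual adjustment is applied first and the group
covariance estimated from the adjusted residuals, so the same machinery
serves both variants. The default is `S3`, which in the package's
Monte-Carlo validation is the variant that errs (slightly) on the
conservative side in very small samples while keeping the false positive
rate inside the binomial validity band from roughly 50 subjects upwards in
balanced designs.

## Wald inference and effective degrees of freedom

Contrasts $C\beta = 0$ (rank $q$) are tested with
$\frac{\nu - q + 1}{\nu q}\,\hat\beta'C'(CSC')^{-1}C\hat\beta
 \sim F(q,\,\nu - q + 1)$, the multivariate analogue of a $t$-test with an
estimated covariance: if $CSC'$ behaved exactly like a Wishart matrix with
$\nu$ degrees of freedom, the rescaled statistic would be exactly F. For
$q = 1$ this reduces to $C\hat\beta/\sqrt{CSC'} \sim t_\nu$, and the two
code paths agree to $10^{-10}$ by test.

$\nu$ has to be estimated. The naive choice $m - p_B$ ($p_B$ = number of
pure between-subject columns) ignores the variability of the sandwich
estimator and is anti-conservative in small samples. The package's default
estimator moment-matches $CSC'$ to a Wishart:

1. Each element of $CSC'$ is written as a quadratic form $e'Ae$ in the raw
   residuals, with $A$ block-diagonal over subjects. For the homogeneous
   variant the correlation-based off-diagonal estimator is linearised to its
   cross-moment form ($\hat V_{0gkk'} \approx m_{gkk'}^{-1}\sum e_{ik}e_{ik'}$,
   exact on complete data); residual-adjustment factors are folded into $A$.
2. Under normality, with $\Sigma_e = (I-H)\,\hat V\,(I-H)'$ and $\hat V$ the
   block-diagonal plug-in from the fitted variant, each element has mean
   $\mathrm{tr}(A\Sigma_e)$ and variance $2\,\mathrm{tr}((A\Sigma_e)^2)$.
3. Matching the total element variance of a Wishart$(\nu, \Lambda/\nu)$
   gives $\nu = \bigl[(\mathrm{tr}\,\Lambda)^2 + \mathrm{tr}(\Lambda^2)\bigr]
   / \sum_{ab}\mathrm{Var}\bigl[(CSC')_{ab}\bigr]$, the scalar Satterthwaite
   $2E^2/\mathrm{Var}$ when $q = 1$.

Two exact anchors justify the construction: in the one-group,
one-observation-per-subject, intercept-contrast case the homogeneous-variant
$\nu$ equals $m - 1$ *identically* (the data cancel), which is the correct
Satterthwaite value for a $\chi^2_{m-1}$ variance estimate; and replicating
every subject $r$ times multiplies $\nu$ by $\approx r$. Both are asserted
in the tests. The heterogeneous variant plugs its noisy per-subject outer
products into the same formulas, so its $\nu$ is data-dependent and less
stable — one more reason the homogeneous variant is the default.

Numerical choices: $\nu$ is used as a real number in $F(q, \nu-q+1)$
(continuous df are well-defined; truncation to an integer would only
discard information); $\nu$ is clamped below at $q$ with a warning so that
p-values remain defined in pathological tiny designs, and clamping events
are counted; the computation is split into contrast-specific
response-independent precomputation and a cheap per-response evaluation,
with subjects sharing (group, visit-pattern, design-block) collapsed into
equivalence classes so that complete balanced designs cost $O(n_G)$ rather
than $O(m)$ per response.

## Design construction and covariate splitting

`build_design()` takes a declarative term list (per-group intercepts,
covariates, orthogonal-polynomial time effects) rather than a formula
language; rows are canonicalised to (subject, time, visit) order so block
indexing is deterministic, and rank is checked by singular values at a
relative tolerance of $10^{-10}$ — rank-deficient designs are rejected, not
pseudo-inverted. A time-varying covariate like age should be entered as two
predictors, its subject mean (between) and the subject-centred deviation
(within), via `split_covariate()`: the two components can have genuinely
different effects, and the split also makes working-independence OLS fully
efficient for the within component under compound symmetry —
`relative_efficiency()` computes the analytic GLS/OLS variance ratio showing
this (ratio 1.00 for the within-centred column under CS at any correlation,
for any design; asserted in tests). The orthogonal-polynomial basis is the
one returned by `stats::poly` over each group's observed times; any
orthonormal basis over the visit grid spans the same column space, and the
tests assert that joint Wald statistics are invariant to re-coding the time
effects in the raw power basis.

## Box's test of compound symmetry

Compound symmetry is what would justify the simpler classical analyses, so
the package ships a diagnostic. Box's determinant-based likelihood-ratio
statistic compares the pooled covariance estimate $S$ (one group, Eqs as
above on the complete-case block) to its best-fitting CS structure
($\hat\sigma^2$ = mean diagonal, $\hat\rho$ = mean off-diagonal over
$\hat\sigma^2$ — the constrained MLE, verified in tests against a numerical
likelihood maximiser):
$u = -(1 - c_1)\,\nu \log(|S|/|S_0|)$ with
$c_1 = k(k+1)^2(2k-3)/[6\nu(k-1)(k^2+k-4)]$, referred to
$\chi^2_{k(k+1)/2 - 2}$, reported on the F scale as $u/\mathrm{df}_1$ with
$\mathrm{df}_2 = \infty$. The scaling constants are not trusted blindly:
the suite checks the 2×2 case against an independent numerically-maximised
likelihood ratio and checks the null calibration by simulation (empirical
FPR inside the 95% binomial band over 2,000 voxel replicates under CS
truth).

Missing data are handled by testing the largest usable complete-case block:
the search maximises `n_complete × choose(#visits, 2)` over visit subsets of
size ≥ 2 — the number of subject-level covariance pairs the block supports —
restricted to subsets with at least `#visits + 1` complete subjects (the
minimum for a nonsingular covariance), with ties broken toward more visits.
The mean structure is removed with the same marginal design supplied for the
main analysis, so the covariance being tested is the analysis-model residual
covariance; the covariance df are taken as the complete-case subject count
minus the number of between-subject design columns (the classic $m-1$ for
an intercept-only model). Both FDR (default, recommended) and Bonferroni
corrections are exposed for the voxelwise map.

## The synthetic-data generator

The generator defines the package's study conditions and is first-class,
tested code. It emulates two families:

* **Balanced designs**: $m \in \{12, 25, 50, 100, 200\}$ subjects (groups of
  equal size; 13/12 at $m=25$), $k \in \{3,5,8\}$ visits at times
  $0,\dots,k-1$ (so per-visit covariance parameters are per visit unit),
  with per-group intercepts and orthogonal-polynomial linear + quadratic
  visit effects.
* **An unbalanced three-group design** shaped like a large observational
  aging/dementia imaging study: per-visit subject counts fixed exactly at
  the published table (817 subjects, 3,314 scans; mean scans/subject 4.16,
  4.43, 3.14 in the control, MCI and dementia groups), baseline ages drawn
  per group (76.0 ± 5.0, 74.8 ± 7.4, 75.4 ± 7.5 years), and the 12-column
  model: per-group intercept, centred subject-mean age, subject-centred age,
  and their interaction. Only the marginal per-visit counts are published,
  so attendance is allocated subject-by-subject uniformly at random under
  the exact-marginal constraint; monotone dropout is *not* imposed (the
  emulated protocol itself is non-monotone — the dementia group has no
  month-18/36 visits). Halving (`halve_subjects()`, keep
  $\lfloor m_g/2\rfloor$) produces the nested sub-studies.

Responses are standard normal draws premultiplied by the lower-triangular
Cholesky factor of the subject's covariance (deterministic among the
distributionally equivalent square roots), built from
$\mathrm{var}(y_{ik}) = \alpha_g(1 + \gamma t_k)$ and
$\mathrm{corr}(y_{ik}, y_{ik'}) = \rho(1 - \psi|t_k - t_{k'}|)$. The four
preset rows (CS, Toeplitz, group heterogeneity, visit heterogeneity) match
the validation study's parameter values; for large $\psi|\Delta t|$ the
correlation may go negative, in which case the assembled matrix is
PSD-checked and repaired with a warning — the preset rows never trigger
this, and a test asserts so. In the unbalanced design $t$ is time-in-study
in years (ages enter only through the mean model); whether decaying
correlation should instead follow age separation is ambiguous in principle,
but time-in-study is the natural reading of "per year" decay and is the
documented choice. Signal, when requested, is the subject-centred time
multiplied by a per-group effect size; the Monte-Carlo harness adds it to
the first group only, so both pure visit-effect and group-difference
contrasts see a non-null alternative.

What the generator deliberately does *not* emulate: spatial correlation
between voxels (each response column is independent), non-Gaussian errors,
registration/preprocessing artefacts, or informative missingness (visit
attendance is independent of the response). Passing tests therefore show
calibration and correctness of the estimator under the stated sampling
model, not robustness to those real-data features.

## Monte-Carlo harness and validation scales

`run_rejection_study()` simulates all realisations of a setting as the
columns of one response matrix, so the estimators run in their vectorised
mass-univariate form; substream seeds are derived deterministically from the
master seed per setting, making studies exactly reproducible. Rejection
rates are reported with the binomial confidence interval around the observed
rate and the validity band around the nominal level (an exact 5% test over
10,000 realisations must land in (4.57%, 5.43%) with 95% probability);
`fpr_code()` translates rates to accurate/liberal/conservative calls.

The validation study shipped in `scripts/acceptance.R` and
`tests/testthat/test-acceptance.R` uses 2,000 realisations per setting
(balanced m = 50 under CS ρ = 0.95 and m = 100 under Toeplitz ψ = 0.1/visit)
— enough for a ±0.96-point band at the 5% level while keeping a full run in
tens of seconds; generator-fidelity checks use 4,000–10,000 subjects and
3-s.e. tolerances; the efficiency and design-emulator checks are analytic or
exact. The liberal behaviour of the uncorrected configuration (S0
heterogeneous with naive df at m = 12) is asserted on the between-subject
contrast, where the miscalibration is far outside the band (≈7.4%); the
within-subject contrast shows the same direction but sits too close to the
band edge for a stable assertion at this replication count.

## Degenerate inputs and other numerical choices

* Subjects observed at a visit pair with $m_{gkk'} = 0$ while both visits
  exist: the correlation is set to 0, the cell to 0, with a warning and a
  flag on the estimate (keeps the estimator defined under pathological
  missingness).
* A visit category with no observations at all is an error (it cannot arise
  from `build_design()`, which derives categories from observed rows).
* Saturated observations ($h_j = 1$) make S2/S3 undefined; the error names
  the offending rows.
* Contrast rank is recomputed numerically; linearly dependent rows are
  dropped with a warning.
* The contrast-wise storage path (`return_S = FALSE`) performs the identical
  arithmetic as the full path and stores only the $q \times q$ projections,
  bounding memory at large $V$; agreement is bit-for-bit by construction.
* Voxelwise batching changes results only at the level of BLAS
  tiling/associativity (relative differences ~$10^{-13}$); per-voxel
  numerical failures become NaN with a logged count, and more than 1%
  failures aborts the run.
* Float64 is used throughout the estimator core; NIfTI maps can be written
  float32 on request.

## Known limitations

* Power: with working independence the estimator can be less efficient than
  a correctly specified GLS/mixed model, and the recommended S3-homogeneous
  test is slightly conservative in very small samples (roughly m < 50
  balanced). Splitting covariates recovers full efficiency for
  within-centred components under CS, which bounds the practical loss.
* Inference is population-averaged only; no subject-specific predictions or
  random-effect inference.
* No non-identity working covariance, no GEE iterations, no spatial
  regularisation, no cluster-level random-field inference (FDR or
  Bonferroni over voxels only), and no permutation/bootstrap inference.
* The effective-df estimator treats residuals as normal when matching
  moments; heavy-tailed data will make $\nu$ (like every Satterthwaite-type
  estimate) only approximate.
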