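---
title: "Proportional subtype assignment and risk prediction for RCC: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proportional subtype assignment and risk prediction for RCC: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rccpsa)
```

# The model

Renal cell carcinoma has three main histological subtypes — clear cell
(ccRCC), papillary (pRCC), and chromophobe (chRCC) — yet a substantial
fraction of tumors express molecular features of more than one subtype.
`rccpsa` models a bulk tumor transcriptome as a mixture of three subtype
reference profiles rather than a member of one class.

The reference is a *signature matrix*: for each of k subtype-specific
genes per subtype (3k rows), the median linear expression in each subtype
of a labeled training cohort. Given a sample vector $y$ over the
signature genes on linear scale (TPM, FPKM, or exponentiated microarray
intensities), both $y$ and each signature column are mean-centered and
standardized (sample standard deviation, $n-1$), and $y$ is regressed on
the three standardized columns without intercept by Huber M-estimation.
The standardized coefficients $\theta_i$ are mapped back to the linear
mixing scale,

$$ w_i = \theta_i \, \frac{\mathrm{sd}(y)}{\mathrm{sd}(S_{\cdot i})}, $$

because for an exact mixture $y = \sum_i a_i S_{\cdot i}$ the standardized
regression yields $\theta_i = a_i\,\mathrm{sd}(S_{\cdot i})/\mathrm{sd}(y)$
— without the back-map the columns' scales would leak into the weights and
even noiseless mixtures would not be recovered. Negative weights are then
truncated to zero and the remainder normalized, giving proportions
$(c, p, h)$ with $c + p + h = 1$.

## Goodness of fit and significance

The fit statistic is the Pearson correlation between the fitted and the
observed standardized vector. Its null distribution is obtained by
permuting the sample's standardized values across gene positions $B$
times and re-deconvolving each permuted vector; the P-value uses the
add-one estimator $(1 + \#\{\text{null} \ge \text{obs}\})/(B+1)$, which is
never zero and makes the null distribution uniform on a lattice. The
permutation scheme destroys the gene-to-profile correspondence while
preserving the sample's value distribution, which is the relevant null
("this expression pattern matches the subtype profiles no better than an
arbitrary gene assignment"). Samples with $P_{psa} > 0.05$ are set aside
as non-significant; significant samples whose maximum proportion is below
0.95 are called molecularly heterogeneous. Both cutoffs are configurable
defaults.

A sample whose three weights are all non-positive (typical for pure
noise) has no defined composition; `psa()` reports its proportions as
`NA` with call `"non-decomposable"` but still computes the permutation
P-value, so null-calibration studies cover every replicate.

## The prognostic index

The assigned ccRCC proportion c (the "RCC-R score") is carried into
survival analysis through a Cox linear predictor. The packaged fixed
model is the cubic polynomial

$$ \mathrm{PI}(c) = 14.71\,c - 25.46\,c^2 + 12.21\,c^3 - 1.46, \qquad
   \mathrm{HR} = e^{\mathrm{PI}}, $$

whose maximum on $[0,1]$ is interior (near $c \approx 0.4$): tumors mixing
clear-cell and papillary character carry the highest risk, higher than
either pure class. The constant $-1.46$ is kept verbatim and interpreted
as centering of the linear predictor, so $e^{\mathrm{PI}}$ is a hazard
ratio against the cohort average. `fit_cox_score_model()` refits such
models on new cohorts — cubic polynomials or restricted cubic splines
(truncated power basis, Harrell's quantile knots 0.05/0.35/0.65/0.95 for
four knots) in a Cox model with Efron tie handling — and sets the constant
so the fitted PI has mean zero over the training samples.

## Risk groups

`find_risk_cutpoints()` stratifies a cohort on the PI in the style of a
conditional inference tree with a survival endpoint: at each node the
candidate binary split (midpoints between adjacent distinct PI values
leaving at least 20 samples per side) maximizing the two-sample log-rank
statistic is accepted only if its asymptotic P-value, Bonferroni-corrected
for the number of candidate splits at that node, is below 0.05. Because
exactly three groups are the target, after the root split only the child
with the stronger significant split is split again (a full depth-2 tree
could yield four leaves). Leaves are ordered into good / intermediate /
poor by their crude hazard, events per person-year — a simple,
monotone-in-hazard ordering that is exact for exponential survival.
Values exactly on a learned cutpoint are assigned to the lower-risk
adjacent interval, a documented convention. When no split is significant,
a flagged single-group result is returned rather than an error.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_fold` | 2 | minimum pairwise median fold change (vs *both* other subtypes, pseudocount 1e-6) for a gene to be subtype-specific |
| `alpha` (selection) | 0.05 | Holm-corrected one-sided rank-sum level per pairwise contrast; the Holm family is the fold-passing candidate set of that contrast |
| `k` | 58 | signature genes per subtype (3k = 174 total) |
| `change_tol` | 0.01 | mean per-sample L1 proportion shift counted as a "substantial change" in the iterative size selection |
| Huber `k` | 1.345 | tuning constant (95% Gaussian efficiency); Tukey bisquare (4.685) selectable |
| IRLS `tol`, `maxit` | 1e-8, 1000 | see numerical notes |
| `n_permutations` | 999 | permutation count; minimum 99 enforced |
| `p_cutoff` | 0.05 | significance gate on $P_{psa}$ |
| `heterogeneity_threshold` | 0.95 | unique-assignment gate on the maximum proportion |
| `min_overlap_fraction` | 0.8 | minimum fraction of signature genes present in a cohort |
| tree `alpha`, `min_leaf` | 0.05, 20 | split acceptance level and minimum leaf size |

# The synthetic-data generator

`sim_config()` fixes the study conditions under which the package is
exercised: 2000 genes of which 58 per subtype are markers, 8-fold marker
up-regulation, multiplicative lognormal noise with a 5% coefficient of
variation, 300-sample cohorts of which 30% are composite samples with
Dirichlet(2, 2, 0.3) compositions (mixtures dominated by clear-cell and
papillary character, echoing the reported predominance of cc/p mixing
among heterogeneous tumors), exponential survival with baseline hazard
0.1/year scaled by $e^{\mathrm{PI}(c)}$, and uniform censoring calibrated
numerically to a 30% censored fraction. Marker folds and noise level are
conventional orders of magnitude for differential bulk expression; none
of these defaults is revisited by the tests.

What the generator reproduces: the mixture structure the deconvolution
assumes, scale heterogeneity across genes (lognormal baselines), and
survival driven by the prognostic index. What it does not reproduce:
correlated gene-gene noise, batch and platform effects, compositional
shifts from tumor purity, FFPE degradation, or realistic TCGA expression
distributions. Passing tests therefore demonstrate correctness of the
algorithms under their own model assumptions, not field performance on
real cohorts.

# Numerical choices

* **IRLS.** Huber IRLS with the residual scale re-estimated each
  iteration as MAD/0.6745; convergence when the maximum relative
  coefficient change falls below 1e-8. The iteration cap is 1000: with
  per-iteration scale re-estimation the tail of the iteration is
  geometric but can be slow on noisy samples, and a 200-iteration cap
  produces spurious non-convergence errors on a few percent of realistic
  samples (the reference implementation in `MASS::rlm` shows the same
  trajectory). A near-perfect fit (residual scale below 1e-12) short-
  circuits to the least-squares solution. The inner loop is compiled
  (RcppArmadillo) because the permutation null refits the model ~1000
  times per sample; the compiled path is cross-checked against
  `MASS::rlm` in the tests.
* **Standardization axis.** Each sample is standardized across signature
  genes and each signature column across genes — the intrasample reading
  of "mean-centered and standardized", consistent with deconvolving one
  sample at a time and with scale-free proportions.
* **Degenerate inputs.** Constant sample vectors raise a zero-variance
  error; collinear signature columns raise a singularity error before
  fitting; per-sample failures in a cohort run are recorded in an `error`
  column and only an all-sample failure aborts.
* **Ties.** Gene-ranking ties on fold change break lexicographically by
  gene identifier; Cox models use Efron tie handling throughout.
* **Cross-validated likelihood.** The held-out partial log-likelihood
  uses the Verweij–van Houwelingen construction (full-data likelihood at
  the fold coefficients minus training-fold likelihood), which stays
  defined for arbitrarily small folds including leave-one-out; the CV
  C-index is Harrell's concordance of pooled held-out linear predictors.
  Fold assignment is stratified by event status and seeded.
* **Cutpoint search.** Asymptotic $\chi^2_1$ log-rank P-values with
  Bonferroni correction over the candidate splits of a node stand in for
  the permutation test of a full conditional-inference implementation;
  at the sample sizes involved (hundreds) the asymptotic and permutation
  answers coincide for practical purposes.

# Design decisions taken where the design was open

* Robust regression is Huber M-estimation without intercept; the
  truncate-then-renormalize handling of negative weights enforces
  non-negative proportions post hoc rather than constraining the fit.
* Raw weights are reported on the linear mixing scale. Proportions, fit
  statistic, P-value and call are invariant to positive rescaling of the
  sample; the raw weights themselves necessarily track the sample's
  scale.
* The "substantial change" criterion of the iterative signature-size
  selection is formalized as the mean per-sample L1 shift of the
  proportion vectors between consecutive candidate sizes, with the
  selected size the largest still moving the deconvolution by at least
  `change_tol`.
* Per-sample permutation seeds derive from the master seed plus the
  sample index, making cohort results independent of evaluation order
  and reproducible under parallelization.

# Problem sizes used by the test suite

The suite exercises: signature construction at k = 58 on a 1000-gene,
90-sample reference; proportion conservation over 1000 deconvolved
mixtures; noiseless recovery on a 174-gene signature and noisy (5% CV)
recovery over 200 samples; permutation-null calibration over 500
pure-noise replicates at B = 999; Cox coefficient recovery over 20 seeds
at n = 800 with 30% censoring; and cutpoint recovery over 20 seeds at
n = 600 with hazard strata 1/4/10. These sizes are the package's chosen
verification conditions and complete in a few minutes on one core.

# Known limitations

* The packaged 174-gene signature is synthetic (generated by this
  package's simulator) and is a format/behavior stand-in, not a
  biological reference; real use requires a signature derived from real
  labeled cohorts.
* The published risk-group PI cutpoints are not public; cutpoints must be
  learned on a cohort with survival and only then transferred.
* Proportions are relative to the three subtype profiles only — no
  immune/stromal compartment, no purity correction.
* The permutation scheme is one concrete instantiation of a
  goodness-of-fit null; other reasonable nulls (e.g. resampling genes
  from the full transcriptome) would give different absolute P-values.
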