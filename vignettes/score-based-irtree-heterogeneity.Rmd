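---
title: "Score-based heterogeneity tests and partitioning for IRTree models"
author: "IRTreeScore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Score-based heterogeneity tests and partitioning for IRTree models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(IRTreeScore)
```

## The model

Likert responses confound the trait a scale is meant to measure with
content-independent response styles: some respondents avoid the scale
midpoint, others prefer the endpoints.  Item response tree (IRTree) models
handle this by decomposing each observed category into a sequence of binary
pseudo-decisions.  For a six-point scale (categories 0--5) the package uses a
three-stage tree:

1. **Agreement** (node 1): disagree (0, 1, 2) vs. agree (3, 4, 5),
   driven by the substantive trait $\theta$ alone:
   $\mathrm{logit}\, p(Y_{1i}=1) = \theta + \delta_{1i}$.
2. **Nonmoderate choice** (nodes 2/3, one per branch): a nonmoderate
   (0, 1 resp. 4, 5) vs. moderate (2 resp. 3) category, driven by the
   nonmoderate response style $\eta^{nm}$ and the trait:
   $\mathrm{logit}\, p(Y_{2i}=1) = \eta^{nm} - \alpha^{nm}\theta + \delta_{2i}$
   on the disagree branch and
   $\mathrm{logit}\, p(Y_{3i}=1) = \eta^{nm} + \alpha^{nm}\theta + \delta_{3i}$
   on the agree branch.  The trait enters with opposite signs because
   stronger agreement pushes *away* from clear-cut disagreement and *toward*
   clear-cut agreement.
3. **Extremity** (nodes 4/5): extreme (0 resp. 5) vs. nonextreme (1 resp. 4),
   analogous with $\eta^{e}$ and loading $\alpha^{e}$.

A category's probability is the product of the node probabilities along its
branch; nodes off the branch are *structurally missing* and contribute a
factor of 1 to the likelihood.  Structural missingness is kept distinct from
person-level missingness throughout (both drop out of the likelihood, but
only the latter is a data-quality matter).

The loadings $\alpha^{nm}, \alpha^{e} > 0$ measure the weight of the trait in
the nuanced within-branch choices relative to its fixed weight of 1 at the
agreement node.  In the default Rasch-style variant they are shared across
items and the latent covariance $\Sigma$ is free; the item-specific variant
frees all five loadings per item and fixes the trait variance at 1 instead
(implemented for a single trait dimension).  Response-style loadings are
fixed at 1 by design: styles are content-independent, so their weight should
not vary by item.

## Estimation

`fitIRTree()` maximizes the marginal likelihood with the latent vector
integrated out on a fixed (non-adaptive) Gauss-Hermite product grid.
Internally the latent vector is written as $z = L u$ with $u$ standard normal
and $L$ the (log-diagonal) Cholesky factor of $\Sigma$, so the prior carries
no parameters and every free parameter — loadings, intercepts, $L$ — sits in
the measurement part.  Two deterministic algorithms maximize the identical
objective:

* `method = "em"` (default): EM whose M-step takes a capped quasi-Newton
  step on the expected complete-data log-likelihood (a generalized EM step),
  so the marginal log-likelihood is non-decreasing across iterations
  (`@loglikPath` records it).  Convergence: maximum absolute parameter
  change below `tol` (default .001).
* `method = "bfgs"`: direct quasi-Newton on the marginal log-likelihood with
  the analytic score.  It reaches the same optimum (a unit test asserts
  this) with a much smaller gradient norm at termination, which is why the
  simulation harness and all refit-heavy routines use it.

A stochastic (Metropolis-Hastings Robbins-Monro style) estimator is *not*
provided: the downstream tests operate on any consistent ML estimate, and
only a deterministic estimator gives a reproducible test suite.

The whole likelihood/score stack is dense matrix algebra (one GEMM and one
`exp` per objective evaluation), which is why the package has no compiled
code: with a tuned BLAS a 1000-person, 30-pseudo-item, 625-node evaluation
costs a few tens of milliseconds.

**Quadrature resolution.** Defaults are 11 points per dimension for up to 3
latent dimensions and 7 for 4.  Accuracy degrades when latent variances are
large (the study design uses trait variance 2.89): at unit scale 11 points
reproduce person log-likelihoods to well under $10^{-3}$ against a doubled
grid, while heavy-tailed scales need 20+ points for that accuracy.  This
matters little for the invariance tests — whatever the grid, the fitted
model is an internally consistent parametric family, its score identity
holds at the quadrature MLE, and the bridge asymptotics apply — but users
reporting loading estimates at large latent variances should raise
`quadPoints`.  The simulation harness deliberately runs at 5 points per
dimension (625 nodes in 4 dimensions) to keep full Monte-Carlo cells
tractable; the Type-I error results in the acceptance suite confirm the
calibration claim survives this choice.  Very coarse grids (3 points with
variance ~3) can create spurious optima during subgroup refits and are not
used anywhere.

## Score-based invariance tests

At the MLE $\hat\Psi$ the total score vanishes, but its per-person
contributions $s(\hat\Psi; y_v)$ need not: ordering them by a person
covariate and accumulating,
$B(t) = \hat I^{-1/2} N^{-1/2} \sum_{v \le \lfloor Nt \rfloor}
s(\hat\Psi; y_{(v)})$
behaves asymptotically as a vector of independent Brownian bridges under
parameter invariance.  $\hat I$ is the *uncentered* outer product of
gradients $(1/N)\sum_v s_v s_v^\top$ — at the MLE the mean score is zero, so
centering is asymptotically irrelevant; the uncentered form is what "observed
cross-product of the gradients" means operationally, and the unit tests pin
this convention.  For subset tests (e.g. only $\alpha^{nm}$) the default
decorrelates with the subset block of $\hat I$; full decorrelation followed
by column selection is available as a non-default option.

Functionals of $B$ give the test statistics: DM, CvM and maxLM for metric
covariates; WDMo and maxLMo evaluated at the $m-1$ category boundaries for
ordinal ones; LMuo for unordered categories.  Numerical choices:

* **Ties.** Persons sharing a metric covariate value form one block; all
  statistics are evaluated at block boundaries only, since the within-block
  order is arbitrary and must not affect results (a property test shuffles
  within blocks).
* **maxLM trimming** defaults to $t \in [0.1, 0.9]$, the standard choice for
  sup-LM statistics.
* **LMuo scaling.** The per-category increments are scaled by
  $(t_l - t_{l-1})^{-1}$, summed over all $m$ increments (the process is
  pinned at 0 at both ends), which yields the $\chi^2((m-1)k)$ null the
  analytic p-value uses.  An unscaled variant is available behind
  `scaleLMuo = FALSE` for sensitivity checks but has no analytic p-value.
* **Rank deficiency.** The inverse square root uses a symmetric
  eigendecomposition with an eigenvalue floor of $10^{-10}$ times the
  largest eigenvalue; anything below the floor raises an error advising a
  smaller subset rather than silently regularizing.
* **Terminal value.** $B(1) = 0$ holds exactly only at the exact MLE; in
  practice its magnitude is bounded by the optimizer's terminal gradient
  norm propagated through $\hat I^{-1/2}N^{-1/2}$, and the tests assert
  exactly that bound rather than an absolute epsilon.

p-values are analytic where a closed form exists — DM via the Kolmogorov law
of the bridge supremum with independence across the $k$ decorrelated
components; WDMo via iterated Gaussian integration of the bridge's Markov
transitions across the boundaries (grid-exact, no simulation); LMuo via the
chi-square survival function — and Monte-Carlo otherwise (CvM, maxLM,
maxLMo), with 10,000 bridge paths on a 1,000-point grid by default and the
seed recorded in the result.  Tests for $\alpha^{nm}$ and $\alpha^{e}$ are
run separately with no multiplicity correction, matching the two-p-values
design of the simulation studies.

## Partitioning

After a significant test, `findCutpoint()` profiles the summed log-likelihood
of two *independently refitted* models (all item parameters and $\Sigma$
free on each side) over every admissible cutpoint — boundaries between
distinct covariate values leaving at least `minSize` (default 300) persons
per side — and selects the maximizer.  `partitionIRTree()` applies this
recursively: test, split, refit, retest inside the subgroups until
non-significance, the size floor, or `maxDepth`.  By default only the
subsets that triggered the parent split are retested in the children.

Design choices worth knowing:

* Split selection is by summed log-likelihood, not by the location of the
  score-process maximum.
* $\Sigma$ *is* re-estimated on each side at every candidate (the refits are
  complete); warm starts from the pooled estimate keep this affordable.
* With hundreds of distinct metric values the profile over all candidates is
  expensive ($2 \times$ candidates full refits); `maxCandidates` thins the
  candidate set to cutpoints evenly spaced in the left-subsample fraction.
  The scaled harness uses 9 candidates; `Inf` (every admissible boundary) is
  the default for data analysis.
* Categorical covariates are split by exhaustive binary partition of the
  category set for up to 6 categories; more categories are rejected rather
  than silently approximated.

## The synthetic-data generator

`simulateStudyData()` emulates a two-trait design: 6 or 10 six-category
items, the first half loading on trait 1 and the rest on trait 2; latent
covariance with trait variances 2.89 and 1.44 (correlation .5) and
response-style variances 1.00 and 2.25 (correlation .5), traits and styles
uncorrelated; intercepts uniform on $(-1, 1)$ at the agreement node,
$(-1, .5)$ at the nonmoderate nodes and $(-2.5, -1.5)$ at the extremity
nodes; covariates either two balanced groups, uniform$(20, 80)$ metric with
a change point at 40 (focal share 1/3), or ordinal 1--5 with uniform or
skewed (.1, .1, .35, .35, .1) categories and the change between 3 and 4.
Heterogeneity adds $\pm.2$ or $\pm.5$ to both loadings (or one, by option)
in the focal group.

Item parameters are drawn from a *test-length-keyed* seed (77000 + number of
items), not the cell seed, because the design holds them fixed across cells
of the same length; person, covariate and response draws come from a
hierarchical cell seed $\to$ replicate seed $\to$ component seed stream so
any single replicate is reproducible in isolation.

What the generator does **not** emulate: real rating data has
non-logistic item response functions, person-level missingness, local
dependence between items, and covariates correlated with the traits.
Passing tests on these simulations therefore validate the statistical
machinery under the stated model, not robustness to model misspecification.

## Scaled experiment sizes

The full factorial of the original design (up to 2000 persons, unknown —
surely large — replication counts per cell) is a long-running mode the
package supports but does not run by default.  The shipped acceptance suite
uses cells the package's own tests can afford: 50 replications at $N = 500$
for Type-I error, 12--40 replications at $N = 1000$ for power, 4--8
replications with a 9-candidate profile for cutpoint recovery, all at 5
quadrature points per dimension.  At these sizes the binomial uncertainty of
a rejection rate is a few percentage points, which is why the suite asserts
interval membership and orderings rather than point values.

## Known limitations

* Non-adaptive quadrature: person log-likelihood accuracy drops for extreme
  responders when latent variances are large (see above).
* The item-specific loading variant is implemented for a single trait
  dimension only.
* A multigroup variant with free latent means and equality constraints
  across groups (useful for separating intercept shifts from latent-mean
  shifts) is out of scope; subgroup intercept differences should be
  interpreted with that confound in mind.
* Single-covariate partitioning per call; looping over covariates and any
  multiplicity correction across them is the caller's responsibility.
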