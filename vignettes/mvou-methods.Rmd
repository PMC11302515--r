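---
title: "Multivariate OU models on phylogenies: models, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate OU models on phylogenies: models, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvou)
```

## The model

`mvou` models a suite of $k$ continuous traits $y(t) \in \mathbb{R}^k$
evolving along a rooted, time-calibrated phylogeny under the multivariate
Ornstein--Uhlenbeck stochastic differential equation

$$ dy(t) = -A\,\bigl(y(t) - \theta(t)\bigr)\,dt + \Sigma_{yy}\, dW(t), $$

where $A$ is the $k \times k$ drift (rate-of-adaptation) matrix,
$\theta(t)$ the primary optimum (a step function over selective regimes
painted on branches), and $\Sigma_{yy}$ the diffusion factor whose square
$\Sigma_{yy}\Sigma_{yy}^\top$ is the covariance of the undirected
stochastic perturbations.  Three families are supported:

* **BM** ($A = 0$): pure drift, no optimum; variance grows linearly.
* **OUOU**: all traits mean-revert; the eigenstructure of $A$ encodes how
  traits pull one another toward their optima.  Interpretation follows the
  standard grid: diagonal vs. non-diagonal $A$ (adaptive interactions) and
  diagonal vs. non-diagonal $\Sigma_{yy}$ (correlated noise).
* **OUBM**: responses $y$ follow an OU pull toward $\psi + Q\,x$ where the
  predictors $x$ evolve as Brownian motion.  This hierarchical model is a
  single OU process on the stacked state with the singular block drift
  $\begin{pmatrix} A & -AQ \\ 0 & 0 \end{pmatrix}$, optimum $(\psi, 0)$ and
  block-diagonal diffusion — `embed_oubm()` constructs exactly this
  embedding, and all simulation and likelihood code goes through it, so
  singular drift is a first-class citizen.

Along a branch of length $t$ the transition is Gaussian with propagator
$F = e^{-At}$, offset $(I - F)\theta$ and covariance
$V(t) = \int_0^t e^{-As}\,\Sigma\Sigma^\top e^{-A^\top s}\,ds$
(`branch_moments()`).  Half-lives $t_{1/2} = \ln 2 / \mathrm{Re}(\lambda_i)$
of the eigenvalues of $A$ are reported in tree-height units and as a
percentage of tree height (`half_lives()`); a nonpositive real part flags a
non-adaptive direction rather than erroring.  The stationary covariance
solves the Lyapunov equation $AS + SA^\top = \Sigma\Sigma^\top$
(`stationary_covariance()`), solved through its Kronecker vectorization —
exact and cheap at the dimensions used here ($k \le 10$ or so).

## Likelihood: one pruning pass, exact GLS profile

The joint tip distribution is Gaussian, so the log-likelihood is available
in closed form.  `loglik_pruning()` computes it in a single post-order pass
(cost linear in the number of tips) by propagating the subtree density as a
quadratic form *jointly* in the unobserved node state $x$ and in the stacked
vector $z$ of all parameters entering the mean linearly (optima per regime,
OUBM intercepts, the root state):

$$ \log f(\text{subtree} \mid x, z) = x^\top L x + (Mz + m_0)^\top x
   + z^\top R z + r_1^\top z + r_0 . $$

Integrating each child state out of this form has a closed-form update, and
at the root the likelihood is an explicit quadratic in $z$.  This yields two
things at once: the exact likelihood at given parameters, and the exact
generalized-least-squares (GLS) profile of every mean parameter
(`gls_linear()`) — the maximizer of a quadratic — so the numerical optimizer
only ever searches over the structural parameters (drift and diffusion
cells).  The independent check is `full_joint_moments()` /
`dense_loglik()`, a deliberately brute-force $O(n^2)$ construction of the
stacked tip mean and covariance by path composition; the test suite fuzzes
hundreds of random models across all three families, with and without
measurement error, and requires agreement to $10^{-8}$.

Branch moments inside the engine come from the eigendecomposition
$A = P\,\mathrm{diag}(\lambda)\,P^{-1}$ with
$V(t) = P\bigl[\tilde S_{ij}\,(1 - e^{-(\lambda_i+\lambda_j)t})/(\lambda_i+\lambda_j)\bigr]P^\top$,
switching to the limit $\tilde S_{ij}\,t$ when
$|\lambda_i+\lambda_j|\,t < 10^{-10}$ — this covers singular drift, hence
the OUBM embedding, with no special casing.  Complex eigensystems are
handled in complex arithmetic (the plain transpose, not the conjugate one,
appears in the $V$ formula; results are real up to rounding).  Only
defective (non-diagonalizable, eigenvector condition number above $10^8$)
drift falls back to a matrix-exponential construction: the augmented
$2k \times 2k$ exponential for general $A$, or the overflow-free identity
$V(t) = S - F S F^\top$ with $S$ the Lyapunov solution when $A$ is stable.

Numerical guards are deliberate errors, never silent regularization: a
singular covariance on a terminal branch (typically a very short tip
branch) raises an error that advises adding measurement error, which is the
mechanism that genuinely removes the singularity; zero-length *internal*
branches are handled exactly by a deterministic substitution step, and
multifurcations are handled natively by the recursion.

## Constrained drift structures and packing

A hypothesis is a `model_spec`: family, an `a_mask` on $A$, diffusion
factor classes, regimes and a root policy.  Masks are $k \times k$ grids
over `"0"` (fixed zero), `"+"` (positive) and `"?"` (free), with named
classes (diagonal, triangular, symmetric positive definite, eigendecomposable
with real or positive eigenvalues, fully free, custom).  `pack()`/`unpack()`
map any real vector to a mask-conforming matrix: positivity via the
exponential map, SPD via a triangular-factor square, and the decomposable
classes via eigenvalues (exp-mapped for the positive variant) and
column-normalized eigenvectors; a near-singular eigenvector matrix
(reciprocal condition below $10^{-8}$) is repaired and penalized so the
optimizer steers away rather than crashing.  When a positive diagonal is
additionally requested for a decomposable class, the exponential is applied
to the diagonal *after* the matrix is rebuilt from its eigendecomposition
parametrization; the realized matrix then carries the positive-diagonal
constraint (its eigenvalues may no longer all be positive, which is the
documented price of that construction).  For OUBM the packed slots carry the
compound $B = -AQ$ directly — estimating $B$ in the optimizer and
recovering $Q = -A^{-1}B$ is markedly better behaved than iterating GLS
over $Q$.

`ferula_model_registry()` ships eight ready-made five-trait OUOU
specifications encoding nested hypotheses about fruit-functional modules
(protection, dispersal, provision); with a diagonal diffusion factor their
parameter counts are 23, 21, 21, 19, 22, 24, 15 and 35, and an
upper-triangular factor adds exactly $k(k-1)/2 = 10$.

**Root policy.** The default for OU families is `root_equals_optimum`: the
root state equals the root-regime optimum (for OUBM, $\psi + Q x_0^{(x)}$
with a free predictor root), so no extra parameters are spent on the root.
This choice reproduces all eight registry parameter counts above, which is
why it is the default; `free_root` and `stationary_root` (root drawn from
the stationary distribution) are available.  BM always uses a free root
(the optimum does not enter its mean).  Degrees of freedom count mask
cells, diffusion cells and the mean parameters implied by the policy;
`n_obs` for the AICc is `n_tips * n_traits`.

## Estimation, model selection, uncertainty

`fit()` runs multi-start numerical optimization over the packed structural
vector, profiling all mean parameters by GLS at every evaluation: a coarse
Nelder--Mead stage (relative tolerance $10^{-6}$, capped iterations)
followed by a BFGS polish at $10^{-8}$.  Starts are spec-conforming random
draws in packed space (rates biased toward order 1–10 on unit-height
trees); a user-supplied start and a start seeded from a preliminary
positive-eigenvalue decomposable fit are optional.  All per-start
log-likelihoods are retained, and a spread above 2 log-units triggers a
warning to run more starts — multi-modality is real in these likelihoods.
For BM without measurement error the closed-form GLS/ML estimate is used
directly and a singular phylogenetic covariance is reported as an
infinite-AICc flag instead of an error.

`model_select()` ranks candidates by AICc
($-2\ell + 2d + 2d(d+1)/(N-d-1)$) and attaches plausibility bands relative
to the best model: differences up to 7 are plausible, 7–14 equivocal, above
14 implausible.  Exact ties rank the smaller parameter count first, then
the lexicographically smaller name.  `parametric_bootstrap()` resimulates
from the fitted parameters, refits, and reports marginal 2.5%/97.5%
quantiles of every scalar summary (optima, root, half-lives, drift cells,
diffusion covariance, OUBM regressions); failed replicate refits are
excluded and counted.

## The synthetic-data generator and the identifiability pipeline

The generator defines the study conditions.  Trees are pure-birth (Yule):
exponential waiting times with rate proportional to the number of open
lineages, the splitting lineage uniform, growth cut at the $n$-th
speciation so the tree is conditioned on its tip count — and then rescaled
to height 1, which makes rates, half-lives and sample sizes comparable
across tree sizes.  (The conditioning convention — cut at the moment the
count is reached, tips share that time point — is documented here because
samplers differ in how they condition; after unit-height rescaling the
downstream properties tested are insensitive to it.)  Trait simulation is
exact, never Euler-stepped: a pre-order recursion draws each child from the
closed-form branch transition; a fixed seed gives bit-identical output,
and per-ingredient substreams are derived from one master seed.
Measurement error is additive independent Gaussian noise per tip, with the
same specification object (`me_spec()`) used for corruption and for the
likelihood.

`run_identifiability_study()` is the simulation--reestimation loop: per
replicate it simulates tree + traits (+ measurement error), fits every
candidate, records the winner ("selected" means *strictly* smallest AICc;
exact ties count for no candidate and are tallied separately), and scores
recovery of the true specification with the squared error metrics
$(x - \hat x)^\top (x - \hat x)$, optionally over $x^\top x$ — applied to
vectorized matrices jointly, not cell by cell, because decomposition-based
parametrizations correlate the cell estimates.  The Euclidean form is for
parameters whose truth is the zero vector (ancestral states, optima at the
origin), where the relative form is undefined.  Replicates with any failed
fit are discarded, logged and redrawn until the target count of successes,
with the attempt count reported — numerical failures are informative data
(they concentrate at large trees without measurement error, where short
tip branches make tip covariances nearly singular).

**Study conditions used by the test suite** (chosen once, as realistic for
unit-height trees, and stated here because the tests' meaning depends on
them): the 4-trait independent-OU recovery and identifiability checks use
$A = \mathrm{diag}(2, 1, 4, 0.7)$ — half-lives between 17% and 99% of tree
height — unit diagonal diffusion and optima $(1, -1, 0.5, 2)$; the OUBM
truth uses $A = \mathrm{diag}(2, 1)$, $Q = \bigl(\begin{smallmatrix}1 &
0.5\\ -0.5 & 1\end{smallmatrix}\bigr)$, unit diffusions; recovery is scored
at $n \in \{64, 512\}$ with 25 replicates, family identifiability at
$n = 128$ with 20 replicates and 2 starts per fit.  The five-trait
diagonal-vs-block contrast uses rates matching half-lives of 1.3–30% of
tree height for the diagonal truth, moderate block couplings for its
rival, diffusion scaled to unit stationary variance, per-trait measurement
variance 0.25, and 10 replicates on 78-tip trees.  These sizes keep the
suite's statistical checks meaningful (binomial/Monte-Carlo error is
quoted next to each band in the tests) while remaining desk-scale.

What the generator emulates — and what it does not: it reproduces the
statistical structure of comparative datasets (shared-ancestry covariance,
regime switching, replicate-based measurement noise), but real data add
phylogenetic error, non-Gaussian tails, missing values and
non-ultrametric sampling, none of which are simulated.  Passing the suite
therefore validates the estimator on its own model class, not robustness
to model violation.

## Pooled measurement error from replicates

With few replicates per species, species-specific measurement variances
are not estimable; `pooled_within_species_variance()` instead assumes a
common within-species variance per trait and estimates it as a weighted
average of per-species sample variances.  The default weight is the
replicate count $n_i$ (the literal sample-size weighting used with
mericarp-type replicate data); the classical pooled estimator's $n_i - 1$
weighting is offered alongside, and the two differ only when replicate
counts vary.  Species with one replicate contribute nothing to the average
but still receive the pooled value.  `me_spec_from_pooled()` turns the
vector into a per-tip diagonal specification, optionally divided by each
species' replicate count when tip values are species means.

For simulation studies on trees larger than any empirical dataset,
`sample_me_variances()` draws per-trait measurement variances i.i.d. —
by default resampling with replacement from a supplied empirical vector
(e.g. the pooled variances above), with a log-normal fallback when none
is given.  This is a deliberately simple, configurable stand-in for an
empirical sampling scheme: the distribution of measurement variance in
real collections is study-specific, so the generator exposes the choice
rather than hard-coding one.

## Known limitations

* Regime paintings are inputs; no stochastic mapping or regime search.
* No missing-data marginalization; every tip needs every trait.
* Oscillatory (complex-eigenvalue) drift is computed correctly but only
  reported through eigenvalues/half-life real parts, with no dedicated
  diagnostics.
* AICc's behavior under hierarchically correlated observations is itself
  an open question; the 7/14 bands are rules of thumb imported from
  independent-data practice and should be read as such.
* The root state of BM is not consistently estimable; its recovery error
  plateaus with tree size by design, not by defect.
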