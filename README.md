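# mvou

Multivariate Ornstein–Uhlenbeck models of continuous trait evolution on
phylogenies: exact simulation, pruning likelihood, constrained
maximum-likelihood estimation, AICc model selection, measurement error,
parametric bootstrap, and simulation–reestimation identifiability studies.

## Who this is for

Comparative biologists asking *how* a suite of traits evolves jointly:
are traits drifting (Brownian motion), adapting toward optima (OUOU), or
tracking optima that themselves drift with predictor traits (OUBM)?  And
statisticians who want to know whether such hypotheses are actually
distinguishable at their sample size before believing a model choice.

## The model

Traits $y(t) \in \mathbb{R}^k$ evolve along the branches of a rooted tree
under

$$dy(t) = -A\,(y(t) - \theta(t))\,dt + \Sigma_{yy}\,dW(t),$$

with drift matrix $A$ (rates of adaptation; its eigenstructure encodes
trait interactions, its eigenvalue half-lives $\ln 2/\lambda$ the
persistence of ancestral signal), regime-dependent optima $\theta$, and
diffusion $\Sigma_{yy}\Sigma_{yy}^\top$.  $A = 0$ is Brownian motion; the
hierarchical OU/BM model (responses tracking Brownian predictors through
the optimal regression $Q$) embeds as a single OU process with a singular
block drift.  Hypotheses are expressed as structural masks on $A$
(diagonal, triangular, eigendecomposable, custom zero/positive/free
grids) and on the diffusion factor.  The likelihood is computed exactly
by post-order pruning in one pass, with every optimum and root state
profiled out by GLS; model selection uses
AICc $= -2\ell + 2d + 2d(d+1)/(N-d-1)$ with $N =$ tips × traits.

## Worked example

```r
library(mvou)
set.seed(1)

## a unit-height pure-birth tree and a 2-trait independent-OU truth
tree <- rescale_to_unit_height(simulate_pure_birth(64, seed = 7))
spec <- model_spec("OUOU", k = 2, a_mask = a_mask(2, "Diagonal"),
                   sigma_class = "Diagonal", name = "OUOUs1")
truth <- model_params(spec, A = diag(c(2, 1)), Sigma_yy = diag(2),
                      theta = c(1, -1))
traits <- simulate_traits(tree, NULL, truth, seed = 11)

## fit the true model and a Brownian rival, rank by AICc
bm <- model_spec("BM", k = 2, sigma_class = "Diagonal", name = "BM")
tab <- model_select(tree, NULL, traits, list(OUOUs1 = spec, BM = bm),
                    n_starts = 3, seed = 2)
tab[, c("model", "loglik", "dof", "aicc", "delta_aicc", "band")]
#>    model    loglik dof     aicc delta_aicc      band
#> 1 OUOUs1 -45.45423   6 103.6027    0.00000 plausible
#> 2     BM -54.18886   4 116.7029   13.10026 equivocal

fit1 <- attr(tab, "fits")$OUOUs1
round(fit1$derived$half_lives$percent_tree_height, 1)
#> [1] 25.4 57.5
```

The selection table says the mean-reverting model is preferred while the
Brownian alternative lands at the top of the equivocal 7–14 AICc band —
at 64 tips this contrast is real but not decisive, which is exactly what
the identifiability machinery below quantifies.  The fitted half-lives
(25% and 58% of tree height, against a truth of 35% and 69%) illustrate
both the reading — the faster trait forgets its ancestral state roughly
twice as quickly — and the sampling noise in drift estimates at this
tree size.

To ask whether two hypotheses are distinguishable at all at a given
sample size, run the simulation–reestimation pipeline
(`run_identifiability_study()`): it simulates under a known truth,
refits all candidates, and reports the fraction of replicates in which
the true model strictly wins the AICc comparison, alongside
parameter-recovery errors.

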