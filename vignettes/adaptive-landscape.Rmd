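---
title: "Inferring macroevolutionary adaptive landscapes with peakscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring macroevolutionary adaptive landscapes with peakscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

peakscape reconstructs the adaptive landscape of continuous (typically
morphometric) traits on a time-calibrated phylogeny. The workflow it
implements is the one used in comparative studies of adaptive radiations:
size-correct a multivariate trait table by phylogenetic regression, reduce
it to principal axes of evolutionary covariation, test which axes carry
more structure than chance, fit competing models of trait evolution to the
axis scores, search for adaptive-peak shifts without a priori hypotheses,
and check the preferred models against the accumulation of disparity
through time — all replicated over a posterior sample of chronograms so
that phylogenetic uncertainty propagates into every summary.

This vignette documents the models, the estimation choices, the design
decisions taken where the methods literature leaves options open, and what
the synthetic data generator does and does not emulate.

## Trees

All functions take standard `ape` `"phylo"` objects. Chronograms are
expected to be ultrametric (contemporaneous tips); the
Ornstein-Uhlenbeck-based likelihoods check this with a relative tolerance
of 1e-6 of tree height and refuse non-ultrametric inputs, because their
covariance formulas condition on tips being sampled at the same time.
Trees are rescaled to unit height (`scale_to_unit_height()`) before
analysis. Rescaling is interpreted as root-to-tip *height* = 1 rather than
summed branch length = 1: height scaling is what makes rate (`sigma2`, per
unit time) and selection (`alpha`, per unit time) parameters comparable
across chronograms of different depths, and it puts internal-node times on
the same relative [0, 1] axis used by the disparity-through-time analyses.

The Brownian covariance structure is the shared-path matrix `C` with
`C[i, j]` the root-to-MRCA path length of tips i and j. Matrices are
returned in canonical (lexicographic) tip order so they are comparable
across trees with the same tip set.

## Trait preparation

Measurements are natural-log transformed (only relative scales matter
downstream; the base is configurable) and averaged within species. Each
trait is then size-corrected by a *phylogenetic* regression on log
standard length: GLS with error covariance proportional to `C`, i.e.
Brownian errors, equivalent to regression through phylogenetically
independent contrasts. Size correction is per-variable simple regression —
one trait at a time against size — and ratio-type variables (fineness and
aspect ratios) go through the same uniform procedure as lengths and areas.
Residuals are returned on the log scale; their GLS-weighted mean is zero
by construction.

## Phylogenetic PCA and the permutation axis test

`phylo_pca()` decomposes the evolutionary covariance matrix
`R = (X - 1a)' C^-1 (X - 1a) / (n - 1)`, where `a` is the GLS estimate of
the ancestral (root) state. Covariance mode is the default because the
inputs are already residuals on a common log scale; correlation mode is
available. Scores are species positions relative to the ancestral state.
On a star phylogeny with equal branch lengths the procedure reduces
exactly to ordinary covariance PCA, which is one of the package's
acceptance checks.

Three conventions keep axes comparable across trees and permuted data
sets, where eigenvector sign and near-ties in eigenvalues would otherwise
scramble summaries:

* within each axis, the loading of largest magnitude is made positive;
* axes of each posterior tree are matched to the summary-tree axes by
  maximal absolute correlation between loading vectors (greedy in axis
  order);
* loadings are compared on absolute values in the permutation test.

`permutation_axis_test()` is a phylogenetic analogue of Horn's parallel
analysis. The null is built by shuffling species assignments independently
within each trait column, destroying both trait-trait and trait-phylogeny
structure — the natural null for "no structured axes"; a joint row
shuffle (preserving trait correlations, destroying only the phylogenetic
association) is available as an option. The observed distribution of each
axis statistic is taken across the posterior tree set, the null
distribution across permutations on the summary tree; an axis is critical
when its observed 95% interval lies wholly above the permuted one.

One numerical property forced a choice here. Permutation destroys
phylogenetic signal, and non-phylogenetic data whitened by `C^-1` has an
inflated implied evolutionary rate — by a factor of roughly
`tr(C^-1)/(n - 1)`, which is 2-50 on simulated chronograms depending on
how short the pendant branches are. Raw permuted eigenvalues therefore sit
on a systematically higher scale than observed ones and the raw comparison
flags nothing, regardless of how much structure the data carry. The
default comparison is therefore on eigenvalue *shares* (percent variance),
the scale-free quantity, with `compare = "eigenvalue"` retained for raw
comparisons. Variable-level flags (which traits drive a critical axis) use
absolute loadings, which are unaffected by this issue.

## Models of trait evolution

Four models of a univariate trait on a chronogram, all with exact
multivariate-normal likelihoods (no pruning approximations; trees of this
size make dense Cholesky factorizations trivial):

* **BM** — Brownian motion, rate `sigma2`, root state `z0`.
* **OU1** — single-peak Ornstein-Uhlenbeck, pull `alpha`, optimum `theta`.
* **EB** — early burst, initial rate `sigma0_2` decaying as `exp(r t)`,
  `r <= 0` at fitting time; `r = 0` is exactly BM.
* **Hansen** — multi-regime OU: a painting assigns one regime to every
  branch (a shift takes effect at the rootward end of its branch and is
  inherited by the whole subtree until overridden), and each tip's
  expectation mixes the regime optima with exponentially decaying
  occupancy weights along its root-to-tip lineage.

The root-state convention for OU and Hansen models is root = (root
regime's) optimum, with no free root parameter — the convention of
stepwise regime-search methods, which keeps a one-regime Hansen model
identical to OU1. Under it the tip covariance is
`sigma2/(2 alpha) * exp(-alpha d_ij) * (1 - exp(-2 alpha t_ij))`.

Parameter counts for information criteria: BM 2, OU1 3, EB 3, Hansen with
m regimes 2 + m. Model comparison across BM/OU/EB/Hansen uses plain AIC;
the stepwise search uses AICc internally (see below). Both are always
computed and stored. Ties are broken toward the model with fewer
parameters.

### Estimation

`fit_model()` profiles the likelihood: conditional on the single shape
parameter (`alpha` for OU/Hansen on a log scale, `r` for EB), the location
parameters (`z0` or the optima) have a closed-form GLS solution and
`sigma2` a closed-form ML (1/n) solution. The remaining 1-D problem is
optimised by deterministic bounded search over five subintervals of
`log alpha` in `[log 1e-8, log 1e4]` (appropriate for unit-height trees;
configurable), or `r` in `[log(1e-5)/height, 0]` with the `r = 0` boundary
checked explicitly. There is no random restart and no seed: identical
inputs give identical fits. This replaces the more common multi-start
quasi-Newton approach; with everything but one parameter profiled out,
1-D bracketing is both faster and more robust to the flat ridges that
make OU optimisation notoriously fragile.

## The stepwise adaptive-peak search

`surface_forward()` starts from OU1 and repeatedly adds the regime shift
that most improves the criterion; `surface_backward()` then repeatedly
merges the pair of regimes whose collapse most improves it, which is how
convergent evolution toward shared peaks is detected. Any improvement
counts (no minimum-improvement gate, though a threshold is exposed), and
ties among candidate branches are broken deterministically: the branch
closer to the root first, then the lexicographically smallest tip label in
its subtree. The search is fully deterministic.

**The criterion.** The search compares models by AICc over `alpha`,
`sigma2`, and the m optima, *plus* `2 log(#branches)` for each of the
m − 1 shifts — the code length of a shift's estimated location. This
placement term matters. Each forward step selects the best of roughly 2n−2
candidate branches; charged only ~2-3 points per added optimum, the
stepwise criterion accepts spurious shifts essentially without bound, and
the fitted `alpha` ratchets upward until the model degenerates into
per-tip clusters (10-16 "regimes" on 32-tip data simulated under one- or
two-regime truth, in our simulations). With the placement term the
operating characteristics are the designed ones: on data simulated under
the printed two-peak parameters the search recovers the true stem shift
cleanly in ~75% of replicates, and on single-peak data it stays at one
regime in ~88% of replicates. The flip side is a conservative null: on BM
data the search reports fewer spurious peaks than the plain-AICc variant
of the published algorithm, so BM-null peak counts land near 1 rather
than 3.

**Candidate evaluation.** For speed, candidates within a step are screened
by a GLS score at the incumbent's `alpha` (one Cholesky factorization per
step covers every candidate); the five most promising are refit with the
full `alpha` profile, and the refit criterion decides acceptance.
Screening alone cannot decide the first step: on regime-shifted data the
OU1 incumbent's `alpha` sits near zero, where a clade shift is absorbed
into the BM-limit covariance and scores poorly.

`bm_null_peaks()` fits BM to the observed scores, simulates under the fit,
reruns the full search on each simulated data set, and reports one-sided
P values (proportion of simulations at least as large as observed) for
the peak statistics k, k′, c, k′conv, Δk, c/k. The null is run on the
summary tree only by default, matching how such nulls are used in
practice given the cost of the search.

## Simulation

`simulate_traits()` draws exact transition densities in preorder — no
Euler discretisation, so branches of any length are simulated correctly.
Each replicate consumes its own RNG substream derived from the seed and
the replicate index, so replicate r is identical whether 10 or 10,000
replicates are requested.

## Disparity through time

Disparity is the mean squared pairwise distance among tip values
(variance-style disparity is a documented alternative the package does
not default to). The DTT curve evaluates, at each internal-node height,
the average relative disparity of the subclades crossing just after that
time; the curve starts at 1 at the root. The time grid is the observed
tree's node heights, and simulated curves are computed on the same tree,
so grids match natively. The MDI is the trapezoidal integral of observed
minus mean simulated curve over relative time [0, 2/3]: the truncation
(configurable) discards the most recent third of the tree, where
incomplete taxon sampling biases subclade disparity; negative MDI means
disparity was partitioned among subclades early.

The posterior-predictive p is the tail frequency in the direction of the
observed MDI's sign: for negative observed MDI, the share of simulated
MDIs at least as negative. Simulated MDIs are computed leave-one-out (each
simulation scored against the mean curve of the others) so observed and
simulated MDIs are exchangeable under the generating model. One
consequence worth knowing when reading p values: with a sign-directed
one-sided tail, a data set truly generated by the model yields
p ~ Uniform(0, 1/2), so a *well-fitting* model produces p values around
0.2-0.3, not 0.5 — which is also where published best-model p values for
this statistic tend to sit. Values near zero still mean misfit, and
model ranking by p is unaffected.

Generating-model parameters for the simulations are maximum-likelihood
refits per tree, and the expectation curve is the mean (not median) of the
simulated curves.

## The synthetic study generator

`gen_study()` produces the inputs the real analysis would read from disk:
a chronogram, a posterior tree set, and a specimen-level measurement
table, together with a ground-truth record sufficient to regenerate every
value. It emulates the design of the study this workflow targets: 32
species, 1-6 specimens per species, standard length plus 15 locomotor
traits, 1000 posterior chronograms (desk-scale runs subsample).

* **Tree**: a pure-birth radiation five times the sampled size is
  simulated and pruned to the sampled species. Pruning is what gives real
  genus-level chronograms their long pendant branches; un-pruned
  pure-birth trees of the target size have near-present splits that make
  `C^-1` ill-conditioned and every downstream method brittle. One
  internal edge with a subtree of ~9 tips is designated the shift clade.
* **Posterior set**: node ages are jittered multiplicatively (log-normal,
  SD 0.05), with parent-older-than-child enforced and heights rescaled,
  so ultrametricity and topology are preserved; optional NNI moves
  perturb topology at a configurable rate (off by default).
* **Traits**: log size evolves by BM (root log 90 mm, rate 0.5); each
  trait is an allometric slope (0.8-1.3, near isometry) times log size,
  plus a latent residual factor, plus independent species-level noise
  (SD 0.1) and specimen-level measurement noise (SD 0.05). The first
  eight traits load on a two-regime Hansen factor with the parameters the
  analysis is expected to recover (`alpha` 0.974, `sigma2` 7.420, optima
  1.126 and −11.027, shift on the designated clade); the rest load on a
  single-peak OU factor (`alpha` 6.77, `sigma2` 15.84, optimum −0.088 —
  the medians rather than the heavy-tail-inflated means of the
  corresponding fitted distributions). Each factor is rescaled so the
  realized GLS evolutionary variance of its block axis matches the two
  critical-axis eigenvalues the design targets (6.57 and 2.59); without
  this, the shift factor's large cross-species spread (a clade mean
  offset contributes much more raw variance than GLS rate) would swamp
  the covariance structure and invert the axis order. Rescaling is linear,
  so `alpha` and all signal-to-noise ratios of the generating processes
  are preserved.

What the generator does *not* emulate: measurement-geometry correlations
among fin areas and lengths beyond shared allometry, missing data,
intraspecific allometric slopes differing from evolutionary ones, and
fossil-calibration uncertainty beyond branch-length jitter. Passing tests
on synthetic data therefore demonstrate that the machinery recovers known
structure of this kind, not that any particular empirical data set has
that structure.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen to keep
a full check under a few minutes of CPU: likelihood oracles on 100 random
trees of up to 5 tips; recovery simulations with 20-60 replicates on
32-tip trees; posterior sets of 5-25 trees; 100-500 permutations; 100 BM
null searches; 100-200 DTT simulations per tree. The analysis scripts
under `analysis/` state their sizes at the top and scale up
straightforwardly.

## Limitations

* Axes are analysed independently; no joint multivariate Hansen fitting
  and no shared-shift multi-trait search.
* The regime search is a greedy stepwise heuristic; it returns one
  painting, not a posterior over paintings, and its placement-penalised
  criterion is deliberately conservative about adding peaks.
* OU-based models assume ultrametric trees; serially sampled tips are not
  supported.
* The BM null for peak statistics is run on the summary tree, not the
  full posterior set, by default.
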