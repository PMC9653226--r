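---
title: "Models and methods behind scartree"
author: "scartree authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scartree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scartree)
```

## The inference problem

Genetic lineage recorders place `m` editable genomic targets (each with an
identifying barcode; together an *integration*) into a precursor cell. While
the editing enzyme is active — the *scarring window* `[t1, t2]` — each
unedited target can irreversibly acquire one of `S` distinguishable scar
outcomes. Independently, a target's readout can be *silenced* at any time,
also irreversibly. At the end of the experiment, time `t_s`, a subset of
extant cells is sequenced, yielding an integer state per cell per target:
`0` unedited, `1` silenced, `2..S+1` scar outcomes, with missing entries for
sequencing dropout.

scartree estimates, from such an edit table, the *time-scaled* phylogeny of
the sampled cells (branch lengths in absolute time), the editing parameters,
and the cell population dynamics (division rate, apoptosis rate, sampling
proportion), in a Bayesian MCMC framework. The posterior over trees makes
the substantial phylogenetic uncertainty of recorder data explicit.

## The editing substitution model

Each target evolves independently down the tree as a continuous-time Markov
chain on `{unedited, silenced, scar_1, ..., scar_S}` with a
piecewise-constant generator. Inside the window, unedited flows to scar `i`
at rate `r * s_i` and to silenced at rate `l`; scars flow to silenced at
rate `l`; silenced is absorbing. Outside the window the scarring terms
vanish. Two parameterizations are interchangeable: *multiplier* (`s_S = 1`,
`r` is the rate of outcome `S`, the `s_i` are relative rates — useful when
outcome frequencies come from a separate experiment) and *clock*
(`sum(s_i) = 1`, `r` is the total editing rate — the molecular-clock form).
They are related by `r_clock = r_mult * sum(s_mult)` and give identical
transition probabilities; the MCMC works internally in multiplier form.

Because the chain is irreversible with this sparse structure, the
transition matrix over any window-homogeneous interval of length `d` has a
closed form, computable in `O(S)` per row rather than via an `O(S^3)`
eigendecomposition. With `sigma = sum(s_i)`:

* `P(0 -> 0) = exp(-(l + r sigma) d)`
* `P(0 -> scar_i) = (s_i / sigma) exp(-l d) (1 - exp(-r sigma d))`
* `P(scar_i -> scar_i) = exp(-l d)`, `P(scar_i -> silenced) = 1 - exp(-l d)`
* `P(0 -> silenced) = 1 - exp(-l d)` (the total silencing mass), and the
  silenced row is the unit vector.

These forms were re-derived from the generator by direct integration
(condition on the scarring time, then on silencing survival) and are
verified in the test suite against a numerical matrix exponential to below
`1e-9` over random parameter draws. Two numerical guards matter: `1 - e^{-x}`
is always computed as `-expm1(-x)` to avoid cancellation at small rates, and
`sigma = 0` is handled as the limit `P(0 -> scar_i) = 0`. Intervals that
straddle `t1` or `t2` are handled by taking the ordered product over the at
most three window-homogeneous segments (`propagate_across_window()`).

## Tree likelihood

The data likelihood of a time-scaled tree and editing parameters is the
product over targets of a sum over ancestral states, evaluated by the
pruning algorithm. Branches are cut at `t1` and `t2` so each segment is
time-homogeneous; the origin — a degree-1 node above the root marking the
experiment start — contributes a point mass on the unedited state, since all
targets start unedited by design. Missing observations enter as all-ones
partial vectors, i.e. dropout is treated as missing at random (no dropout
model is imposed; the rate of dropout carries no information about the tree
under this treatment). Per-node, per-site rescaling with log-accumulated
scale factors prevents underflow on tables with hundreds of cells. The
pruning core is implemented in C++ (as is usual for phylogenetic
likelihoods); an independent R implementation that enumerates all ancestral
state assignments over the subdivided tree verifies it exactly on small
trees.

Observed silenced states are data by default. Because an RNA readout cannot
distinguish a silenced integration from dropout, `silenced_is_missing =
TRUE` remaps observed `1`s to missing; this is left as a user-facing switch
because the right choice depends on the readout chemistry. All computational
studies in this package set `l = 0` (no silencing), matching the regime of
the experimental systems the package targets.

A structural property worth knowing: a tip can only carry a scar if a
portion of the scarring window lies on a path where the scar could be
acquired. In particular, two tips whose most recent common ancestor
postdates `t2` cannot carry *different* scars; such configurations have
probability zero, and the likelihood reports them as a diagnostic error (or
`-Inf` for the sampler). The MCMC's start tree therefore places all initial
divergence times inside the scarring window, where every configuration has
positive probability.

## Tree prior: birth-death with incomplete sampling

The tree prior is the constant-rate birth-death-sampling density: each cell
divides at rate `lambda`, dies at rate `delta`, and extant cells are sampled
independently with probability `rho` at `t_s`. The density is the standard
one built from `p0(t)` (no sampled descendants) and `p1(t)` (exactly one),
conditioned on the origin time; constants shared by all trees on the same
tips are dropped, as usual for MCMC. For `delta = 0, rho = 1` it reduces to
the Yule density `lambda^(n-1) exp(-lambda L)` (`L` = origin branch plus all
branch lengths), which the tests verify by hand on 3-tip trees; the 2-tip
density is also checked to integrate to the Monte Carlo probability of
sampling exactly two cells.

**Conditioning.** Simulated datasets are retained only when the sampled tip
count falls in a configured range, so the prior must condition the same way
or coverage is miscalibrated. Three options are provided: none, survival
(at least one sampled cell — the default), and a tip-count range
`c(min, max)`. The range mass has a closed form because the sampled tip
count of a constant-rate process is geometric given survival
(`bds_tip_range_prob()`), a fact the tests verify by simulation. The
well-calibrated and scenario studies use the range conditioning that
matches their retention rule — at small retained sizes the mismatch is not
benign: pooling replicates amplifies it into a systematic birth-rate bias.
The recovery study keeps plain survival conditioning, mirroring the usual
analysis setup where retention caps rarely bind.

Only some of `(lambda, delta, rho)` are identifiable from a single
reconstructed tree; the tests check the practical symptom (the profile in
`rho` on one tree is nearly flat relative to `lambda`). The studies below
therefore fix `delta = 0` and focus on `lambda` and `rho`, and pooling
replicates is what makes `lambda` sharp.

## MCMC

A Metropolis-Hastings sampler updates, per iteration, either one free
parameter (multiplicative scale move, log-Hastings `log m`) or one
dataset's tree: uniform node-time moves, a scale move on all internal-node
ages (log-Hastings `n log m`), narrow exchange, and Wilson-Balding subtree
prune-regraft with uniform reattachment time (Hastings ratio = ratio of
attachment-interval lengths; the move can relocate the root). Scale windows
adapt toward an acceptance rate of 0.234 during burn-in only (10% by
default), keeping the post-burn-in chain Markovian. With multiple datasets
the parameters are shared (pooled) and each dataset keeps its own tree;
each tree move touches only that dataset's likelihood.

Start trees come from average-linkage (UPGMA-like) clustering of Hamming
distances, with all divergence times placed inside the scarring window (see
above); parameters start at prior medians. Priors are proper distributions
per parameter (lognormal, gamma, beta, uniform, exponential, normal) or
`prior_fixed()` to pin a value, e.g. known relative scarring rates.

The sampler is validated two ways. First, with the likelihood replaced by a
constant, the chain must reproduce the prior: the edit rate then matches
its raw prior (KS test), while the correct reference for `lambda`, `rho`
and the MRCA age is the prior *conditioned on the sampled tip count* —
because the tree space explored has fixed tips — which the tests obtain by
rejection sampling from the simulator. Second, on a fixed tree with one
free parameter, the chain matches a 1-D quadrature posterior in total
variation. Identical-sequence subtrees mix slowly through likelihood-flat
regions; the Wilson-Balding move resamples attachment times from their full
support, which in practice suffices at the problem sizes used here, and is
the main cost driver at larger ones.

## Validation studies and chosen problem sizes

Three study harnesses reproduce the package's validation surface at
reduced scale (sizes chosen as a compromise between Monte Carlo error and
desk runtime; all are parameters of the harness):

* **Well-calibrated coverage** (`well_calibrated_validation()`): truths
  drawn from the priors, inference under the same priors; 95% HPD coverage
  must sit in the binomial band around 95%. Default smoke version: ~100
  replicates, up to 30 cells, `m = 20`, `t1 = 0, t2 = 16, t_s = 32`, trees
  fixed to truth with rate parameters free, 12k iterations per replicate.
* **Recovery study** (`recovery_study()`): truths from a dispersed grid
  (`lambda` lognormal about 0.11, `rho` uniform on (0.05, 0.95), `r`
  lognormal about 0.05), joint tree-plus-parameter inference under weakly
  informative priors, 40 replicates of 4-22 cells. Reported as Pearson
  correlations between posterior medians and truths for tree length, tree
  height, birth rate and sampling proportion, stratified by whether the
  true MRCA falls inside the editing window. At this scale the expected
  ordering R(length) > R(height) > R(birth) > R(sampling) is reproduced,
  with correlations attenuated relative to studies with hundreds of cells
  per tree.
* **Scenario study** (`scenario_study()`): a common batch analysed three
  ways — (A) one alignment, multipliers free; (B) one alignment,
  multipliers known; (C) ten pooled alignments, multipliers known. Pooling
  is what sharpens the birth rate (smaller RMSE and HPD width in C);
  knowing the multipliers mainly improves the tree parameters.

The simulator emulates: birth-death population growth from one precursor,
Bernoulli sampling of extant cells, independent per-target editing under
the exact transition probabilities, and missing-at-random dropout. It does
not emulate sequence-level repair outcomes, inter-target deletions,
cell-type structure, or non-random dropout — so passing validation here
supports the correctness of the inference machinery, not the adequacy of
the model for any particular recorder chemistry.

## Numerical and design choices

* State encoding fixed as `0/1/2..S+1` (unedited/silenced/scars) everywhere.
* Forward time from the origin at 0; conversions to "age before sampling"
  happen only at I/O boundaries and in the birth-death formulas.
* Degree-2 subdivision nodes are a likelihood-internal view; written Newick
  and NEXUS output is always a standard binary tree with a root edge.
* Tree length excludes the origin branch; tree height is the MRCA age at
  sampling.
* HPD intervals use the sorted-window (shortest-interval) estimator; ESS
  uses the autocorrelation-time estimator truncated at the first negative
  autocorrelation; Pearson CIs use the Fisher z transform.
* The 95% credible tree set adds unique topologies (keyed by unranked
  labelled shape) in decreasing posterior probability until 95% is reached.
* Empty or out-of-range simulated replicates are resimulated with the next
  sub-seed and the attempt count is recorded; the matching tip-range
  conditioning of the tree prior is then available and used in calibration
  studies.
* MCMC estimates one shared editing model across targets. Per-site editing
  models (shared rate with per-site outcome multipliers, or fully free) are
  supported throughout the likelihood and simulator; freeing them per site
  in the sampler is a deliberate non-goal at this package's problem sizes.

## Known limitations

Runtime grows quickly with cells (the posterior over trees is the cost);
hundreds of cells are feasible, thousands are not. No relaxed clock: `r` is
constant in time. No ascertainment correction for targets chosen because
they edit often. Dropout is missing-at-random by assumption. The
birth-death prior is single-type: differentiation structure is outside
scope.
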