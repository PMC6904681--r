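---
title: "Penalized-likelihood dating with a cross-validated discrete clock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penalized-likelihood dating with a cross-validated discrete clock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronocv)
```

## The problem

Given a rooted phylogram — a tree whose branch lengths are expected
substitutions per site — and a handful of fossil, geological and secondary
calibration bounds on node ages, we want absolute node ages (a chronogram,
in My) and, in particular, the age of a focal clade's crown node (its
tMRCA). Because substitution rates vary across lineages, the branch lengths
alone cannot separate rate from time; the calibrations anchor the time
scale, and a relaxed-clock model absorbs the rate variation.

`chronocv` implements a *discrete* relaxed clock: every branch carries one
of `k` shared rate categories. Two tuning choices dominate the result — the
number of categories `k` and a smoothing weight `lambda` that penalizes
rate differences between adjacent branches. Both are selected by a
terminal-deletion cross-validation score, and dating uncertainty is
integrated by refitting the whole grid of `(k, lambda)` combinations over
collections of optimal and bootstrap trees.

## The model

For branch $i$ with observed length $b_i$ (substitutions/site) on an
alignment of $s$ sites, the substitution count $x_i = b_i s$ is modelled as
Poisson with mean $\mu_i = r_{c(i)}\, d_i\, s$, where $d_i$ is the branch
duration implied by the node ages, $r_1 < \dots < r_k$ are the category
rates (substitutions/site/My) and $c(i)$ assigns branch $i$ to a category.
The fitted objective is

$$\log L - \lambda \sum_{(i,j)\ \text{adjacent}}
  \left(\log r_{c(i)} - \log r_{c(j)}\right)^2,$$

with $\log L = \sum_i \left[x_i \log \mu_i - \mu_i - \log\Gamma(x_i+1)\right]$
(a continuous Poisson term, since $x_i$ need not be integral). Adjacency
pairs each non-root branch with its parent branch; the root's child
branches are compared with each other.

The penalty acts on *log* rates. This makes it dimensionless: rescaling
all calibrations by a factor $c$ maps the optimum to ages $\times\, c$ and
rates $/\, c$ exactly, for every `lambda` — the time unit cannot leak into
the smoothing. A squared-difference penalty on raw rates would instead
carry units of rate$^2$: at realistic magnitudes (around $10^{-3}$
substitutions/site/My) it would be numerically negligible against the
log-likelihood for any `lambda` in the unit interval, and the selection
grid below would be sweeping a dead parameter. On the log scale,
`lambda` in $[0, 1]$ trades measurable roughness of rate *ratios* against
fit, and `lambda -> Inf` with `k > 1` approaches the strict clock.

Calibrations are hard boxes, not penalties: each resolved constraint pins a
node's age into $[\min, \max]$. Minima propagate rootwards (a parent is at
least as old as any descendant's minimum) and maxima tipwards; an empty box
is reported as an error naming the two colliding calibrations. The root
must be bounded above by some calibration, otherwise the time scale is
unidentified.

## Optimization

`fit_chronogram()` maximizes the objective by alternating two blocks:

* **Category reassignment.** Each branch moves to its best category given
  everything else (Jacobi sweeps, accepted only while the full objective
  does not decrease; ties break to the lowest category index, so runs are
  deterministic).
* **Joint ages + rates.** Node ages and log category rates are optimized
  together by L-BFGS-B with analytic gradients. Ages are parameterized as
  proportional depths: each internal node's age is
  $\text{lo} + f\,(\min(t_{\text{parent}}, \text{hi}) - \text{lo})$ with
  $f \in [0,1]$ in preorder, which makes every calibration box and every
  parent-older-than-child constraint implicit. Optimizing ages and rates
  jointly avoids the slow zigzag along the rate–time compensation ridge
  that strictly alternating updates exhibit.

Branch durations are floored at $10^{-8}$ of the root's upper bound inside
the likelihood, so $\mu_i > 0$ always and the objective stays finite on the
closed box.

The discrete assignment makes the surface multimodal, and the basins are
sticky. Cold fits therefore ladder up: a strict-clock (`k = 1`) fit —
concave given the parameterization and well identified — provides starting
ages; several deterministic category splits are then tried (1-D k-means on
log per-branch rate estimates, rank splits skewed towards mostly-slow and
mostly-fast assignments, and a Poisson-mixture EM on branch counts with
exposures $d_i s$, which weights branches by their information content),
each followed by the block iteration, keeping the best. A polish pass
re-derives the split at the fitted ages and refits until no further
improvement. `n_starts > 1` adds seeded restarts that jitter the starting
ages by ±15% and redo the k-means and EM splits. Inside grid scans, where
thousands of related fits are run, a `lean` mode keeps only the k-means and
EM candidates, and the strict-clock ladder is computed once per tree and
reused across all cells (it does not depend on `k` or `lambda`).

Defaults: `tol = 1e-8` relative objective change, `max_iter = 500` outer
cycles (fits typically converge in 2–6), rate floor $10^{-12}$,
`s = 3754` sites — the alignment length the package's synthetic benchmark
mirrors — always user-overridable. Grid scans in the test-suite and
acceptance script use `tol = 1e-4` to `1e-5` and a reduced L-BFGS-B
iteration cap; at those settings the selected cell and the CV ranking are
unchanged on the benchmark while scans run several-fold faster.

## Cross-validation of (k, lambda)

For a candidate `(k, lambda)`, the reference tree RT gives the focal
clade's observed crown height (OCH). Each terminal of RT is deleted in
turn; refitting each pruned tree gives a predicted crown height (PCH), and

$$\mathrm{CV} = \sum_{i=1}^{M} \frac{(\mathrm{OCH}-\mathrm{PCH}_i)^2}{\mathrm{OCH}}$$

scores the combination (units of My; no further normalization). The grid —
by default `k` from 2 to 10 and `lambda` from 0 to 1 in exact ninths, 90
cells — is scanned exhaustively and the argmin selects the clock, ties
broken towards smaller `k`, then smaller `lambda`.

Two degeneracies force a deletion to be skipped, and both are logged so `M`
can be audited: deleting one of only two remaining focal terminals (the
crown vanishes), and deletions after which no calibration bounds the root
from above. A calibration point whose clade degenerates to a single
terminal with a crown role is dropped from that replicate only. No other
exclusions are applied.

Replicate fits restart from the pruned tree's own cached strict-clock
ladder, taking the reference fit's category rates only as one candidate
seed. The obvious shortcut — warm-starting every replicate directly from
the reference solution — proved treacherous: a minority of replicates stay
trapped in modes far below their own optimum, and the CV score then
measures optimizer noise rather than prediction stability, inflating CV by
two orders of magnitude in the worst cells we examined. CV scores must be a
property of the data and model, not of the initialization path.

We note what CV does and does not reward: it is a *stability* criterion on
the focal crown height. On synthetic data generated under a k-category
clock it usually, but not always, selects the generating `k` or less; a
richer clock that refits deletions reproducibly can score as well as the
generating one. It is not an information criterion and carries no explicit
complexity penalty.

## Ensembles over trees

`run_ensemble()` refits the full grid on every tree of one or more
collections (an optimal tree, alternative optima, bootstrap replicates) and
records one tMRCA per (tree, cell). The record-count identity
$n = \sum_{\text{sets}} |\text{set}| \times |\text{grid}| - \text{logged
failures}$ is asserted on every run; trees lacking two focal terminals or a
root upper bound are skipped with a warning, never silently. Along a tree's
grid, cells are warm-started from the previous cell's solution — here the
distributional summary integrates over cells, so per-cell mode identity
matters less than throughput, and seeded runs stay deterministic.

Summaries use type-7 quantiles (linear interpolation between order
statistics — R's default, and that of the software family this analysis
descends from; the convention is stated because quartiles of small grids
depend on it). The "central 75%" interval is the 12.5th–87.5th percentile
range. The below-threshold count uses strict inequality (`tMRCA <
threshold`). Non-converged fits are included but flagged, with a
`converged_only` switch; histograms default to 50 equal-width bins on
$\log_{10}$(My) because ensemble tMRCAs typically span several orders of
magnitude.

## The synthetic benchmark

`make_benchmark()` builds seeded instances with known truth, so every stage
is testable without any sequence data:

* **Topology and ages:** a Yule (pure-birth) backbone rescaled to a fixed
  root age; the study system makes no claim about the branching process, and
  pure birth is the simplest process with adjustable depth. A shallow focal
  clade is grafted in place of one backbone terminal (stem length keeps the
  tree ultrametric), emulating a recently radiated cluster of strains
  sampled within a much older clade.
* **Rates:** `k` discrete categories with Markov switching along the tree —
  each root-child branch draws uniformly; every other branch inherits its
  parent branch's category with probability `1 - switch_prob` (default
  0.2), else redraws. This gives the smoothing penalty autocorrelated
  structure to exploit.
* **Noise:** branch lengths are Poisson counts over `s` sites,
  $x_i \sim \text{Pois}(r_i d_i s)$, $b_i = x_i/s$ — exactly the dating
  likelihood's sampling model.
* **Calibrations:** boxes drawn around true ages (containment is asserted
  at generation time): a root box at 0.85–1.25 of truth, a deliberately
  wide fossil-style box on the focal crown (0.5–4 times truth), and
  age-stratified boxes (roughly 0.6–0.85 to 1.2–1.6 of truth) on
  mid-depth nodes, one encoded as a stem point.
* **Bootstrap analogue:** `perturb_tree()` redraws all branch lengths by
  the same Poisson mechanism and applies a nearest-neighbour interchange to
  each eligible internal edge with probability `nni_prob`.

Two profiles are packaged. `toy`: 8 terminals (3 focal), 3 calibrations,
`s = 2000`, root age 100 My — fast enough to run full 90-cell grids over
hundreds of trees in minutes. `paperlike`: 56 terminals (11 focal), 8
calibrations, `s = 3754`, root age 300 My, `k = 2` with rates
$5\times10^{-4}$ and $2\times10^{-3}$ substitutions/site/My. Those rates
put the root-to-tip molecular depth near 0.2–0.3 substitutions/site,
which is what multi-locus ribosomal/plastid phylograms of diatoms spanning
a few hundred My actually look like; the 4:1 spread is a moderate level of
among-lineage heterogeneity. The profile mirrors the *scale* of the study
design it emulates (terminal counts, calibration count, alignment length,
90-cell grid), not its data.

What passing on this generator does *not* show: the Poisson branch-length
model matches the fitting likelihood by construction, so benchmark
recovery says nothing about alignment error, model misspecification across
loci, or topological error beyond NNI-level perturbation. Real bootstrap
trees also vary in ways parametric redraws do not capture.

## Numerical and design choices

* Proportional-depth transform bounds: `f` clipped to $[10^{-4},
  1-10^{-4}]$ when converting ages to coordinates; L-BFGS-B operates on the
  closed unit box.
* Degenerate inputs: zero-length branches are legal everywhere (bootstrap
  trees contain them); a zero duration with positive substitution count
  evaluates to $-\infty$ in `pl_objective()` (signalled, not an error).
* Ties: category reassignment and argmin selection break ties towards the
  lowest index / smallest `k` / smallest `lambda` for determinism.
* Calibration merging: published tables often state one-sided bounds on
  separate rows; rows sharing a name merge to the largest minimum and
  smallest maximum. Points whose clade is not monophyletic on a given tree
  are skipped with a warning rather than aborting — parsimony and bootstrap
  topologies routinely break a calibrated clade, and the analysis should
  proceed on the remaining anchors.
* The `lambda` axis uses exact ninths; reported values are formatted to two
  decimals (grid point $3/9$ prints as 0.33).
* All randomness flows from one top-level seed through named substreams
  (hashed stream names), so simulation, restarts and perturbation are
  independently reproducible.

## Known limitations

* The optimizer is a heuristic over a multimodal surface. The candidate
  ladder plus restarts recovers the dominant mode in most benchmark
  instances, but occasional instances remain where a clearly better basin
  exists and is found only from an oracle start; their fitted ages can be
  off by 30–50% at mid-depth unconstrained nodes. More restarts help
  stochastically.
* CV selection inherits the stability-not-parsimony caveat above.
* Uniform calibration boxes only; no probabilistic calibration densities.
* Branch-length, not sequence-level, simulation; no model-misspecification
  suite beyond NNI perturbation.

## Problem sizes used by the shipped tests and acceptance script

Unit and property tests run on 6–40-terminal trees. The acceptance script
runs the full 90-cell grid over 207 toy trees (the 1 + 6 + 200 study
design, 18,630 chronogram fits), the 90-cell CV surface on the toy
reference tree, and a 3-seed paperlike recovery with a 9-cell selection
grid (`k` in 2–4, `lambda` in {0, 1/3, 1}); the test suite's recovery check
uses 10 seeds at the same grid. These sizes were chosen so a full run
completes on one CPU in well under half an hour while still exercising
every code path at the study's design scale.
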