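---
title: "De novo C-alpha tracing from cryo-EM maps: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De novo C-alpha tracing from cryo-EM maps: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catracer)
```

## The problem

A near-atomic-resolution cryo-EM map (3-5 Angstrom) shows a protein as a
continuous tube of density: individual atoms are not resolved, but the
main chain and the bulk of large side chains are. Given such a map for a
*single* chain and the protein's sequence, `catracer` builds ranked
C-alpha models directly from the density, without using any known
structure or fragment library. The pipeline has five stages, each exposed
as ordinary functions so every stage is testable in isolation:

1. **Local dense points (LDPs)** — mean-shift mode seeking on the map
   (`detectLdps`).
2. **Minimum spanning tree** over the LDPs (`buildGraph`,
   `minimumSpanningTree`).
3. **Tabu-search refinement** of the tree, maximizing the summed lengths
   of its top-K longest paths (`tabuRefine`).
4. **Sequence threading** — the longest tree path is resampled and the
   sequence is placed on it, in both directions, by dynamic programming
   matching local density against expected residue volume
   (`resamplePath`, `threadSequence`, `buildCaModel`).
5. **Ensemble and confidence** — stages 1-4 are repeated over a parameter
   grid; models are ranked by threading score and a per-residue consensus
   confidence is computed over the top scorers (`runSweep`,
   `confidenceProfile`).

Model quality against a reference is measured by five standard metrics
(`evaluateModel`): sequence-dependent C-alpha RMSD and GDT-TS, and
sequence-independent unlabeled RMSD, recall and precision at 2 and 3
Angstrom.

## The density model and mean shift

The working assumption is that map density is a sum of Gaussian kernels
centred on atoms. The smoothed density at a point $x$ is

$$ f(x) = \sum_{g:\,\rho(g)>0,\ \|g-x\|\le 3\sigma}
   \rho(g)\, e^{-1.5\,\|(g-x)/\sigma\|^2}, $$

where $g$ runs over map grid points with positive stored density
$\rho(g)$ and $\sigma = 1.0$ Angstrom by default. Every grid point whose
stored value exceeds a *threshold fraction* of the map's recommended
contour level is used as a seed and moved iteratively to the
kernel-weighted mean of its neighbourhood (`shiftPoint`), which ascends
$f$ until the displacement falls below `convergenceTol`. Converged
positions within `mergeRadius` of one another are merged by single
linkage; each cluster is represented by its highest-density member (not
the centroid), which keeps LDPs on ridges of the field.

Numerical choices, all overridable through `meanShiftParams()`:

| parameter | default | why |
|---|---|---|
| `sigma` | 1.0 A | kernel bandwidth of the smoothed field |
| `thresholdFraction` | 0.5 | seed cut as a fraction of the contour level; the 2016-style preset uses {1.0, 0.5}, the 2017-style preset {0.5, 0.25} |
| `convergenceTol` | 0.01 A | displacement at which a seed is converged |
| `maxIter` | 100 | iteration cap per seed |
| `mergeRadius` | 0.5 A | single-linkage merge radius for converged seeds |

The 3-sigma neighbourhood cutoff truncates a kernel tail below
$1.2\times10^{-6}$ of its peak; the merge radius is well under half the
3.8 Angstrom C-alpha spacing, so distinct backbone positions are never
merged. The inner accumulation loop is compiled (C++ via Rcpp) because
every seed is iterated to convergence.

## Tree building and tabu refinement

All LDP pairs within `edgeCutoff` (default 5.0 Angstrom, just above the
C-alpha virtual bond of 3.8) become edges weighted by Euclidean distance;
the minimum spanning tree of the largest connected component is the
initial skeleton. Edge weights are pure distances; a density-weighted
variant is deliberately not the default because the objective it would
optimize is not defined by the underlying method description.

The tree is then refined by tabu search. A tree is scored by the sum of
the lengths of its top-K longest leaf-to-leaf paths (every path in a tree
is determined by its endpoints, and interior-endpoint paths are sub-paths
of leaf-pair paths, so leaf pairs dominate the ranking). Each iteration
deletes one tree edge and adds a parent-graph edge reconnecting the two
halves, applying the best candidate move even if it worsens the score;
edges touched by the last `tabuTenure` (default 20) moves are forbidden
unless a move beats the best score ever seen (aspiration). When the
delete-by-add neighbourhood exceeds `moveBudget` (default 500) candidate
moves, a uniform sample is evaluated, drawn from a seeded RNG so entire
runs are reproducible bit for bit. The best tree ever visited is
returned, so the best-so-far score is non-decreasing by construction.

**Scale and the choice of K.** K = 100 is the production default. It
presumes trees with at least ~100 leaf pairs (hundreds to thousands of
LDPs, where the top-100 objective approximates "100 times the trunk
length" and penalizes erroneous shortcuts). On desk-scale fixtures with
only tens of LDPs the same objective is degenerate: a clean single-path
tree has exactly one leaf pair, so *any* branching multiplies the number
of counted paths and the search happily shatters a correct trace into a
brush of medium arms. The `fast` preset therefore scores trees with
K = 1 — the longest path, which is exactly the object the threading
stage consumes — and sweeps `edgeCutoff` over {4, 5} Angstrom. The
4-Angstrom cutoff excludes the 4.5-5.0 Angstrom cross-turn shortcuts an
alpha-helix offers, which are geometrically admissible but not supported
by the chain. Both knobs are part of the ordinary parameter sweep.

## Threading: sequence onto path

The longest path is resampled every `step` (default 1.0) Angstrom of arc
length. At each sample the raw map is interpolated trilinearly, smoothed
along the arc with the same Gaussian kernel form (bandwidth 2 Angstrom),
and z-normalized over the path, which makes the threading score invariant
to affine rescaling of map values. A numerically constant profile
z-normalizes to exact zeros rather than amplified rounding noise.

Each residue `a` carries the z-score of its mean residue volume (a
standard crystallographic table; glycine ~60 cubic Angstrom, tryptophan
~228). Placing residue `a` at path point `p` scores
$-(\hat z_{dens}(p) - \hat z_{vol}(a))^2$: large residues should sit in
relatively dense path regions. A dynamic program places a contiguous
block of the sequence on strictly advancing path points under these
rules:

* consecutive residues advance between `minSpacing` = 2.8 and
  `maxSpacing` = 4.5 Angstrom of arc (bracketing the 3.8 virtual bond) at
  no cost;
* larger interior jumps cost `gapOpen` (default 1.0, in squared-z units)
  per skipped spacing window — this permits hopping a noisy branch
  region;
* every unplaced terminal residue costs `gapOpen`, supporting maps that
  cover only part of the chain (e.g. a transmembrane-only segmentation).

The sequence is threaded in both directions (the chain direction is not
knowable from density alone) and both models are kept: direction errors
must be surfaced and ranked, not hidden. The DP optimum is verified
against brute-force enumeration of all legal monotone assignments on
small instances in the test suite.

## Ensemble, ranking, confidence

`runSweep` executes the Cartesian product of the configured grids
(threshold fraction, edge cutoff, tabu iterations, tabu seeds, gap
penalty), pools all models, ranks by threading score (ties broken by the
provenance id) and keeps the top `nModelsKeep` (500 by default; a
desk-scale sweep produces tens of models rather than the production-scale
"over ten thousand", but the counts are configuration, not constants).
Near-identical models are counted as-is, without de-duplication.

The consensus confidence of residue `i` in a chosen model is the
fraction of the top `nConsensus` (default 100) scoring models whose
residue-`i` C-alpha lies within 3.5 Angstrom of the chosen model's.
Matching is by residue number — the stricter reading; `anyAtom = TRUE`
gives the register-blind variant. Models not covering the residue count
as dissent. On mixed-quality ensembles the mean positional error falls as
consensus rises (this calibration is asserted on synthetic ensembles in
the tests), so the profile is written into the B-factor column of output
PDBs for coloring.

## Evaluation metrics

All metrics default to the *fixed shared frame*, because models are built
in the map frame and references are author-fitted into the same map; a
Kabsch superposition flag exists for frame-free use (whether published
challenge tables superposed is not stated, so both modes are provided and
labeled). GDT-TS normalizes by the reference length, so unmodeled
residues count as misses — a partial-coverage model can have high
precision and still a low GDT-TS. Unlabeled RMSD is directional
(model-to-reference by default, matching its usual definition); the
opposite direction is a flag. Recall and precision use strict
"closer than" at 2 and 3 Angstrom.

## The synthetic-map generator

`simulateMap` renders each C-alpha as the same Gaussian kernel the
mean-shift stage assumes, on a grid covering the structure plus `pad`
(default 5 Angstrom). `sigmaSim` defaults to half the nominal resolution
(a "4 Angstrom map" is simulated with `sigmaSim` = 2), which makes 3-4
Angstrom fixtures visually tube-like. The contour level attached to a
fixture is the 60th percentile of its positive voxel values — an
arbitrary but fixed convention; every downstream threshold is a fraction
of it. Fixtures are C-alpha-only; an optional per-residue weight
proportional to residue volume creates the density contrast along the
chain that real side chains would.

What the fixtures deliberately do **not** emulate: noise, CTF,
B-factors, solvent, map anisotropy, neighbouring chains, or real
side-chain density. Passing the end-to-end tests therefore demonstrates
that the tracing logic inverts its own generative model at realistic
geometry and sampling — not that the pipeline handles microscopy
artifacts. One consequence is visible in the worked example: on an
unweighted fixture the density along the chain is nearly uniform, so the
threading score contains almost no register signal, and the top model
may run in the reversed direction — high recall/precision and ~1
Angstrom unlabeled RMSD alongside a poor sequence-dependent RMSD and
GDT-TS, the classic reversed-chain signature also seen on real maps.

## Problem sizes and determinism

The test suite and the acceptance script run a 30-residue helix in a
~15 x 15 x 54 voxel map (about 12,000 voxels, ~30 LDPs, 16 models from
the fast preset) — sizes chosen so the full pipeline completes in tens of
seconds while still exercising every stage at realistic geometry.
Combinatorial stages are verified against exhaustive oracles at small n
(spanning trees via Pruefer enumeration up to 7 nodes, threading via
brute-force assignment enumeration up to 15 path points). Every
stochastic component (tabu move sampling) draws from an explicit
per-combination seed; two runs from the same configuration are
byte-identical, and the sweep's combinations are independent, so
parallel execution would have to reproduce the sequential result.

## Known limitations

* Single chain only: maps must be pre-segmented; there is no multi-chain
  tree partitioning.
* One path per tree: only the longest path is threaded, so topologies
  whose chain leaves the tree diameter (long branches that are real
  chain) lose coverage.
* The residue-volume signal is weak at 3-5 Angstrom and vanishes on
  unweighted fixtures; chain direction is then decided by near-ties.
* MRC input must be orthogonal; skewed cells are rejected rather than
  resampled. Anisotropic voxel sizes are supported throughout.
* No full-atom building or refinement: the deliverable is ranked
  C-alpha traces with confidence, the stage where density information
  ends and force-field modeling begins.
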