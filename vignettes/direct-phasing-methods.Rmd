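---
title: "Genetic-algorithm-enhanced direct phasing: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic-algorithm-enhanced direct phasing: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The phase problem and the dual-space cycle

An X-ray diffraction experiment on a protein crystal records the amplitudes
$|F_{obs}(h)|$ of the structure factors but not their phases; both are needed
to invert to an electron density map. Direct phasing recovers the phases from
the amplitudes alone by alternating between constraints that the true density
satisfies in reciprocal space (the measured amplitudes) and in real space
(a flat disordered-solvent region occupying a known fraction of the cell, and
a protein region whose density-value distribution matches that of solved
structures at comparable resolution).

`evophase` implements one iteration of this cycle as follows. Starting from
the current density $g_k$ on a unit-cell grid:

1. **Amplitude projection.** An FFT gives $|F_{cal}|, \varphi_{cal}$. A
   least-squares scale $\lambda = \sum |F_{obs}||F_{cal}| / \sum |F_{cal}|^2$
   over the working set maps the calculated amplitudes onto the observation
   scale; the working amplitudes are replaced by $|F_{obs}|/\lambda$ (phases
   kept), and the residuals before replacement give
   $R_{work} = \sum ||F_{obs}| - \lambda|F_{cal}|| / \sum |F_{obs}|$ and the
   analogous $R_{free}$ on a held-out 1% of reflections that are never
   replaced. Unmeasured reflections (the low-angle beam-stop gap) and all
   reflections above the low-resolution cutoff (default 15 Å) are filled with
   $(\sum_{work}|F_{obs}| / \sum_{work}|F_{cal}|)\,|F_{cal}(h)|$ every
   iteration. The inverse FFT gives the projected density $g'_k$.
2. **Envelope determination.** The local weighted average
   $w_{k,i} = \sum_j \exp[-r_{ij}^2/(2\sigma_0^2)]\, g'_{k,j}$ (a periodic
   FFT convolution at minimal-image distances) is thresholded at the
   solvent-fraction quantile: exactly $\mathrm{round}((1-f_{solv})N)$ points
   with the largest $w$ become protein. The radius $\sigma_0$ ramps linearly
   from 4.0 Å down to 3.0 Å over the first 60% of the iteration budget:
   a generous radius tolerates the disconnected density of early iterations,
   a tight one sharpens the boundary once features emerge.
3. **Real-space modification.** Protein-region values are rank-transformed
   onto a reference histogram (plotting positions $(k-\tfrac12)/n$, linear
   interpolation of the sorted reference sample, index-order tie-break).
   Solvent-region values receive the hybrid input–output feedback
   $g_{k+1} = g_k - \beta g'_k$ ($\beta = 0.7$ by default), which relaxes the
   solvent toward constancy without the stagnation of plain solvent
   flattening. After convergence the run switches to 200 cycles of true
   solvent flattening (solvent set to its mean), which is the fixed-point
   variant used for the final polish.

Because the histogram matching touches only protein points and the feedback
only solvent points, their order within one cycle is immaterial; with NCS
averaging enabled the order is HIO feedback, then NCS averaging, then
histogram matching.

## The genetic layer

A single reconstruction started from random density frequently stalls in a
local minimum. `evophase` therefore evolves a population of `population_size`
independent reconstructions, exchanging information every `ga_interval`
iterations:

* **Fitness.** With $R_{thres} = R_{avg} + (R_{avg} - R_{min})$ over the
  current population, fitness is $f_i = (R_{thres} - R_i)/(R_{thres} -
  R_{min})$ for $R_i < R_{thres}$ and 0 otherwise — linear in quality, and
  adaptive because the threshold tracks the population.
* **Diversity control.** Pairwise map distances $d_{ij}$ (RMSD over the
  asymmetric unit after origin alignment) feed a convergence score
  $s_i = \sum_j \exp(-d_{ij}^2 / 2\sigma^2)$ with $\sigma$ the standard
  deviation of the off-diagonal distances. Crowded individuals have their
  effective R pushed toward the threshold,
  $R_{mod} = R_{thres} - (R_{thres} - R_i)/s_i$, before the fitness is
  computed, so near-duplicates do not monopolize the roulette.
* **Selection, crossover, mutation.** Two parents per offspring are drawn
  independently by inverse-CDF roulette over $p_i = f_i/\sum f_j$
  (distribution-equivalent to an accept–reject loop, at deterministic cost).
  Crossover replaces 10 disjoint contiguous runs of the first parent's
  asymmetric-unit vector — 50% of its points in total — with the second
  parent's values; mutation then redraws 1% of points uniformly in (0,1).
  Offspring are re-expanded to an exactly symmetric full cell.
* **Elite preservation.** A reconstruction whose sliding-window mean
  $R_{work}$ (iterations $i{-}300$ to $i{-}200$ versus $i{-}100$ to $i$)
  drops by more than 0.02 — with the $R_{free}$ windows required to drop in
  parallel, to guard against overfitting — is flagged elite, keeps its slot
  untouched in every later generation, and remains available as a parent.
  The run terminates when all members are elite or the budget is exhausted.

Amplitude-only data cannot distinguish maps related by allowed origin shifts
or inversion, so before genetic exchange every map is aligned to the
highest-fitness member: candidate transforms are scored by the overlap
(Jaccard index) of protein masks, computed for all cyclic shifts at once by
FFT cross-correlation and then restricted to the space group's allowed set.
Offspring are returned to their rank's original frame afterwards, preserving
the continuity that the HIO feedback relies on.

Converged members are aligned, averaged — independent reconstructions
approach the solution from different directions, so averaging cancels
uncorrelated error — and the phases of the averaged map are the result.

## Degenerate-case guards

* If all $R_{work}$ coincide, $R_{thres} = R_{min}$ and the fitness formula
  is 0/0. The standalone fitness function returns uniform $1/N$; the
  population selection path instead uses the sharing-only limit
  $f_i = 1/s_i$, which is the limit of the full chain as the R values
  coalesce and preserves the intended preference for isolated individuals.
* If all pairwise distances are equal ($\sigma = 0$), the convergence score
  is set to its collapsed-population limit $s_i = N$.
* Quantile ties in envelope determination are broken by stable ascending
  index order, so the protein point count is always exact and runs are
  bitwise reproducible.

## Non-crystallographic symmetry

For targets with a known rotational NCS axis, the map can additionally be
averaged over the $n$ rotation images of each grid point (trilinear
interpolation, periodic wrap) every iteration, inside a staged core mask:
the weighted density at radii 15, 5 and 3 Å successively localizes the NCS
center, grows the core, and covers the full protein region (stages 1 and 2
are additionally confined to a cylinder of twice the stage radius about the
axis). Axis order, direction and position are inputs; determining them from
the data (e.g. from a self-rotation Patterson) is out of scope. On a cubic
grid with a lattice-commensurate axis the interpolation is exact, which is
how the averaging operator is tested.

## The synthetic toy crystal

The generator builds a fully self-contained test problem: ~150 Gaussian
blobs of width 0.7–1.1 Å — atom-like scatterers, so the simulated amplitude
spectrum stays significant out to the resolution limit as real atomic
structures do — are placed in one contiguous sub-box (a connected protein
region), symmetrized, and the solvent region is flattened to zero with the
envelope recomputed until stable, making the truth an exact fixed point of
its own constraints. Amplitudes are computed from the truth to 3 Å on a
31 Å P1 cell (a 32³ grid at 3× oversampling), reflections beyond 25 Å are
dropped to emulate the beam-stop gap, 1% of the rest is held out as the free
set, and optional multiplicative lognormal noise models measurement error.
The reference histogram is taken from the truth's own protein region, as a
stand-in for a solved structure at matching resolution.

What the toy does *not* emulate: atomic form factors and B-factors, bulk
solvent scattering, anisotropy, measurement-error models beyond lognormal
noise, and the sheer size of real unit cells. Passing tests on the toy
demonstrate the correctness and the qualitative behavior of the machinery —
not the success statistics achievable on deposited diffraction data.

## Desk-scale study conditions

The end-to-end tests and the acceptance script run the toy problem at 72%
solvent content and zero amplitude noise with a population of 16, genetic
operations every 50 iterations, and a 3000-iteration budget — sizes chosen so
the full stochastic experiment (with a matched GA-disabled control) completes
comfortably on one CPU. The solvent estimate passed to the run is 0.65,
deliberately below the true 0.72, mirroring the recommended practice of
underestimating so the envelope covers the whole protein. Success of one
member is defined as real-space correlation ≥ 0.8 with the truth after
origin/enantiomer alignment.

Two behaviors observed at these conditions are worth noting. First, the
truth is an exact fixed point of the cycle at the converged-stage radius
$\sigma_0 = 3$ Å; at the exploratory 4 Å radius a few percent of boundary
points are intentionally mislabeled by the over-smoothed envelope, so
stability tests address the late-stage cycle. Second, mask-boundary
smoothness improves with $\sigma_0$ only up to the construction radius of
the envelope; far larger radii over-smooth the quantile mask and roughen its
boundary again.

## Tunables

| parameter | default | units | role |
|---|---|---|---|
| `solvent_fraction` | 0.65 | — | envelope quantile; underestimate the true value |
| `beta` | 0.7 | — | HIO solvent feedback strength |
| `sigma_start`, `sigma_end` | 4.0, 3.0 | Å | weighted-density radius ramp |
| `ramp_end` | 0.6·`max_iter` | iterations | end of the σ₀ ramp |
| `lowres_cutoff` | 15 | Å | replace measured data above this d by calculated |
| `free_fraction` | 0.01 | — | held-out reflection fraction |
| `max_iter` | 10000 | iterations | per-reconstruction budget |
| `flatten_cycles` | 200 | iterations | final solvent-flattening polish |
| `population_size` | 100 | — | independent reconstructions |
| `ga_interval` | 100 | iterations | spacing of genetic operations |
| `crossover_fraction`, `n_segments` | 0.50, 10 | — | exchanged fraction, segment count |
| `mutation_rate`, `mutation_range` | 0.01, (0,1) | — | redrawn fraction and range |
| `elite_drop_threshold` | 0.02 | R units | window drop marking an elite |

## Numerical conventions

Fractional coordinates with 0-based grid indices $x = i/n$ and periodic wrap
everywhere; structure factors $F(h) = N^{-1} \sum_j g_j e^{+2\pi i h\cdot
x_j}$, so $F(000)$ is the grid mean — it is carried, never replaced by data
(the beam stop makes it unmeasurable; histogram matching fixes the density
scale instead, with the reference histogram supported in [0,1] so that the
GA's uniform(0,1) mutation is commensurate with real density values). Grid
dimensions are the smallest 2,3,5-smooth integers giving a spacing of at
most $d_{min}/3$. Origin searches along polar axes are quantized to the
grid, which is all the crossover needs. Frame transforms are exact index
permutations, never interpolations, so align–restore round trips are
bitwise. The supported space groups are P1, P21212, P212121, P42212 and
C121; other groups fail with an explicit error.

## Limitations

Phasing success depends fundamentally on solvent content: below roughly 65%
the solvent constraint carries too little information unless NCS supplies
more, and nothing in the genetic layer changes that arithmetic. Single
overall scale (no resolution-shell scaling), no anomalous signal, no
intensity-to-amplitude conversion, no twinning, no translational NCS, and
reflection input limited to structure-factor mmCIF.
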