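---
title: "Methods: activation states, conformational landscapes, and umbrella-sampling free energies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activation states, conformational landscapes, and umbrella-sampling free energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statescan)
```

`statescan` implements the analysis layer of a receptor-activation study:
given trajectories and umbrella-sampling records (not a molecular-dynamics
engine — generating the physics is out of scope), it computes
activation-state metrics, conformational landscapes, and potentials of
mean force. This vignette explains the models behind each stage, the
parameters that matter, the synthetic data the tests rest on, and the
numerical choices that were genuinely open.

## Units and constants

Coordinates are Angstrom internally; reaction coordinates follow the
GROMACS convention and are nm. Energies are kcal/mol internally; force
constants arrive in kJ mol⁻¹ nm⁻² and are converted once, at the
estimator boundary, with the exact factor 4.184. The gas constant is
R = 0.0019872 kcal mol⁻¹ K⁻¹ and the default temperature is 310 K
(physiological, matching the simulation conditions the package targets),
so RT ≈ 0.616 kcal/mol.

## Activation metrics

**Cα distances.** The opening of the intracellular transducer-binding
cavity is tracked by Cα–Cα distances, canonically the ionic-lock pair
R173–E318 and the TM5/TM6 pair Q262–E318. Distances are
superposition-invariant, so no alignment is applied. Reference levels for
"open"/"closed" states come from experimental structures and are
user-supplied numbers, not constants of the package.

**A100 index.** The A100 score is an affine function of five Cα
distances with fixed per-Angstrom weights (−14.43, −7.62, +9.11, −6.32,
−5.22) and intercept 278.88. Distances enter in Angstrom: the published
classification thresholds (0, 25, 55) are only consistent with
Angstrom-scale distances, which is worth stating prominently because nm
inputs would silently compress the score range. The three-state model
labels score < 0 inactive, score < 55 intermediate, and the rest active;
the two-state model splits at 25. The published rule states only strict
inequalities for the lower classes, so the boundary convention had to be
decided: boundaries are left-closed on the active side (a score of
exactly 55, or exactly 25, is active; exactly 0 is intermediate).
`classify_state()` is monotone by construction — raising a score never
moves the label toward inactive.

**RMSD/RMSF.** RMSD is mass-weighted and computed after Kabsch
superposition onto the reference over the analysis selection (the
mass-weighting matches the PCA convention; unit weights are an option).
RMSF is the per-atom RMS fluctuation about the time-mean position, by
default after superposing every frame onto the time-averaged structure,
which removes global drift.

## Conformational landscape

**Selection.** PCA operates on the helix bundle only: the intrinsically
disordered loops (ICLs 102–108, 179–189, 263–314; ECLs 138–145, 217–231,
347–354 in the 70–399 numbering) are far more flexible than the
transmembrane core and would otherwise dominate the eigenvalue spectrum.
`atom_selection("ca", exclude_residues = loop_residues())` leaves 229 of
the 330 residues. Backbone atoms N/CA/C/O are used when present; the toy
receptor is Cα-only.

**PCA.** Coordinates are scaled by sqrt(mass), mean-centred, and the
covariance diagonalized. The trace of the covariance equals the sum of
eigenvalues (checked to 1e-8 relative), and eigenvectors are orthonormal.
Frames must share a rigid frame of reference before a covariance is
meaningful; an unsuperposed input is not detectable from the data, so
this is a documented contract, with `superpose = TRUE` (alignment to
frame 1 over the selection) as the default. The reference frame is a
parameter because the choice is arbitrary in principle.

**Clustering.** k-means runs in the 2D PC1/PC2 space (the space in which
the ensembles are inspected), using k-means++ seeding — written here
because base R's `kmeans()` does not provide it — followed by Lloyd
iterations via `stats::kmeans`, with `n_init = 10` restarts keeping the
best inertia, deterministic under a seed. At most four ensembles are
assigned; with `k = "auto"` the count is chosen by mean silhouette width
over k ∈ 2..4 (silhouette is undefined at k = 1, which is kept only as a
degenerate fallback). Centroid frames are the frames nearest each
center, ties broken by the lowest frame index.

**Reference comparison.** Centroids are Kabsch-aligned to named
reference structures (mass-weighted RMSD; ties in the nearest-reference
label broken by supplied name order). The scalar TM6 readout
`tm6_outward_shift()` superposes a conformation onto the closed
reference over everything *except* the TM6 block and reports the mean Cα
displacement of the block — 0 for closed, ~4 Å for partially-open, ~8 Å
for fully open states.

## Umbrella sampling and WHAM

**Model.** Window *i* restrains the reaction coordinate with
w_i(ξ) = ½ k_i (ξ − x_i)², typically k = 1000 kJ mol⁻¹ nm⁻² at ~0.1 nm
spacing (~40 windows over ~4 nm). The WHAM equations
P(b) = Σᵢ nᵢ(b) / Σᵢ Nᵢ exp((Fᵢ − wᵢ(b))/RT) and
Fᵢ = −RT ln Σ_b P(b) exp(−wᵢ(b)/RT) are iterated to self-consistency;
convergence is declared when the largest window free-energy change drops
below tol·RT (default tol = 1e-7, cap 100000 iterations, initial Fᵢ = 0;
exp(−wᵢ(b)/RT) is precomputed once so an iteration is a pair of
matrix–vector products). Binning defaults to 200 uniform bins over the
data range (~0.02 nm at a ~4 nm span). `k = 0` windows are legal and
reduce WHAM to a histogram estimate. Adjacent-window histogram overlap
is diagnosed and a zero-overlap pair triggers a warning, since the
profile is only determined up to a constant within each connected block.

**Reported bins.** A bin holding n samples contributes shot noise of
roughly RT/√n to −RT ln n; a bin with one or two stray counts at the
edge of the sampled range can therefore carry an error of order 1
kcal/mol while the well-sampled interior sits near 0.05. Bins with fewer
than `min_count = 10` total raw counts (shot noise ≈ 0.32 RT) are
masked as unsampled in the *reported* profile only; every occupied bin
still enters the self-consistent iteration, so window free energies are
unaffected. The result is insensitive to the threshold over a wide range
(5–100 at the default problem scale).

**Uncertainty.** The Bayesian bootstrap re-solves WHAM with
whole-window weights drawn from a flat Dirichlet (each window's
effective sample count scaled by its weight) — the "complete histogram"
bootstrap, appropriate when within-window samples are correlated but
windows are independent; per-bin standard deviations across replicates
(convention: 250) give the error band. Replicates are warm-started from
the base solution and brought to a common gauge (the bulk region when
given, else the jointly occupied bins) before deviations are taken,
since the raw WHAM output is only defined up to a constant. One
replicate yields a zero band by definition. No autocorrelation-based
inefficiency correction is applied (a documented simplification; the
window-level bootstrap absorbs much of it).

**Free energies.** The profile is zeroed so the mean over a bulk region
is 0 ("free energy is zero when the ligand is in bulk water"); binding
free energy is then the minimum of the profile inside the site region,
with the bootstrap error at the minimizing bin. Neither region is
defined numerically in the conventions this package follows, so the
demo pipeline defaults to the 10% of the coordinate range farthest from
the site as bulk and the near 50% as site — both are parameters.
Subpocket differences ΔΔG = ΔG_EBP − ΔG_OBP combine errors in
quadrature by default (a linear sum is available; published tables are
not always consistent between the two, and the package makes no attempt
to guess which convention produced a given table). The occupancy ratio
is exp(ΔΔG/RT); its `orders_of_magnitude` is floor(log₁₀ ratio).
`pmf_barrier()` reads barrier heights from local quadratic fits at the
stationary points rather than single-bin extrema, because the pointwise
maximum of a noisy profile is biased upward by exactly the per-bin
noise.

## Synthetic data: what it emulates, and what it does not

The generators define the package's test conditions.

**Toy receptor.** 330 Cα pseudo-atoms (residues 70–399) on seven ideal
helices (rise 1.5 Å/residue, 100°/residue, radius 2.3 Å) placed on an
11 Å bundle circle with alternating direction, loops interpolated with a
lateral bow plus 0.05 Å seeded jitter so no two residues coincide.
Per-residue masses cycle through the twenty amino-acid residue masses.
Only the topology matters — contiguous segments, a distinct TM6 block at
315–346, the label map of the activation index — not structural realism.
The Ballesteros–Weinstein map stores labels as metadata with residue ids
as ground truth; the activation index's published form carries the label
4.42 twice (T160 and A192), almost certainly a typo in one of them, so
the second occurrence is stored as `"4.42b"`.

**Two-state collapse.** The "open" reference displaces the TM6 block
rigidly along the unit vector from the R173 Cα to the E318 Cα, so the
ionic-lock distance difference equals the requested shift exactly (8 Å
for the fully open state, 4 Å for a partially-open one). Trajectories
mix open into closed with a mixing coefficient λ(t) falling linearly
from 1 to 0 at `collapse_frame`, plus i.i.d. Gaussian noise per
coordinate (default scenario: 1000 frames, collapse at 250, noise
0.3 Å). The collapse is deterministic and scheduled — real trajectories
switch stochastically and replica-dependently, and the generator
deliberately exposes `collapse_frame` rather than modelling that
stochasticity.

**Umbrella windows.** Samples are drawn from the biased Boltzmann
density exp(−(U(ξ)+w(ξ))/RT) by a Metropolis random walk: step size
adapted toward ~40% acceptance during a 1000-step burn-in only (frozen
afterwards, so the retained chain satisfies detailed balance), thinning
10. Ground-truth potentials are analytic (harmonic, a quartic double
well parameterized by barrier height and minima, or a tabulated curve),
so the estimator can be scored against an exact answer — something real
umbrella data never allows. What the synthetic data does *not* contain:
correlated MD dynamics, slow orthogonal degrees of freedom, and
pull-direction hysteresis; passing the recovery tests therefore
validates the estimator, not the sampling quality of any particular
simulation.

**Test problem sizes.** The estimator-recovery checks run at the default
study scale (40 windows × 5000 samples, 1000-frame trajectories, a
50-replicate bootstrap); unit tests use smaller versions of the same
generators (8–12 windows, hundreds of samples) chosen to keep each
property sharp at small n.

## Known limitations

- PDB input is ATOM/HETATM only; insertion codes and altlocs are
  rejected with an error naming the line, never silently normalized.
  Periodic-boundary unwrapping is not performed — trajectories must
  arrive unwrapped.
- No binary trajectory formats (XTC/DCD/TRR); the flat TSV table is the
  interchange surface.
- WHAM here is 1D with harmonic (or zero) biases; no periodic
  coordinates, no MBAR production estimator (an MBAR-style
  self-consistent estimator exists in the test suite as an independent
  oracle), no free-energy surfaces over PC space, no time-lagged PCA
  variants.
- The microswitch rotations that accompany activation (toggle switch,
  PIF, NPXXY) are not reduced to scalar metrics; they are assessed on
  centroid structures by inspection in the workflows this package
  supports.
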