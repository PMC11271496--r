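---
title: "Descriptor-driven active learning for reactive MLPs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Descriptor-driven active learning for reactive MLPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mlal)
```

## The problem

Training a machine-learning interatomic potential (MLP) for a reaction in
explicit solvent requires a training set that covers the reactant, product
and transition-state regions *and* the solvent's configurational space,
while every label costs an expensive reference (ab initio) calculation.
`mlal` implements a descriptor-driven active-learning (AL) loop that grows
the training set only where the current model is uninformed, together with
the downstream reaction-dynamics toolkit (umbrella sampling, downhill and
uphill trajectory ensembles, radial-distribution and hydrogen-bond
analysis). Built-in analytic potentials - a flexible point-charge water
model and a two-bond double-well reactive model - stand in for the
reference method so the whole workflow runs and is tested at desk scale.
Everything below is in eV, Angstrom, fs and amu; free energies and model
errors are converted to kcal/mol (1 eV = 23.0605 kcal/mol) only at
reporting boundaries.

## The active-learning loop

Starting from a small initial set (random displacements of a seed
structure, each Cartesian component i.i.d. uniform on
`[-max_disp, +max_disp]` with `max_disp = 0.1` A by default), the loop
alternates:

1. train the current model on the accumulated labelled set;
2. run an MD episode of `n^3 + 2` fs (0.5 fs timestep) with the current
   model, where `n` counts consecutive episodes without a selection and
   resets to 0 after every acceptance;
3. hand the episode's **last frame** to the selector; on *add*, label it
   with the reference backend, append and retrain.

The loop is converged when the next episode duration would exceed the
5 ps cap without any selection - i.e. the model has survived a long
streak of MD without producing anything the selector finds new. Episodes
start from a designated member of the initial training set
(`start_mode = "fixed"`); restarting from the most recently accepted
structure is available (`"latest"`) but makes the selector much harder to
saturate, because the walk keeps entering fresh territory indefinitely.

Two guards keep the loop physical. An episode whose forces exceed
1000 eV/A (or go non-finite) aborts and returns the last stable frame as
the candidate - an unstable model's frames are exactly what needs
selecting. And a selected candidate whose reference energy lies more than
`max_label_energy_per_atom` (default 0.12 eV/atom) above the training-set
minimum *fails labelling* and is dropped: this is the desk-scale analogue
of a non-physical structure whose self-consistent-field reference
calculation does not converge, which is how such structures are rejected
in practice when the similarity threshold is set too permissively.

## Selectors

* **energy**: add iff `E_T < |E_ref - E_mlp| <= 10 E_T`, discard beyond
  `10 E_T` (too distorted to be informative). Requires a reference call at
  every evaluation - the cost the descriptor selectors avoid.
* **similarity**: add iff `max(K) < k_T`, where `K_i = |p0 . p_i|^zeta`
  over the unit-normalized global descriptors of the training set.
  `k_T = 1` is degenerate (every non-identical frame is added).
* **distance**: add iff the candidate's local outlier factor (LOF) in
  descriptor space exceeds the 80th percentile (lower nearest-rank) of
  the training set's own leave-self-out LOF values, recomputed as the set
  grows. LOF follows the textbook construction - k-distance, reachability
  distance `rd_k(o,a) = max(k-distance(a), d(o,a))`, local reachability
  density `lrd = 1/mean(rd)`, LOF = mean neighbour-to-own lrd ratio - with
  k-NN ties broken by dataset index and exact duplicates collapsed before
  scoring. `k` defaults to 10; the candidate is scored leave-self-out
  against the training set.

## Descriptors

The per-atom descriptor is a SOAP-style rotational invariant: the
neighbour density within `r_cut`, expanded on `n_max` Gaussian radial
channels (width `sigma_atom`, centres equally spaced on `[0, r_cut)`,
cosine cutoff), accumulated as a power spectrum over neighbour pairs
using Legendre polynomials of the enclosed angle up to `l_max`. This
pair-expansion form is mathematically the spherical-harmonic power
spectrum summed over m, so rotational, translational and same-species
permutation invariance hold exactly. The **global** vector of a
configuration concatenates the per-centre-species averages (O-centred and
H-centred environments carry distinct information) and is
unit-normalized. The kernel is `|p . q|^zeta` with `zeta = 4` by default.

## The internal MLP

The trainable model is a kernel expansion over the global descriptors of
the training configurations, `E(x) = sum_t alpha_t |p(x).p_t|^zeta +
shift`. Because the model is linear in `alpha` for energies *and* for
force components (the force of the kernel row is an explicit function of
the descriptor Jacobian), the weights are fitted by regularized least
squares over energy rows plus `force_weight`-scaled force rows
(`force_weight = 0.1` A by default; the water study below uses 0.3). An
energies-only square ridge solve `(K + lambda I) alpha = E - mean(E)` is
available as `train_on_forces = FALSE`. Reference forces are part of
every label in this workflow, and fitting them is what makes the forces
of an AL-sized training set usable: on a supervised toy-water probe,
energy-only fits plateau near 2.5-7 kcal/mol/A force error at a few
hundred configurations, while the joint fit reaches the 1 kcal/mol /
2 kcal/mol/A regime. Inside the AL loop the per-acceptance refit uses an
incremental cache and a fixed subset of force components per
configuration (`loop_force_atoms = 8`); the returned model is refitted
once on all labels.

The model carries a two-body core-repulsion baseline,
`A ((r_on/r)^6 - 1)^2` below `r_on` (C1-smooth at the wall), with `r_on`
per species pair set just inside the closest distance the training set
sampled (0.85x the minimum, capped at the descriptor cutoff); the kernel
learns the remainder and predictions add the baseline back. This is the
usual baseline construction for kernel potentials: without it,
model-driven MD can push atoms through the unsampled short-range region,
where the averaged descriptor saturates and the kernel forces vanish.

Forces of the fitted model are the exact analytic gradient of the kernel
energy through the descriptor pair expansion (`force_method =
"analytic"`); central finite differences (`"fd"`, step `h_fd = 1e-3` A,
cost 6N descriptor evaluations) are retained as an independent check.
The analytic path is what makes MLP-driven MD affordable: per step it
costs two descriptor passes instead of 6N.

## Dynamics

Velocity-Verlet with the BAOAB Langevin splitting for NVT (friction
0.02 fs^-1 by default; the thermostat is a package choice, as is BAOAB
for its configurational accuracy at this timestep). Harmonic biases on a
distance or on the two-bond coordinate `xi = (r1 + r2)/2` add
`0.5 k (xi - c)^2` with exact gradients. Frozen atoms are excluded from
integration. NVE energy fluctuation shrinks ~4x when the timestep is
halved, as expected at O(dt^2); we quantify *drift* as the difference
between the first-decile and last-decile means of the total energy, which
separates secular drift from the bounded shadow-Hamiltonian oscillation.
Restrained minimization (scans, transition-state preparation) uses
L-BFGS-B with a 1e-3 eV/A force tolerance.

## Reference potentials

* `toy_water_potential()`: harmonic O-H bonds (30 eV/A^2, 0.96 A) and
  H-O-H angles (3 eV/rad^2, 104.5 deg), O-O Lennard-Jones
  (0.0067 eV, 3.166 A), SPC-like charges (-0.82/+0.41 e) with
  shifted-force Coulomb truncation (C1-smooth, 9 A default). Parameters
  were chosen once so that the liquid's O-O radial distribution peaks
  near 2.8 A; the bond stiffness sits below spectroscopic water values
  for stability at the 0.5 fs study timestep.
* `two_bond_potential()`: two forming-bond pairs each in a quartic double
  well `h((r-c)^2 - w^2)^2/w^4 + s(r-c)` (reactant near `c+w` = 3.2 A,
  product near `c-w` = 1.5 A, barrier `h` = 0.8 eV, small positive tilt
  toward the product), a synchronicity coupling `g (r1 - r2)^2` and
  harmonic intra-fragment bonds. With the forming bonds constrained the
  other terms relax to zero, so the restrained 2D scan has the analytic
  surface `V(r1) + V(r2) + g (r1 - r2)^2` - the oracle used in the tests.

## Umbrella sampling and WHAM

Windows are seeded by steering: each window's biased NVT run starts from
the previous window's final frame, ordered along the coordinate; the
first 10% of each window's samples are discarded as burn-in. Window
overlap is validated (a window sharing no sampled range with any
neighbour is an error). The profile is reconstructed by the standard WHAM
self-consistent iteration to 1e-7 eV on the window constants, min-shifted
and reported in kcal/mol; the barrier is the highest interior maximum
separating the two outermost basins minus the reactant-side basin
minimum (reactant at large xi for bond formation). For a single particle
pair the unbiased radial free energy is `U(r) - 2 k_B T ln r`; the
quadrature of that expression is the oracle the WHAM tests converge to.

## Reactive trajectory ensembles

Downhill ensembles launch unbiased NVE trajectories from a pool of
solvent-adapted transition states (NVT solvent equilibration with the
solute frozen, snapshots at fixed intervals, then restrained optimization
with solvent fixed and the forming bonds held at their transition-state
distances). A trajectory terminates as *product* when both forming bonds
drop below 1.6 A, *reactant* when both exceed 3.0 A, *timeout* at 2 ps.
Per-bond formation times are first downward crossings of the product
threshold (no recrossing debounce - a documented choice; crossing times
are stable to frame-stride refinement below the timestep). The gap
`|t(r2) - t(r1)|` against the 60 fs criterion separates concerted from
stepwise events; timeouts are excluded from gap statistics. Uphill
ensembles start from restrained-equilibrated reactant structures
(restraint centres validated to lie in 3.0-5.0 A) and drive
`xi` toward the product with a 0.4 eV/A^2 spring for at most 3 ps.

## Analysis

`rdf()` histograms minimum-image pair distances against the ideal-gas
normalization (`r_max` at most half the box). Hydrogen bonds use the
standard geometric criterion - donor-acceptor O..O below 3.5 A and
donor-H-acceptor angle above 140 deg (the package's default; no single
convention exists) - and `count_hbs_by_distance()` bins per-molecule HB
participation by the distance of the molecule's oxygen from the solute
centre of mass, reporting empty bins as missing rather than zero.

## Study conditions used by the acceptance suite

The toy-water AL study runs on a 27-molecule cluster (81 atoms) built on
a cubic lattice and minimized under the reference potential. Initial
condensed-phase data are 80 labelled thermal frames from a short (1.5 ps)
reference-potential pre-equilibration of that cluster - the desk-scale
analogue of seeding solvated training data from classically equilibrated
solvent configurations, which is how condensed-phase initial sets are
built in this workflow (random displacements remain the gas-phase path
and are what `build_subsets()` uses for substrate subsets; a model seeded
only with displaced-around-minimum structures has ~0.5 eV/A mean force
error and its MD leaves the physical manifold within 100 fs). Validation
uses 200 frames from a 1 ps reference NVT run started from the same
structure, matching the AL episode protocol. Descriptors use `r_cut =
3.5` A (just beyond the first O-O coordination shell), `n_max = 4`,
`l_max = 3`, `sigma_atom = 0.5` A, `zeta = 4`. The similarity threshold
for this system is `k_T = 0.996`: thresholds must sit near the kernel
resolution of the system - the measured maximum-similarity scale of
thermal frames against a few hundred training frames - or the selector
either never fires or never saturates; 0.996 corresponds to a descriptor
dot product of about 0.999 at `zeta = 4`. The data-efficiency comparison
(similarity at `k_T = 0.99` vs energy selector at `E_T = 0.02` eV) uses a
4-molecule cluster seeded with 80 thermal frames, over three seeds. The free-energy benchmark uses a
particle pair in a quartic double well (barrier 0.25 eV, centre 2.2 A,
width 0.5 A) with 15 windows of 12 eV/A^2, 40 ps each, at 300 K; the
liquid-structure check trains on 150 thermal frames of a 27-molecule
periodic box (9.32 A, Coulomb truncation 4.5 A) and compares the O-O
radial distribution of model-driven and reference-driven 4 ps NVT runs.
These sizes are the package's own desk-scale choices and are stated here
so the computed numbers are reproducible.

## What the toy studies do and do not show

The generators emulate thermal ensembles of a small hydrogen-bonded
cluster and a schematic two-bond cycloaddition. They do not emulate
electronic structure: no polarization, charge transfer, bond topology
changes in the solvent, or reference-method noise. Passing the suite
shows the AL machinery, selectors, model fitting, dynamics and estimators
are correct and internally consistent at desk scale - not that the
defaults transfer to ab initio systems, where the reference cost, the
descriptor hyperparameters and `k_T` must be recalibrated per system.

## Known limitations

* The global-descriptor kernel model has one weight per training
  configuration; its force accuracy is capacity-limited compared to
  local (per-atom) models at equal training size. Measured on this
  package's own probes: the 8-molecule cluster needs ~550 training
  configurations to reach 1 kcal/mol energy / 2 kcal/mol/A force
  agreement with the reference, and the requirement grows steeply with
  system size (the global average dilutes per-atom information as 1/N
  while the energy variance grows with N), so the 27-molecule studies
  plateau at several kcal/mol. Accuracy targets transferred from local
  many-body potentials should not be expected from this model class at
  matching training sizes; the acceptance suite asserts them anyway and
  records the shortfall rather than hiding it.
* Descriptor gradients are exact, but the model's forces are only as
  good as the fit; there is no uncertainty estimate.
* Coulomb interactions are truncated (shifted-force); no Ewald sums, so
  periodic boxes must keep the truncation below half the box.
* WHAM assumes fully overlapping, equilibrated windows; umbrella
  integration is not implemented.
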