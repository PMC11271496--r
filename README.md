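# mlal — active learning for reactive machine-learning potentials

`mlal` trains reactive machine-learning interatomic potentials (MLPs) by
descriptor-driven active learning (AL) and analyses the resulting reaction
dynamics, all in R with the inner numerics in C++. It targets the
condensed-phase workflow where every training label is an expensive
reference (ab initio) calculation: the AL loop runs short MD episodes with
the current model and asks a *selector* whether the last frame is worth
labelling.

Three selectors are implemented:

* **energy** — add when `E_T < |E_ref − E_mlp| ≤ 10·E_T`; discard frames
  beyond `10·E_T` as too distorted (needs a reference call per evaluation);
* **similarity** — add when `max(K) < k_T`, with
  `K_i = |p₀ · p_i|^ζ` the SOAP-kernel similarity vector of the candidate
  descriptor `p₀` against the training descriptors `p_i`;
* **distance** — add when the candidate's local outlier factor (LOF) in
  descriptor space,
  `LOF_k(o) = mean_i lrd_k(i) / lrd_k(o)` over the `k` nearest
  neighbours (with `lrd` the inverse mean reachability distance
  `rd_k(o,a) = max(k-distance(a), d(o,a))`), exceeds the 80th percentile
  of the training set's own LOF values.

MD episodes last `n³ + 2` fs (0.5 fs timestep), where `n` counts
consecutive episodes without a selection; the run is converged when the
next episode would exceed the 5 ps cap with nothing selected. The internal
MLP is kernel ridge regression over unit-normalized global SOAP-style
descriptors, fitted to reference energies and forces; built-in analytic
potentials (flexible point-charge water, a two-bond double-well reactive
model) stand in for the reference method, so everything runs at desk
scale. The reaction toolkit covers relaxed 2D scans, umbrella sampling
with WHAM reconstruction of the free-energy profile along
`ξ = (r₁ + r₂)/2`, downhill/uphill trajectory ensembles with
bond-formation time gaps (60 fs concerted/stepwise criterion), radial
distribution functions and hydrogen-bond statistics.

## Worked example

Active learning on a small water cluster against the analytic reference:

```r
library(mlal)

reference <- toy_water_potential()
cluster <- minimize_config(build_water_cluster(4, rng_seed = 3),
                           reference, maxit = 2000)$config
# condensed-phase initial data: labelled thermal frames from a short
# pre-equilibration of the cluster
equil <- run_md(cluster, reference,
                md_params(dt = 0.5, temperature = 300, duration = 3000,
                          rng_seed = 21), stride = 20)
nf <- traj_n_frames(equil)
initial <- configuration_set(lapply(round(seq(nf %/% 3, nf, length.out = 80)),
                                    function(i) traj_frame(equil, i)))

cfg <- al_config("similarity", similarity_selector_config(k_T = 0.99, zeta = 4),
                 soap = soap_params(c("O", "H"), r_cut = 3.5, n_max = 3,
                                    l_max = 3),
                 temperature = 300, force_weight = 0.3, rng_seed = 1,
                 max_label_energy_per_atom = 0.25)
run <- al_train(initial, reference, cfg)
run$converged
#> [1] TRUE
length(run$training_set)
#> [1] 91
table(run$log$verdict)
#>          add label_failed         skip
#>           11           15           36

heldout <- run_md(cluster, reference,
                  md_params(dt = 0.5, temperature = 300, duration = 1000,
                            rng_seed = 602), stride = 20)
frames <- configuration_set(lapply(2:101, function(i) traj_frame(heldout, i)))
mad_metrics(run$model, reference, frames)
#> $mad_energy
#> [1] 2.919762
#> $mad_forces
#> [1] 7.624436
```

The loop converged by the 5 ps rule after 11 acceptances (15 candidates
failed the labelling guard, 36 were skipped as already-known);
`run$training_set` carries per-configuration provenance (selector,
iteration, verdict) and `run$log` one row per episode. `mad_metrics()`
returns the mean absolute deviation of the model against the reference in
kcal/mol (energies) and kcal/mol/Å (force components) over held-out
frames — the two accuracy numbers used throughout. The several-kcal/mol
deviation of this tiny run is expected: the global-kernel model carries
one weight per training configuration, so accuracy is training-set
limited (see the vignette's limitations section for the measured
capacity curve).

Free energies on the built-in reactive model:

```r
pot <- double_well_pair_potential(barrier = 0.25, centre = 2.2, width = 0.5)
rc  <- reaction_coordinate(c(1, 2), c(1, 2))
cfg0 <- configuration(c("O", "O"), rbind(c(0, 0, 0), c(2.7, 0, 0)))
wins <- run_umbrella(pot, rc, data.frame(center = seq(1.6, 2.9, length.out = 12),
                                         k = 15),
                     md_params(duration = 20000, rng_seed = 1), cfg0)
fes <- reconstruct_fes(wins)
fes$barrier   # kcal/mol, relative to the reactant basin
```

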