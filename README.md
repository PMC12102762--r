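# peripose

Quantitative analysis of how peripheral membrane proteins bind lipid
bilayers in molecular dynamics trajectories, plus free-energy-perturbation
(FEP) bookkeeping for alchemical mutation scans of membrane affinity.

The package grew out of the analysis needs of a cis-prenyltransferase /
ER-membrane binding problem — a nominally soluble enzyme that must dock
onto the membrane surface to hand over its lipophilic product — but every
component is generic: give it a topology, coordinate frames and two atom
selections and it will profile any protein–membrane encounter.

## What it computes

**Weighted contacts.** A heavy-atom pair at distance $d$ contributes a
fractional contact through a logistic kernel,

$$C_i = \sum_{j \in B} \frac{1}{1 + \exp\!\big[5\,\text{Å}^{-1}(d_{ij} - 4\,\text{Å})\big]},$$

where $B$ is the set of membrane heavy atoms. Per-residue time series,
trailing-window means, cumulative profiles along a chain-concatenated
residue axis, and association/dissociation event detection (total contacts
persistently crossing a threshold) are built on this statistic.

**Insertion depths.** Per residue and frame, the signed z-distance between
the membrane's geometric centre and the residue heavy atom nearest that
centre; histograms over the trailing window and classification of residues
that breach the surface (the mean phosphate plane per leaflet).

**Pose free energies.** The tilt angle between the vector joining two
anchor residues and the membrane normal, Boltzmann-inverted per bin:

$$\Delta G = -kT \ln(P_1 / P_2),$$

with $P_1$ the frames in a tilt bin and $P_2$ the frames outside it,
reported in kT units. `most_favored_tilt()` returns the minimum of the
profile.

**FEP cycles.** Per-λ-window free energies by the exponential (Zwanzig)
estimator or the Bennett acceptance ratio (BAR), summed over the 15-value
λ schedule (45 ns per transition, 90 ns per bidirectional reaction at the
default 3 ns/window), and the thermodynamic-cycle relative binding free
energy of a mutation,

$$\Delta\Delta G = \Delta G_\text{bound} - \Delta G_\text{solution},$$

positive when the mutation weakens membrane binding. NAMD-style `fepout`
files and generic TSV work tables are both accepted; harmonic
positional-restraint energies ($U = k\,|x - x_\text{ref}|^2$, $k = 1$
kcal/mol/Å²) can be audited across λ windows.

**Synthetic ground truth.** A generator produces a slab pseudo-bilayer
with an ER lipid recipe (100 lipids per leaflet, net charge −10), scripted
approach/bind/wobble/unbind trajectories with planted anchor depths and
tilt distributions, and Crooks-consistent Gaussian work samples with known
free energies — so every estimator in the package is tested against known
answers.

## Worked example

```r
library(peripose)
library(dplyr)

mem  <- build_membrane_slab(scale = 0.5)                  # 50 lipids/leaflet
prot <- build_protein_template(n_res = 10, length_A = 30)
scen <- binding_scenario(phases = c(approach = 50, bound = 450),
                         anchor_depth = 9, tilt_mode = 42, tilt_sd = 8,
                         seed = 11)
sim <- simulate_binding_trajectory(scen, mem, prot)

top      <- sim$trajectory$topology
protein  <- make_selection(top, "protein and heavy")
membrane <- make_selection(top, "membrane and heavy")

ser  <- contact_series(sim$trajectory, protein, membrane)
head(cumulative_profile(window_mean_profile(ser, 0.5)), 3)
#>   chain residue_id global_index mean_contact cumulative
#> 1 A              1            1         5.00       5.00
#> 2 A              2            2         6.90      11.9
#> 3 A              3            3         6.02      17.9

detect_dissociation(total_contact_series(ser), 0.5,
                    persistence_frames(sim$trajectory, 10))
#> <pp_dissociation> associated at frame 37; 0 dissociation event(s)

residue_depth_series(sim$trajectory, protein, membrane) |>
  filter(residue_id == 1, frame > 50) |>
  summarise(mean_depth = mean(depth))
#>   mean_depth
#> 1       8.74        # planted: 9 Angstrom

ts <- tilt_series(sim$trajectory, tilt_spec(c("A", 1), c("A", 10)), 0.5)
most_favored_tilt(pose_free_energy(ts, bin_width = 2))
#> [1] 41              # planted mode: 42 degrees, 2-degree bins

bound <- simulate_fep_leg(fep_scenario(dg_per_window = 3.27 / 14,
                                       sigma = 1.5, seed = 12))
soln  <- simulate_fep_leg(fep_scenario(dg_per_window = 0,
                                       sigma = 1.5, seed = 13))
ddg_cycle(
  leg_free_energy(bound$work, leg = "bound",    mutation = "W238A-F241A"),
  leg_free_energy(soln$work,  leg = "solution", mutation = "W238A-F241A")
)
#> <pp_cycle> W238A-F241A: ddG = 3.261 +/- 0.298 kcal/mol (bound 3.295, solution 0.034)
```

The contact profile concentrates at the membrane-proximal anchor end of
the rod; the recovered anchor depth, favoured tilt and cycle ΔΔG all land
on their planted values within the estimators' reported uncertainty.

Real trajectories enter through `read_structure()` (PDB) and
`read_trajectory()` (DCD, concatenating replicas), and the same analyses
run through the config-driven `run_contacts()` / `run_depth()` /
`run_tilt()` / `run_fep()` / `run_simulate()` stages, which write TSV
tables and a manifest for exact reruns (schema in
`inst/config-schema.yaml`).

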