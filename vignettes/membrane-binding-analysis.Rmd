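---
title: "Methods: quantifying peripheral membrane binding and mutation effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying peripheral membrane binding and mutation effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peripose)
```

peripose analyses molecular-dynamics trajectories of peripheral membrane
proteins — proteins that dock reversibly onto a bilayer surface rather
than spanning it — and estimates how point mutations shift their membrane
affinity. This vignette is the package's own account of the underlying
models, the defaults and why they hold, the numerical choices, and what
the synthetic-data tests do and do not demonstrate.

## Conventions and assumptions

* Coordinates are Angstrom, times ns, energies kcal/mol unless a result is
  explicitly in kT units. Atom and frame indices are 1-based (R
  convention); residue identifiers keep their source numbering.
* The membrane normal is the z axis, and trajectories are assumed
  pre-wrapped with the bilayer contiguous. `rewrap_z()` recentres the
  membrane at z = 0 per frame when a run drifted along the normal. Boxes
  are orthorhombic, and the minimum-image convention is applied along z
  only, where the periodic bilayer image actually matters for distances.
* All contact and depth statistics use heavy (non-hydrogen) atoms only.
  Hydrogens are identified from the element column when a PDB provides
  one, otherwise by the leading-letter rule on the atom name after
  stripping digits (`H`, `1H`, `2HB1`, ...), since CHARMM-dialect PDB
  files often omit the element column.
* Multi-chain proteins are plotted on a chain-concatenated residue axis:
  the first chain keeps its source numbering and each further chain is
  appended after the previous chain's maximum, so a catalytic chain
  numbered 1–333 followed by a partner chain 76–293 spans global indices
  1–551.

## The weighted contact statistic

A hard distance cutoff makes contact counts jump discontinuously as atoms
cross it. The package instead weights every heavy-atom pair by a logistic
kernel, `1 / (1 + exp(s (d - d0)))`, with steepness `s = 5` per Angstrom
and midpoint `d0 = 4` Angstrom: a pair at 4 Å counts as half a contact, at
3 Å as 0.993, at 5 Å as 0.007. A residue's contact count sums the kernel
over all (residue heavy atom, membrane heavy atom) pairs.

Two aggregation conventions were possible — summing the kernel over a
residue's atoms, or taking a per-atom maximum. The package sums: summation
preserves additivity over membrane subsets (a property the tests verify
exactly) and reproduces the magnitudes of cumulative contact profiles; the
alternative is deliberately not offered as a hidden switch. The membrane
universe defaults to membrane heavy atoms because the quantity of interest
is protein–membrane contact; passing any other heavy-atom selection gives
the literal all-heavy-atom variant.

No cutoff truncation is applied by default — at 12 Å the kernel weight is
below 4e-18, so truncation would only matter for speed, and the systems
this package targets at analysis scale do not need it.

**Dissociation detection** scans the per-frame total contacts with a
two-state machine: the protein associates at the first frame where the
total holds at or above a threshold (default 0.5 contacts) for a
persistence window, and dissociates at the first subsequent frame where it
holds below the threshold equally persistently. The default persistence is
the number of frames spanning 10 ns, which suppresses single-frame
flickers while still registering genuine unbinding; both parameters are
exposed because the right values depend on the save frequency and the
noise floor of the system.

## Insertion depths

For each residue and frame the package reports the signed z-offset from
the membrane's geometric centre (the mean z of all membrane heavy atoms,
not only phosphates) of the residue heavy atom *nearest* that centre.  For
a protein sitting on one leaflet this atom is also the residue's deepest
non-hydrogen atom, which is why the two phrasings coincide; depths are
kept signed, with an `absolute` flag in the histogram stage for users who
want folded distributions.

The membrane *surface* needs an operational definition; the package uses
the mean phosphorus z per leaflet (atoms above vs. below the centre), the
conventional choice for phosphate-bearing bilayers. A residue "breaches"
the surface when more than 5% (default) of its depth-histogram mass lies
inside the surface planes. Histograms use 0.5 Å bins over the trailing
half of the trajectory by default, matching the practice of analysing the
equilibrated second half of a run.

## Tilt-angle pose free energies

The binding pose is summarised by one angle: between the vector joining
the heavy-atom geometric centres of two anchor residues and the +z axis.
The two-residue definition is used throughout (an alpha-carbon-only centre
rule is available); a three-point variant that also involves the N-terminus
appears in some descriptions of this analysis but is not implemented,
because the two-residue form is the one stated precisely enough to code.
Angles live on [0, 180] degrees and are not folded to [0, 90]: a bound
protein defines an oriented vector, and folding would alias distinct
poses.

Occupancy converts to free energy by Boltzmann inversion,
`dG = -kT ln(P1/P2)`, with `P1` the frames in a bin and `P2` all other
frames. Results are reported in kT units — the natural unit for a
single-molecule pose statistic — with the temperature only entering if a
kcal/mol conversion is requested (default 310 K). Empty bins are flagged
`+Inf` and excluded from minimum searches; a bin holding every frame would
be `-Inf`. Swapping `P1` and `P2` negates `dG` exactly, and occupancy
ranks mirror free-energy ranks; both identities are tested.

The default bin width is 2 degrees: narrow enough to resolve a 10-degree
separation between two pose modes, wide enough that a few thousand frames
give usable per-bin counts. One estimator property is worth knowing: when
the planted mode sits exactly on a bin edge (42° with 2° bins), the two
adjoining bins carry equal mass, so the argmax legitimately lands in
either — and, with finite sampling, occasionally one bin further out. The
acceptance analyses therefore pool several replicas (25 000 frames) before
binning, as one would pool the last halves of several production runs.

## FEP estimation

The alchemical protocol uses 15 λ values (0, 0.02, 0.05, 0.1, 0.2 ... 0.9,
0.95, 0.98, 1), i.e. 14 adjacent windows, with 3 ns of sampling per window:
45 ns per transition and 90 ns for a forward+backward reaction. The
coverage checker demands every adjacent pair exactly once (per direction
for BAR) and rejects both gaps and windows outside the schedule.

Two per-window estimators are provided:

* **EXP (Zwanzig)**: `dG = -kT ln <exp(-dU/kT)>`, evaluated via
  log-sum-exp so large energies cannot overflow. Its standard error comes
  from block averaging over 5 contiguous blocks — enough blocks for a
  variance estimate, few enough that each block retains serial
  correlation structure.
* **BAR (Bennett acceptance ratio)**: the statistically optimal
  bidirectional estimator. With `M = kT ln(nF/nR)` and the Fermi function
  `f`, the estimate solves
  `sum_F f((M + wF - dG)/kT) = sum_R f((-M + wR + dG)/kT)`.
  The placement of `M` follows from the Crooks relation and was verified
  by simulation to leave the estimator unbiased at `nF != nR`. The
  residual is strictly monotone in `dG`, so the root is found by Brent
  bracketing (an expanding bracket around the work-mean initial guess)
  rather than damped fixed-point iteration — same contract, guaranteed
  convergence; the residual is checked against the tolerance (1e-8
  kcal/mol) on return. The standard error is the delta-method variance of
  the implicit equation, which calibrates well against the empirical
  scatter of repeated synthetic estimates (verified in development at
  n = 500/direction). In the zero-variance limit BAR and EXP both equal
  dU exactly, and BAR is antisymmetric under exchanging the two
  directions.

Leg totals sum window estimates; leg errors add window errors in
quadrature, which treats windows as independent — correct for the
synthetic generator and the standard assumption for production FEP. The
thermodynamic cycle subtracts the solution leg from the bound leg,
`ddG = dG_bound - dG_solution`, so positive values mean the mutation
weakens membrane binding. Temperature is a required estimator input with a
310 K default (a physiological choice; the exact simulation temperature
should be supplied when known).

**Restraints.** Bound-state FEP runs restrain protein alpha-carbons and
membrane phosphates to reference coordinates with
`U = k |x - xref|^2`, `k = 1` kcal/mol/Å². That published form carries no
1/2 prefactor, and the package implements it exactly as printed, with a
`half_factor` flag for the conventional `k/2` form used by MD engines.
`restraint_audit()` summarises the per-frame restraint energy by λ window,
the standard consistency check that the restraint load does not drift
across the schedule.

**File formats.** NAMD-style `fepout` files are parsed directly
(equilibration records before the collection marker are discarded; window
direction is inferred from the λ ordering), and a generic TSV work table
(`lambda_start`, `lambda_end`, `direction`, `delta_u`) makes the module
engine-agnostic.

## The synthetic-data generator

The generator exists so that every estimator can be exercised against
known answers; it makes no pretence of physics.

* **Membrane**: two leaflets of pseudo-lipids on square grids (8 Å
  spacing), each lipid one "P"-named atom at the phosphate plane (±16 Å)
  plus four tail carbons at 2 Å steps toward the centre. Species counts
  follow an ER-like recipe (per 100 lipids: 61 PC+PE across tail
  variants, 6 PI, 3 PS, 4 SM, 1 PA, 5 cholesterol; 10 anionic lipids give
  a net charge of −10 per leaflet), scaled by largest-remainder rounding
  with table-order tie-breaks, so scaled compositions conserve totals
  exactly (a 1.9 scale gives the 190-lipid leaflets of a full-size
  model).
* **Binding trajectories**: a rigid rod-shaped protein template (residues
  along an axis, three clustered heavy atoms plus one hydrogen each)
  moves through a scripted phase sequence. In the bound phase the deep
  anchor residue is held at its planted depth (default 9 Å from the
  centre, i.e. inside the surface) and the tilt is drawn per frame from a
  normal at the planted mode, wrapped mod 360 and folded to [0, 180] —
  exactly the distribution of an axis angle, preserving the mode. In
  diffuse/dissociated phases the protein's lowest atom is held ~30 Å
  above the surface regardless of orientation, so contacts are
  numerically zero by construction; the approach phase interpolates
  linearly. Gaussian positional noise (0.25 Å) is added per atom.
  Everything is bit-reproducible under the scenario seed.
* **Work samples**: for each window, forward work is
  `N(dG + sigma^2/2kT, sigma^2)` and backward work
  `N(-dG + sigma^2/2kT, sigma^2)` — the Gaussian pair satisfying the
  Crooks fluctuation relation with free energy `dG`.

What passing tests on this generator *show*: the estimators implement
their definitions, recover planted parameters within their reported
uncertainties, and respect their exact identities (additivity,
equivariance, antisymmetry, conservation). What they *do not* show:
behaviour on real trajectories with conformational flexibility, lipid
dynamics, leaflet undulations, correlated work samples, or slow pose
relaxation. In particular the quadrature leg error assumes independent
windows, and real FEP sampling error can exceed the statistical error
substantially when the restrained starting snapshot biases the
transformation.

## Problem sizes

The shipped tests and the acceptance analysis are sized for a desk run:
membranes at 0.2–0.5 of the reference recipe (20–50 lipids per leaflet),
rod proteins of 5–12 residues, trajectories of tens to a few thousand
frames (5 000 per replica for pose statistics, pooled over five
replicas), and FEP legs of 14 windows with 500 samples per direction at
sigma = 1.5 kcal/mol. These sizes keep the full suite under a minute
while leaving every estimator in its asymptotic regime.

## Known limitations

* Trajectory input is PDB and DCD; XTC is not read (no XTC reader exists
  in the R ecosystem this package builds on, and the compressed-coordinate
  codec is out of scope here). Convert with any standard tool first.
* No trajectory alignment/fitting, no force-field or connectivity
  parsing, no leaflet assignment, curvature or thickness analysis.
* BAR is pairwise; multi-state estimators (MBAR/WHAM) are out of scope.
* The dissociation classifier is threshold-based by design; systems
  hovering at the threshold need the persistence window tuned to their
  save frequency.
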