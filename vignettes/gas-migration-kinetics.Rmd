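---
title: "Three-state kinetics of gas migration through a protein matrix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-state kinetics of gas migration through a protein matrix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

Heme gas sensors such as bacterial H-NOX domains bind NO, CO or O2 in two
stages: the ligand first diffuses from the solvent through the protein
matrix into the distal pocket next to the heme iron, and only then forms a
chemical bond. `gasflux` quantifies the *diffusion* stage from molecular
dynamics trajectories of one protein copy plus tens of free gas molecules
in a periodic cell.

Every gas molecule in every frame is assigned one of three states from two
distances, both computed on the ligand's reference point (its site
center of mass for the kinetic analysis, the central "dummy" site of
three-site diatomic models for contact analysis):

* **G** ("geminate pair"): distance to the heme Fe `< 3.5` Å.
* **P** ("protein"): not geminate, but `< 6` Å from some protein heavy atom.
* **S** ("solvent"): everything else.

Both comparisons are strict `<`, mirroring the `>=` conditions that define
the complementary states in the source protocol. A complete passage
S → P → G is a *global in event*; G → P → S a *global out event*.
Oscillations that do not complete a passage (G↔P or P↔S) are not counted.
The counter is a two-state anchor automaton per ligand: the anchor starts
at the ligand's first non-P state (an equilibrated trajectory may begin
mid-passage), an entry into G while anchored at S counts one in event, and
an entry into S while anchored at G counts one out event. The number of
completed cycles is `min(n_in, n_out)` per ligand, summed; a final entry
without a return is reported but not counted, because in equilibrium the
two event counts must balance. An equivalent formulation — delete P's,
collapse repeats, count SG and GS adjacencies — is used as an independent
oracle in the test suite, where both are checked against each other for
every state string up to length 8.

With `N` completed cycles over simulation time `t` in a cell of volume `V`
(dm^3), copy numbers are converted to concentrations as `c = n/(N_A V)`
and the rate constants of the diffusion step are

* entry: `k1 = N / (N_A t V [Protein][XO]) = N N_A V / (t n_p n_l)`
  in M^-1 s^-1, with `[XO]` formed from the **total** ligand copy number
  of the analyzed species (the reading that reproduces the reference
  calculations; in mixtures each species uses its own copy number),
* exit: `k-1 = N / t_geminate` in s^-1, because during occupancy the
  complex concentration is exactly one copy per cell,
* equilibrium: `K = k1 / k-1` in M^-1.

Geminate residence `t_geminate` accumulates as (number of G frames) × dt
with the entry frame counted and the exit frame not (half-open runs); the
identity `k-1 × t_geminate = N` is exact by construction.

The same exit equation can be inverted: given a target release rate
constant, a protein concentration and a cell volume,
`residence_time_for_rate()` returns the pocket residence time that would
produce that rate by ligand release alone
(`t = 1/(k_off N_A V [Protein])` for one event). The package exposes both
concentration conventions here — a printed concentration can be passed
directly, or derived from copies via `copies_to_molar()` — because the
reference thought experiment uses a printed 0.044 M concentration that is
ten-fold larger than one copy in its quoted 3.78e-22 dm^3 cell would give;
the published 1.64 ms figure is only reproducible with the printed value,
so no intent is guessed and the caller chooses.

## Parameters that matter

| parameter | default | unit | meaning |
|---|---|---|---|
| `geminate_cutoff` | 3.5 | Å | Fe–ligand bound of the geminate state |
| `protein_cutoff` | 6.0 | Å | protein heavy-atom bound of the protein state |
| `contact_cutoff` | 4.0 | Å | contact distance for descriptors and pocket ranking |
| `top_fraction` | 0.5 | – | upper fraction of contacted atoms kept for pockets |
| `occupancy_cutoff` | 3.5 | Å | centroid–ligand bound of pocket occupancy |
| `cluster_linkage_cutoff` | 5.0 | Å | single-linkage join distance for pockets |
| `equilibration_cut` | 0 | ps | leading trajectory span discarded |
| `dt` | 4 | ps | frame spacing |
| `volume` | from box | dm^3 | periodic-cell volume in the rate equations |

Distances are minimum-image in an orthorhombic cell by default (`wrap =
FALSE` is available because the source protocol does not state whether
wrapping was applied). The original simulations used a dodecahedral cell;
an orthorhombic treatment is sufficient because the kinetic model consumes
only the cell *volume*, which is shape-independent. A sanity band
(1e-23–1e-20 dm^3) guards against unit slips in the volume; it can be
overridden.

Two readings in the source protocol were ambiguous and are resolved as
follows. The state list labels both its second and third state "protein";
the third is read as the solvent state (an evident typo, as the in/out
event definitions require a solvent state). Whether contact ranking uses
all ligand sites or only the dummy site is ambiguous; the dummy site is
the default, with an all-sites option via the `reference` argument.

# Structure metrics

RMSF is computed per atom as the root mean square displacement about the
time-average position after rigid-body superposition, aggregated per
residue (mean over the residue's heavy atoms by default; pass a Cα-only
selection for a backbone profile — the source does not state which
convention it used, so both are available), and reported in nm with a
0.15 nm flagging threshold for mobile regions. Superposition is a two-pass
Kabsch fit: frames are fitted to frame 1, their mean structure becomes the
reference, and frames are refitted — the standard convention when the
reference is not stated. Fitting removes six rigid degrees of freedom and
therefore deflates pure-noise RMSF by about `sqrt(1 - 6/(3 n_atoms))`;
validation against the closed-form jitter law is accordingly done on
unfitted jitter trajectories.

Global descriptors are the per-frame averages of (i) ligands inside the
matrix (state P or G), (ii) protein heavy-atom contacts within 4 Å summed
over those ligands, and (iii) their ratio. The published values of these
descriptors for the real proteins require the original trajectories, which
are not deposited; the package fixes the schema and validates the
arithmetic against brute-force recounts instead.

# Pocket identification

The reference analysis ranked protein heavy atoms by ligand contacts,
kept the upper 50%, and grouped close-lying residues into pockets *by
visual inspection*. The package substitutes a deterministic equivalent:
single-linkage clustering of the trajectory-averaged positions of the top
atoms at a 5 Å join distance, discarding clusters under 3 atoms. Ties at
the top-fraction boundary are all kept (so the set can exceed the nominal
size), which keeps the selection deterministic under reordering. Occupancy
uses the same half-open run convention as geminate residence, so
`mean_residence × n_events = occupied_frames × dt` exactly, and the
per-frame simultaneous-ligand average is taken over occupied frames only
(consistent with published occupancy/average pairs such as 1.32 at <100%
occupancy). The distal site is scored around the per-frame Fe position
(with the mean Fe–ligand distance over occupied pairs reported); a
proximal site can be scored around any user-chosen anchor residue.

# Synthetic data: what it emulates, and what it does not

Three generators provide data with the statistical structure the
estimators assume, with known ground truth:

* **Markov chains** (`generate_markov_states()`): independent
  continuous-time chains over S/P/G with direct S↔G jumps forbidden,
  sampled with exact exponential event times and then discretized on the
  frame grid, so dwell statistics carry no integration bias beyond the
  grid itself. The generator returns the analytic effective geminate
  escape rate `q_GP q_PS/(q_PS + q_PG)` — the rate at which an anchored
  geminate ligand completes a passage to solvent per unit geminate time —
  which is exactly what `N/t_geminate` estimates. Validation uses dwell
  means far above the 4 ps grid (400/25/500 ps at the default recovery
  rates) so that sub-frame excursions, which merge or hide events, stay
  an order of magnitude below the three-standard-error Poisson band of
  roughly 5000 recovered cycles.
* **Brownian toy shell** (`generate_toy_system()`): a static spherical
  pseudo-protein (radius 9.5 Å, 400 atoms, 1.5 Å hard core) with an Fe
  site at its center and three 45° channels, in a periodic cube of edge
  73 Å holding 40 point ligands (0.17 M, matching the simulated gas
  solutions) stepped by per-coordinate Gaussian moves of 2 Å per 4 ps
  frame (about 5e-9 m^2/s, a light gas in water). The shell radius is the
  largest for which every interior point is geminate or protein under the
  6 Å cutoff, so the cavity never reads as solvent; the closed surface
  keeps every point within 1.28 Å of an atom, and moves are
  collision-checked along the whole step segment at 0.5 Å resolution, so
  a shell with closed channels provably admits no entries. At the default
  scale (25,000 frames, 100 ns-equivalent, minutes on one CPU) the open
  system yields on the order of 10^2 completed cycles. The toy reproduces
  the *statistical* structure — stochastic entry, competition for a small
  geminate volume, channel blocking — but none of the energetics of a
  real matrix: there is no attraction, so it cannot reproduce the high
  in-protein occupancies or residence hierarchies of real pockets, and
  passing toy tests says nothing about force-field realism.
* **Jittered structures** (`generate_jittered_structure()`): i.i.d.
  isotropic Gaussian displacements about a base structure; per-atom RMSF
  converges to σ√3, giving a closed-form target for the RMSF estimator
  (validated at 500–800 frames, where the three-standard-error band is a
  few percent).

All generators are bit-reproducible given their spec and seed (R's
default Mersenne-Twister RNG; the seeding scheme is part of the API and
stable across releases).

# Numerical and design choices

* Strict `<` at both classification cutoffs; exact boundary values fall
  to the outer state.
* Minimum-image displacement per dimension via `x - L round(x/L)`;
  validated against a 27+-image brute force.
* Contact-count ties in the atom ranking break by atom index; pockets
  sort by size, then lowest member index, for deterministic output.
* Split-half consistency recomputes both constants on each half of the
  frame range and reports `|a-b|/mean`; halves without events are flagged
  rather than propagated as spurious deviations.
* Classification of a species in a mixture run uses that species' copy
  number; species interact only through the trajectory itself.
* Fewer than 5 completed cycles raises a low-sampling flag on every
  kinetics result and a warning in the pipeline report, matching the
  caution the reference analysis attaches to its least-sampled system.
* The pipeline (`run_pipeline()`) is the package's orchestration surface
  (there is no shell executable; an R function plus the persisted
  CSV/JSON report fills that role). Reports carry a config hash, package
  versions and all warnings for provenance.

# Known limitations

* Tunnel geometry (pathway tracing between pockets) is out of scope; the
  package quantifies pockets and global passage statistics only.
* The chemical bond-formation step (spin-forbidden Fe–XO binding) is not
  modeled; computed `k-1` values cannot be compared directly to
  experimental `k_off`, which bond scission dominates.
* Published per-protein descriptor and pocket tables cannot be reproduced
  without the original (undeposited) trajectories; the package asserts
  their schema and validates all arithmetic on synthetic ground truth.
* The orthorhombic cell treatment assumes the input box is orthorhombic;
  triclinic cells must be converted upstream.

# A worked desk-scale example

```{r, eval = FALSE}
library(gasflux)

# published inputs: 14 CO passages in 300 ns, 16.4 ns geminate residence,
# 3.78e-22 dm^3 cell, 1 protein and 40 CO copies
ki <- kinetics_input(14, 300e-9, 16.4e-9, 3.78e-22, n_protein = 1,
                     n_ligand = 40)
signif(rate_in(ki), 2)   # 2.7e8  M^-1 s^-1
signif(rate_out(ki), 2)  # 8.5e8  s^-1

# end-to-end on the synthetic toy system
bundle <- run_pipeline(list(simulate = list(), seed = 1))
bundle$table1
```
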