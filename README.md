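# gasflux

Kinetics of diatomic gas (NO, CO, O2) migration through a heme protein's
matrix, from molecular dynamics trajectories.

Heme-based gas sensors — the bacterial H-NOX domains among them — bind
their ligand in two stages: the gas molecule first *diffuses* from the
solvent through the protein matrix into the distal pocket beside the heme
Fe(II), and only then forms a chemical bond. The diffusion stage has its
own kinetics, distinct from the experimentally measured overall
k_on/k_off, and it can be read directly off an equilibrium MD trajectory
of one protein copy surrounded by free gas molecules. `gasflux` is a
toolkit for exactly that analysis, for structural-bioinformatics users
working with GROMACS-style trajectories or synthetic benchmarks.

## The model

Every ligand in every frame is assigned one of three states by its
reference point (site center of mass, or the central dummy site of
three-site gas models):

* **geminate pair (G)** — within 3.5 Å of the heme Fe,
* **protein (P)** — otherwise within 6 Å of any protein heavy atom,
* **solvent (S)** — everything else.

A complete passage S → P → G is a global *in* event, G → P → S a global
*out* event; oscillations that do not complete a passage are ignored (an
anchor automaton per ligand enforces this). From N completed cycles in
simulation time t in a periodic cell of volume V, with concentrations
formed from copy numbers as c = n/(N_A·V):

    k1  = N / (N_A t V [Protein][XO])  =  N·N_A·V / (t·n_p·n_l)   [M^-1 s^-1]
    k-1 = N / t_geminate                                           [s^-1]
    K   = k1 / k-1                                                 [M^-1]

where t_geminate is the total time ligands spend in the geminate state.
Around this core the package provides per-residue RMSF profiles (with
two-pass Kabsch superposition), global gas–protein contact descriptors,
contact-based pocket identification with occupancy/residence statistics,
a three-state Markov generator and a Brownian toy shell system for
validation, and a `run_pipeline()` orchestrator that emits the full
report (kinetics, descriptor and pocket tables, RMSF profile, state
matrices) as CSV/JSON.

## Worked example

Rate constants from a published-style input — 14 complete CO passages in
a 300 ns trajectory with 16.4 ns of geminate residence, one protein and
40 CO copies in a 3.78×10⁻²² dm³ cell:

```r
library(gasflux)
ki <- kinetics_input(14, 300e-9, 16.4e-9, 3.78e-22, n_protein = 1, n_ligand = 40)
signif(rate_in(ki), 2)   # 2.7e+08   entry rate constant k1, M^-1 s^-1
signif(rate_out(ki), 2)  # 8.5e+08   exit rate constant k-1, s^-1
```

The exit equation inverted — the pocket residence time that would, by
release alone, yield hemoglobin's O2 release rate of 61.1 s⁻¹ at 0.044 M
protein in the same cell:

```r
residence_time_for_rate(61.1, 0.044, 3.78e-22) * 1e3  # 1.634043 ms
```

End to end on the synthetic toy shell (40 ligands at 0.17 M around a
channeled pseudo-protein, 25,000 frames at 4 ps; a few minutes on one
CPU):

```r
bundle <- run_pipeline(list(simulate = list(), seed = 1))
bundle$table1
#>     species n_in_out t_sim_ns t_geminate_ns      k1 k_minus1     K
#> LIG     LIG      159      100          1.61 9.3e+09  9.9e+10 0.094
```

159 complete in-and-out cycles were observed in the 100 ns-equivalent
run; the toy ligands enter faster and leave much faster than gases in a
real protein matrix (k1 ≈ 9.3×10⁹ M⁻¹s⁻¹, k₋₁ ≈ 9.9×10¹⁰ s⁻¹, K ≈ 0.094
M⁻¹) because the hard shell has no attractive pockets. Closing the toy's
three channels (`channel_aperture_deg = 0`) yields exactly zero in
events — the blocked-tunnel control. `bundle$pocket_table` scores the
distal site and every discovered pocket (occupancy %, average/maximum
simultaneous ligands, mean residence, transfer events, mean Fe–ligand
distance for the distal site), and `bundle$rmsf` holds the per-residue
profile with >0.15 nm flagging.

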