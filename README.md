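# bindcalor

Absolute ligand–protein binding enthalpies from molecular-dynamics
potential-energy series, with blocking-analysis uncertainties and
binding-site loop-state conditioning.

## The problem

Binding free energy ΔG is routinely computed for protein–ligand systems,
but its components ΔH and TΔS are much harder: the potential energy of a
solvated protein system fluctuates by hundreds of kcal/mol, so estimating a
mean to sub-kcal/mol precision needs massive sampling *and* honest error
bars for strongly autocorrelated series. The *direct method* estimates the
binding enthalpy as a difference of mean potential energies over four
separate simulations (two for the bound state, two for the unbound state):

    ΔH = ⟨E⟩_complex + ⟨E⟩_solvent − ⟨E⟩_receptor − ⟨E⟩_ligand

with the atom counts on the two sides balanced exactly (excess water is
deleted at setup time) and the pressure–volume term neglected. A further
complication in bromodomain systems such as BRD4-1 is that the ZA loop
flanking the acetyl-lysine pocket occupies two conformational states — the
crystal-like **ZA1** and an outward alternative **ZA2** — whose potential
energies differ by several kcal/mol in some complexes; conditioning the
estimate on loop state can turn an outlier prediction into an accurate one,
while ΔG alone hides the substates through entropy–enthalpy compensation.

`bindcalor` packages this analysis layer for anyone running such
calculations:

* **I/O** — GROMACS-style XVG energy traces (kJ/mol → kcal/mol), ITC
  benchmark CSV tables (Unicode minus accepted), multi-model PDB
  trajectories, YAML run configuration.
* **Re-blocking** — Flyvbjerg–Petersen blocking curves with the
  conservative *maximum-SEM* selection, per replica or on concatenated
  replicas.
* **Direct enthalpy** — leg combination with quadrature error propagation
  and a hard atom-balance gate.
* **Loop dynamics** — Kabsch superposition, region RMSD after a global
  fit, per-residue RMSF, backbone dihedrals (IUPAC sign), atom-pair
  distances; per-frame ZA1/ZA2 assignment from the two hinge dihedrals
  (ψ of the Asp88 hinge, φ of the Asp96 hinge; defaults ψ>5° & φ<−105° ⇒
  ZA1, ψ≤5° & φ≥−105° ⇒ ZA2, disagreement ⇒ UNASSIGNED), with an
  RMSD-based classifier as a cross-check, dwell-time smoothing, occupancy
  and transition statistics.
* **State conditioning** — segment-wise blocking of single-state runs
  (blocking never crosses a state boundary), per-state and combined
  enthalpies, ΔG/ΔH/TΔS bookkeeping with a consistency flag.
* **Benchmark scoring** — RMSE, R² (squared Pearson), Kendall τ-b by
  direct pair counting, and outlier flagging at a strict 2 kcal/mol limit.
* **Synthetic data** — AR(1) energy traces and a hidden two-state Markov
  loop process with dihedral emissions, giving known ground truth for every
  estimator above.

## Worked example

Twenty synthetic 5000-frame AR(1) replicas per leg, leg means chosen so the
true binding enthalpy is −7 kcal/mol:

```r
library(bindcalor)
mus <- c(complex = -9520, solvent = -480, receptor = -9208, ligand = -785)
legs <- lapply(seq_along(mus), function(i) {
  cfg <- leg_config(mus[[i]], sigma = 2, rho = 0.9, n_frames = 5000,
                    n_replicas = 20, leg = names(mus)[i],
                    system_id = "TOY", seed = 42 + i * 1000)
  estimate_leg(generate_ar1_leg(cfg), min_blocks = 8)
})
do.call(combine_legs, c(legs, list(system_id = "TOY")))
#> <enthalpy_estimate> TOY [all]: dH = -7.03 +/- 0.06 kcal/mol
legs[[1]]
#> <leg_estimate> complex: -9519.9647 +/- 0.0311 kcal/mol (20 replicas, 100000 frames)
#>   rule: per_replica; max(quadrature 0.03084, replica-scatter 0.03114)
```

The estimate recovers the truth well inside 2 SEM; the provenance line
shows which of the two per-replica error terms (within-replica blocking
quadrature vs between-replica scatter) set the reported SEM.

Thermodynamic bookkeeping on the shipped ITC benchmark table finds the one
row whose printed TΔS contradicts ΔG = ΔH − TΔS (flagged, never corrected):

```r
tab <- read_benchmark_table(bindcalor_extdata("table1_itc.csv"))
chk <- infer_entropy_and_check(tab)
chk[!chk$consistent, ]
#>   system_id    dH dG TdS_stored TdS_computed consistent
#> 8      5DW2 -10.1 -8        2.1         -2.1      FALSE
```

## Command line

The CLI entry point is `inst/exec/bindcalor` (or `bindcalor_cli()` from R):

```sh
bindcalor estimate  --leg complex c*.xvg --leg solvent s*.xvg \
                    --leg receptor r*.xvg --leg ligand l*.xvg \
                    --atoms atoms.csv --min-blocks 8 --mode per_replica
bindcalor states    --psi psi.csv --phi phi.csv --dt 100 --min-dwell 5
bindcalor condition --condition ZA2 --trace 'traces/*.csv' --leg ...
bindcalor benchmark --pred estimates.csv --exp table1.csv
bindcalor synth     --mu -100 --sigma 2 --rho 0.9 --frames 5000 --replicas 20
```

## Vignette

`vignettes/binding-enthalpy-workflow.Rmd` documents the model and its
assumptions, all tunable parameters with defaults and units, what the
synthetic generator does and does not emulate, and the numerical choices
(tie-breaks, short-segment handling, smoothing).
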