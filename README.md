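# aggkin — aggregation kinetics of coarse-grained amyloid assemblies

`aggkin` analyses the onset of amyloid aggregation in coarse-grained
multi-peptide simulations. It is written for structural-bioinformatics /
molecular-modelling practitioners who have (or want to emulate)
trajectories of small amyloidogenic peptides — the reference system is 20
chains of GNNQQNY, the Sup35 prion fragment, in a 200 Å cubic box
(4.15 mM) — and who want quantitative answers to: *when does a cluster
count as a β-sheet aggregate, what kinetic events drive assembly, and how
large is the critical nucleus?*

## What it computes

* **β-sheet clusters.** Per frame, peptides are nodes of a
  strand-attachment graph: an edge requires ≥ 2 hydrogen bonds passing
  the Kabsch–Sander (DSSP) energy criterion
  `E = 27.888·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) < −0.5 kcal/mol`,
  and both peptides must have ≥ 3 residues in the Ramachandran β region
  (φ ∈ [−180,0] ∪ [150,180], ψ ∈ [−180,−150] ∪ [0,180]). Clusters are
  connected components of size ≥ 2; strand orientation (parallel vs
  antiparallel) is the sign of the dot product of end-to-end CA vectors.
* **Kinetic events and rates.** Frame-to-frame lineage tracking
  classifies monomer addition/loss, oligomer fusion/fragmentation, and
  direct monomers ↔ oligomer events; per-size creation/destruction rates
  satisfy Σₙ n·(net creation) = 0 in every time bin, and per-bin event
  totals separate single-monomer from oligomer-involving events.
* **Thermodynamics.** Occupancy P(n) over aggregate sizes gives
  F(n) = −ln P(n) (k_BT units); the critical nucleus n\* is the interior
  argmax of F, with ties within 0.5 k_BT reported as a range. A
  classical-nucleation-theory model ΔG(n)/k_BT = −n·ln S + θ·n^(2/3) is
  fit (with a mandatory small-system warning for ≤ 20 monomers), and its
  closed-form barrier n\* = (2θ/3 ln S)³ is exposed.
* **Synthetic data.** Self-verifying ideal β-sheet and random-coil
  fixtures, scripted trajectories with ground-truth events, and an exact
  Gillespie aggregation simulator whose detailed-balance mode samples a
  prescribed free-energy profile exactly — the ground truth for
  parameter-recovery tests.

## Worked example

```r
library(aggkin)

concentration(20, 200)        # molarity of 20 peptides in a 200 A box
#> [1] 4.151348                # mM
steps_to_time(5000, 1.5)      # 5000 integration steps at 1.5 fs
#> 7.5 ps

# a self-verified ideal parallel sheet of 5 strands
sheet <- build_ideal_sheet(5, "parallel")
sheet$graph$edges
#>   a b n_hbonds orientation
#> 1 1 2        7    parallel
#> 2 2 3        6    parallel
#> 3 3 4        7    parallel
#> 4 4 5        6    parallel
parallel_fraction(sheet$partition)
#> [1] 1

# recover a nucleation barrier from the detailed-balance simulator:
# the preset profile peaks at n = 5 (2.5 kBT) and is downhill to n = 20
trace <- gillespie_aggregation(kmc_config(seed = 1, max_events = 2e5))
prof  <- free_energy_profile(kmc_occupancy(trace))
critical_nucleus(prof)
#> $n_star
#> [1] 5
#> $range
#> [1] 5 6        # F(6) ties within the 0.5 kBT tolerance
#> $f_max
#> [1] 4.748805
#> $no_nucleus
#> [1] FALSE

# a scripted growth trajectory, analysed end to end
st <- script_trajectory(script_growth(10, final_size = 5))
ev <- classify_events(cluster_timeseries(st$trajectory)$partitions)
table(ev$type)
#> monomer_addition
#>                4
```

The numbers mean: the box/count pair reproduces the 4.15 mM reference
concentration; the sheet fixture passes its own DSSP/β-window
verification with every adjacent strand pair attached by ≥ 2 H-bonds in
the requested orientation; the −ln P estimator applied to the simulator's
occupancy puts the barrier maximum at n\* = 5 (the plateau report `[5, 6]`
reflects the preset profile's own 0.3 k_BT gap between sizes 5 and 6,
inside the 0.5 k_BT tie tolerance); and a coil → dimer → … → pentamer
script yields exactly the four monomer-addition events it encodes.

## Command line

`exec/aggkin` provides `synth`, `analyze`, `kinetics`, `thermo` and
`report` subcommands around a JSON run configuration (`run_config()` /
`write_config()`), writing TSV/JSON-lines outputs plus a manifest. Exit
codes: 0 ok, 2 bad input, 3 bad configuration.

## Scope notes

Quantities that require the original microsecond-scale coarse-grained MD
ensembles (lag times, reversibility percentages, parallel-dominance
fractions, absolute energies) are *not* reproduced here; the package
ingests such data when available and validates all of its machinery
against synthetic ground truth. The per-frame secondary-structure series
is the package's own β-residue fraction, not a STRIDE assignment. See
`vignettes/aggkin-methods.Rmd` for the model, defaults, and limitations.
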