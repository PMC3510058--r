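---
title: "Methods: beta-sheet aggregation kinetics at coarse-grained resolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: beta-sheet aggregation kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggkin)
```

# The problem

Amyloid-forming peptides such as GNNQQNY (the amyloidogenic heptapeptide
fragment of the yeast prion protein Sup35) self-assemble from free
monomers into ordered beta-sheet aggregates by a nucleated-growth
process: a lag phase of reversible stochastic association, the formation
of a metastable critical nucleus, rapid growth, and a slow stabilization
phase. `aggkin` implements the full analysis chain needed to quantify
this process in coarse-grained multi-chain simulation data — and, because
such data is expensive to produce, a synthetic-data module that generates
every input the pipeline needs with known ground truth.

The reference system is 20 GNNQQNY chains in a 200 Å cubic periodic box,
i.e. a 4.15 mM peptide concentration, each residue represented by the
five heavy backbone atoms (N, H, CA, C, O) plus one side-chain bead (SC).

# Cluster detection model

Two peptides are *attached* when they share at least `min_hbonds = 2`
backbone hydrogen bonds satisfying the Kabsch–Sander (DSSP) electrostatic
criterion,

$$E = q_1 q_2 f \left(\frac{1}{r_{ON}} + \frac{1}{r_{CH}} -
\frac{1}{r_{OH}} - \frac{1}{r_{CN}}\right), \qquad
q_1 q_2 f = 27.888\ \mathrm{kcal\,mol^{-1}\,\mathring{A}},$$

with a bond accepted when $E < -0.5$ kcal/mol. A peptide participates in
clusters only if it is itself in a *beta state*: at least
`min_beta_residues = 3` of its residues have backbone dihedrals inside
the beta windows $\varphi \in [-180,0] \cup [150,180]$,
$\psi \in [-180,-150] \cup [0,180]$ (closed intervals, degrees).
Clusters are the connected components of size ≥ 2 of the resulting
strand-attachment graph; everything else is a free monomer.

Choices worth calling out:

* **Beta-window assignment.** Conventions differ in how the two interval
  unions are assigned to $\varphi$ and $\psi$; under the swapped
  assignment the canonical beta-sheet point
  $(\varphi,\psi) = (-120°, +130°)$ would *fail*. The default is the
  assignment under which it passes; both windows are fully configurable
  and the values actually used are echoed at INFO level by every command.
* **Attachment threshold semantics.** "Two hydrogen bonds" is applied
  *per pair of strands* (a peptide needs ≥ 2 bonds to a single partner),
  not summed over a cluster. Configurable via `min_hbonds`.
* **Side-chain contact cutoff.** No cutoff is standardized for SC-bead
  contact maps; the default is 6.5 Å between bead centres. Both axes of
  the structure maps depend on it, so it is logged prominently.
* **Orientation.** A strand pair's orientation is the sign of the dot
  product of the two end-to-end CA vectors; exactly perpendicular pairs
  are counted antiparallel with a warning (a configurable dead zone can
  exclude them instead). The antiparallel fraction is 1 minus the
  parallel fraction by construction.
* **Beta fraction vs. DSSP/STRIDE.** The per-frame "secondary structure"
  series is this package's own beta-residue fraction, *not* a STRIDE
  assignment; absolute percentages are not comparable to STRIDE-based
  plots and the documentation flags this.

# Kinetic event bookkeeping

Consecutive frame partitions are matched by shared-peptide overlap; each
changed overlap group is classified by its aggregate-size multiset
transformation:

| transformation | type |
|---|---|
| $(n)+(1)\to(n+1)$ | monomer addition |
| $(n)\to(n-1)+(1)$ | monomer loss |
| $(a)+(b)\to(a+b)$, $a,b\ge 2$ | oligomer fusion |
| $(a+b)\to(a)+(b)$, $a,b\ge 2$ | fragmentation |
| $k\ge 3$ monomers $\to (k)$ | monomers → oligomer |
| $(k)\to k$ monomers, $k\ge 3$ | oligomer → monomers |

Dimer formation $(1)+(1)\to(2)$ is a monomer event: only oligomers larger
than dimers count as direct monomer–oligomer interconversion. Compound
changes within one save interval are decomposed greedily — monomer events
first, then fusion/fragmentation — deterministically and never dropped;
the `compound` flag marks them. Pure peptide *exchanges* that leave the
size multiset unchanged are invisible to size-based bookkeeping (and to
size-histogram replay), a deliberate limitation.

From the event stream the package accumulates, per aggregate size $n$
and time bin, four separate rate groups (creation/destruction via the
monomer route and via multi-monomer routes) whose combination is the net
rate of creation of size-$n$ species; $\sum_n n \times$ (net creation)
vanishes in every bin (mass conservation, asserted in tests). Event
totals per bin separate single-monomer events from oligomer-involving
events, association and dissociation reported independently, with a
default (configurable) bin of 5 ps. Because no single convention exists
for normalizing rates — by concentration or by time alone — both the raw
counts and counts/bin-width are emitted.

Nucleation/reversibility episodes are defined operationally (no standard
definition exists): nucleation is the first time the largest cluster
reaches `n_star` (default 5, the critical-nucleus scale) sustained for
`hold_time` (default 0.5 ns); a reversal is a subsequent sustained drop
below `dissolve_threshold` (default 2, i.e. full dissolution). Both the
per-episode and per-run reversal statistics are reported since either
reading of a "fraction of reversible events" is defensible.

Energy traces (ingested from CSV; the package computes no force-field
energies) are aligned at their first downward crossing of −80 kcal/mol —
roughly the midpoint of the aggregation energy drop — and averaged on a
±5 ns window. Note the crossing is located on the sampling grid, so
traces whose true crossing falls between samples align with a phase error
of up to one save interval.

# Free energy and the critical nucleus

The occupancy $P(n)$ of aggregate sizes is pooled over frames and runs;
$F(n) = -\ln P(n)$ in units of $k_BT$, shifted so the minimum is zero,
with gaps (unsampled sizes) left undefined rather than imputed. The
critical nucleus $n^\ast$ is the argmax of $F$ over interior sizes; ties
within 0.5 $k_BT$ are reported as a range ("between 4 and 5"-style).
Two weightings are computed — per aggregate (default; each aggregate
counts once at its size) and per peptide — because the convention is not
standardized; monomers count as size-1 aggregates in both.

Over the beta-residue-count coordinate the reported critical value is the
*first* interior maximum with at least the tie tolerance of prominence on
both sides (so counting noise cannot fake a barrier); the rise of $F$ at
high counts is annotated as a finite-size boundary effect (no monomers
left to recruit), never corrected.

The classical nucleation theory model is
$$\Delta G(n)/k_BT = -n \ln S + \theta\, n^{2/3},$$
with supersaturation $S$ and a surface coefficient $\theta$ (absorbing
the interfacial energy and the geometric prefactor, which is therefore
not reported separately); for $S>1$ the barrier top is at
$n^\ast = (2\theta / 3\ln S)^3$, exposed in closed form and checked
against numeric maximization. `cnt_fit` performs the least-squares fit
with an additive constant absorbing the profile shift, and *always*
attaches a warning for systems of ≤ 20 monomers: with so few peptides and
a low critical nucleus the continuous CNT expression cannot be fit
reliably, and finite size biases the apparent nucleus upward (the
finite-size correction itself is cited, not reproduced).

# The synthetic stated world

The generators emulate the reference system, not any particular
trajectory:

* **Ideal sheets** use near-extended torsions (φ = −160°, ψ = +160°) —
  inside the default beta windows and nearly planar, so strands stacked
  at 4.8 Å with a deterministic registry scan robustly satisfy the DSSP
  criterion. Every fixture is verified through the full analysis stack at
  build time (beta rule, ≥ 2 H-bonds per adjacent pair, requested
  orientation, connectivity); an unrealizable fixture is a hard error.
* **Random-coil boxes** draw all torsions strictly outside the beta
  windows, so the strand graph is empty by construction (verified). The
  minimum centroid separation must be below half the box edge, the
  minimum-image guarantee radius.
* **Scripted trajectories** realize a prescribed partition sequence
  geometrically on a lattice of well-separated sites and return the
  script as ground truth for the clustering and kinetics stages.
* **The Gillespie simulator** has two modes. The *multiset* mode is an
  exact stochastic simulation over the full aggregate-size multiset with
  mass-action propensities for all six event types. The
  *detailed-balance* mode tracks a single aggregate performing a
  birth–death walk on sizes 1..N with detachment rates derived from the
  attachment rates and a target free-energy profile, so its stationary
  distribution is exactly the target Boltzmann distribution — the ground
  truth for parameter-recovery tests. The default `barrier_profile()` is a
  20-peptide profile rising linearly to a 2.5 $k_BT$ barrier at $n = 5$
  and descending to −2 $k_BT$ at $n = 20$; under the default 0.5 $k_BT$
  tie tolerance its own barrier region spans sizes 5–6 (the gap between
  $F(5)$ and $F(6)$ is 0.3 $k_BT$), while the argmax is 5. These
  constants are the stated world for the recovery tests: 10⁶ events for
  the pointwise check, 2×10⁵ events per replicate for the argmax check
  (chosen a priori so barrier-top visits number in the hundreds).

What a green test does *not* establish: the generators are geometric and
Markovian, with no force field, no thermostat, and no spatial diffusion;
they validate the bookkeeping, estimators and criteria — not the physics
of any particular simulation engine, and not headline numbers (lag times,
reversibility percentages, parallel-dominance fractions) that require the
original microsecond-scale ensembles.

# Numerical choices

* Torsions follow the IUPAC sign convention on $(-180°, 180°]$;
  degenerate (collinear) geometry yields a flagged `NA`, never a silent
  zero. Window membership uses closed intervals.
* All inter-atomic distances use the minimum-image convention on the
  cubic box; the box (200 Å) is large relative to aggregates so this is
  rarely exercised but kept consistent.
* Statistical sampling checks against the detailed-balance simulator use
  the estimator's actual standard error from batch means: successive
  Gillespie states are autocorrelated, so the naive multinomial σ would
  understate the error (they coincide in the iid limit).
* Cluster lineage ties (equal overlap) break to the cluster containing
  the lower minimum peptide index — deterministic across platforms.
* The logistic fit uses `nls` with data-driven starting values; fits with
  $R^2$ below 0.9 (configurable) are flagged non-sigmoidal and the
  parameters withheld. The lag time is $t_0 - 2\tau$ (tangent
  construction).
* Event times within a save interval are assigned to the interval's end;
  a rate bin narrower than the save interval is an error (the workbench
  raises the bin to the save interval and logs it).

# Limitations

* Size-multiset bookkeeping cannot see pure peptide exchanges between
  clusters of equal size.
* The PDB/DCD readers support the formats this package writes plus plain
  conforming files; they are not general-purpose structure parsers.
* The beta-fraction series is not a STRIDE percentage.
* `cnt_fit` on 20-monomer systems is reported but explicitly untrusted.
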