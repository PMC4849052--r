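# porineva

Structure-and-sequence analysis of bacterial outer-membrane porins and
substrate-specific diffusion channels.

These proteins share a transmembrane β-barrel: 8–26 antiparallel β-strands
closed into a cylinder, short periplasmic turns on one side, longer
extracellular loops on the other, and — in specific channels — a
constriction loop (usually L3) folded inside the barrel that narrows the
pore. porineva is for structural bioinformaticians who want to reproduce or
extend this family's canonical analysis on their own structures and
alignments:

* **Structure preparation** — PDB/mmCIF reading, cleaning (waters, hetero
  residues, altlocs, MSE→Met), chain/model selection, renumbering, van der
  Waals radius assignment.
* **Topology** — Kabsch–Sander style hydrogen-bond assignment, closed-barrel
  detection with strand count and axis, strand / periplasmic-turn /
  extracellular-loop partitioning, constriction- and long-loop detection,
  inward/outward residue orientation, composition statistics.
* **Core superposition** — sequence-seeded Kabsch fits with iterative
  outlier trimming: RMSD, % residues superposed, structural and global
  sequence identities, per-subclass aggregation.
* **Pore profiling** — deterministic minimum-pore-radius profiles along the
  barrel axis for whole structures, barrel cores and poly-alanine cores.
* **MSA filtering and EVA** — redundancy filtering (pairs above 90%
  identity), divergence filtering against the reference, and per-column
  entropy–variability analysis: the Shannon entropy
  `E_i = −Σ_a p_a ln p_a` over non-gap frequencies, the variability `V_i`
  (number of residue types above 0.5% frequency), and the five-box EV
  classification — Box 11 (main site, red), 12 (support, orange),
  22 (communication, yellow), 23 (modulation, green), 33 (no known
  function, blue) — mapped onto structural regions.
* **Synthetic data** — idealized barrels on the sheared lattice
  `R = sqrt((S·a)² + (n·b)²)/(2π)` and alignments with per-column
  conservation profiles, both with exact ground truth, so every stage is
  testable without downloads.
* **Pipeline** — `run_pipeline()` orchestrates the whole workflow over a
  subclass configuration with a reproducible manifest.

## Worked example

A study fixture plants strong conservation on the inward (pore-facing)
strand residues of an 8-stranded barrel and draws a 200-sequence alignment:

```r
library(porineva)
fx  <- generate_study_fixture("inward", n_strands = 8, strand_length = 8,
                              n_sequences = 200, seed = 1)
ann <- annotate_topology(fx$model)
ann
#> <topology_annotation> synthetic_barrel: 8 strands, 93 residues
#>    EXTRACELLULAR_LOOP=20  PERIPLASMIC_TURN=9  STRAND=64

ev  <- compute_eva(fx$msa)
map <- map_columns(fx$msa, fx$reference_id, fx$model)
ori <- orient_residues(fx$model, ann)
tab <- region_box_distribution(ev, map, ann, ori, classify_long_loops(ann), NA)
tab
#>               region    11  12  22  23    33
#>                  all  34.4 0.0 0.0 0.0  65.6
#>               strand  50.0 0.0 0.0 0.0  50.0
#>          periplasmic   0.0 0.0 0.0 0.0 100.0
#>        extracellular   0.0 0.0 0.0 0.0 100.0
#>   extracellular_long   0.0 0.0 0.0 0.0 100.0
#>  extracellular_short   0.0 0.0 0.0 0.0   0.0
#>         constriction   0.0 0.0 0.0 0.0   0.0
#>               inward 100.0 0.0 0.0 0.0   0.0
#>              outward   0.0 0.0 0.0 0.0 100.0
```

Every inward strand residue lands in Box 11 (fully conserved) and every
outward one in Box 33 (maximally variable) — exactly the planted pattern.
`interface_conservation_summary(tab)` reduces this to conserved fractions
(inward 1.0, outward 0.0, difference 1.0) and would flag an outward
conserved patch — the trimer-interface signature — above a configurable
floor. The pore profile of the same barrel:

```r
pore_profile(fx$model, attr(ann, "axis"), attr(ann, "origin"), attr(ann, "slab"))
#> <pore_profile> mode whole: min radius 5.23 A at z = -0.56 A (65 slices)
```

which matches the analytic value for an unobstructed generated barrel
(lattice radius minus C-beta reach minus carbon van der Waals radius).

For real data, point `run_pipeline()` at a configuration listing your
subclasses, member structure files, templates and aligned FASTA files; it
emits per-structure topology tables, composition and superposition/pore
tables, per-subclass EVA statistics and region distributions, plus a
manifest with checksums.

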