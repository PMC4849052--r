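---
title: "Methods: entropy-variability analysis of beta-barrel porins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: entropy-variability analysis of beta-barrel porins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porineva)
```

## The analysis

Bacterial outer-membrane porins and substrate-specific diffusion channels
share a transmembrane beta-barrel architecture: 8 to 26 antiparallel
beta-strands closed into a cylinder, connected by short periplasmic turns on
one side and longer extracellular loops on the other. In substrate-specific
channels one extracellular loop (usually L3) folds back inside the barrel,
constricting the pore and setting specificity. porineva implements the full
joint structure-and-sequence analysis of this family: structure
preparation, topology partitioning, core superposition, pore-radius
profiling, alignment filtering, per-column entropy-variability statistics
with a five-box functional classification, and the mapping of conservation
onto structural regions (loops, constriction loop, inward and outward
strand faces). The outward-face conservation pattern is the sequence
signature used to argue for oligomeric (trimeric) interfaces.

## Structure preparation

`read_structure()` keeps one model and one chain, removes waters,
hydrogens and hetero residues, maps selenomethionine to methionine, and
resolves alternate locations to the highest occupancy (ties broken by
altloc identifier order). Residues are renumbered 1..N; residues missing
from the experimental model remain a counted gap and all downstream
statistics are computed over observed residues only. Van der Waals radii
are assigned per element from an editable Bondi-style table
(`default_vdw_radii()`); the pore profile depends directly on this table,
which is why it is explicit and overridable. For multimeric crystal forms,
`first_monomer()` analyses chain "A" when present, else the first protein
chain, with a warning.

## Secondary structure and barrel topology

`assign_secondary_structure()` is a Kabsch-Sander style assignment: the
amide hydrogen is rebuilt from the preceding carbonyl
(`H = N + unit(C_prev - O_prev)`), the hydrogen-bond energy is the classic
electrostatic model
`E = 0.084 * 332 * (1/d_ON + 1/d_CH - 1/d_OH - 1/d_CN)` kcal/mol, and a
bond exists below a cutoff (default -0.5 kcal/mol). Strand (`E`) labels
come from ladders of two or more consecutive parallel or antiparallel
bridges. Two deliberate choices differ from the textbook assignment:

* bridges are admitted at chain distance >= 2 rather than >= 3. In barrels
  with very short (or absent) connectors, the first ladder pair behind a
  junction sits two residues away in the chain; the stricter rule frays
  every junction by one or two residues.
* a conservative one-pass strand extension absorbs a residue that is
  flanked by ladder residues on both chain sides (or the single side, at a
  chain terminus) and shares a backbone hydrogen bond with a ladder
  residue. This covers beta-bulge interiors and the chain-initial residue,
  whose amide hydrogen cannot be rebuilt. Because the rule requires both
  neighbours to already be strand, it cannot creep into turns.

Residues with incomplete backbones are labelled `-` with a warning, never
assigned.

`detect_barrel()` takes maximal `E` runs (bridging interruptions up to one
residue), splits runs at axial direction reversals (strands alternate
up/down; direct strand-to-strand junctions would otherwise fuse), and
requires a closed cycle of strand adjacency, where two strands are adjacent
when they share at least `min_bridges` (default 2) bridges or backbone
hydrogen bonds. The barrel axis is the principal direction of strand
C-alpha coordinates best aligned with the mean (sign-aligned) strand
direction, and the membrane slab is the 5th-95th percentile axial span of
strand C-alpha atoms.

`classify_regions()` assigns every non-strand residue to the connector
joining consecutive strands; a connector's side is the sign of its mean
axial coordinate against the slab midplane. The extracellular side is the
side whose connectors are on average longer - porins have short periplasmic
turns and long extracellular loops - and can be overridden per structure.
Terminal tails are counted with the side they exit. The constriction loop
is the extracellular loop with more than half (configurable) of its
C-alpha atoms radially inside the mean strand radius minus a 1.0 A margin;
these two constants are our operationalisation of "located inside the
barrel". A loop is "long" when it exceeds 15% of the structure's total
extracellular-loop residue count, with a per-subclass override for the
petite-porin convention of naming three of four loops long. A strand
residue faces inward when its C-alpha to C-beta vector has a negative
radial component; glycine (or any residue with no C-beta) uses the
standard idealized virtual C-beta from backbone geometry.

Composition statistics weight each structure equally by default
(`weight = "residue"` pools residues instead); the group tables never state
how they were weighted, so the choice is exposed.

## Core superposition

`superpose_cores()` seeds the residue correspondence with a global
Needleman-Wunsch alignment (BLOSUM62, gap open 10, extend 0.5) of the core
sequences, fits matched C-alpha pairs by least squares (Kabsch, SVD), and
iteratively trims pairs deviating by more than 3.5 A until the retained
set is stable. We do not re-implement a structural aligner: within a
subclass the sequence identities are high enough that sequence seeding
plus spatial trimming recovers the correspondence, and the quantities that
matter (RMSD, fraction superposed) are defined on the retained set.
Numbers from a dedicated structural aligner will differ in detail. The
percentage superposed uses the shorter core as denominator. Both a
structural-match identity (over retained pairs) and the global-alignment
identity are reported, as the two printed identity columns of the study
design differ only by the aligner that produced them. Subclass aggregation
averages all within-subclass pairs, then averages subclasses with equal
weight; singleton subclasses yield NA rows.

## Pore-radius profiling

At each axial slice z (default step 0.25 A across the membrane slab) the
pore radius is the largest sphere clearance achievable at any centre in a
lateral search disc (default 5 A) around the axis:
`max_c min_atoms(|c - x| - vdw)`. The maximisation is a deterministic
coarse grid (0.5 A) with local 5x5 grid refinement down to 0.01 A from the
three best coarse candidates. A deterministic search replaces the
stochastic simulated annealing of the classic pore software so that runs
are exactly reproducible; agreement with annealing-based values is
approximate by construction. Note that an off-axis search changes the
answer where a single obstruction sits near the axis: the optimal centre
slides away from the obstruction, balancing it against the far wall.
Collapse `disc_radius` toward zero for an axis-constrained profile.
Negative clearances are floored at zero and flagged blocked. Radii are
radii, not diameters. `polyalanine()` reduces every residue to N, CA, C,
O, CB (glycine unchanged) for side-chain-independent profiles; removing
atoms can only widen the pore, so core and poly-alanine minima bound the
whole-structure minima from above.

## Alignment filtering and EVA

Identity between aligned sequences counts matches over columns where both
hold a residue; half- and doubly-gapped columns are excluded from the
denominator. `filter_redundant()` iteratively removes, from the current
highest-identity pair above the ceiling (default 0.90, strict), the member
with the greater mean identity to everything else - the more redundant
sequence - with ties broken by later input order. This keeps maximal
diversity, is deterministic, idempotent, and leaves no surviving pair
above the ceiling. `filter_divergent()` removes sequences below a floor
identity to the structure-derived reference (default 0.20 of the
published 20-30% range; configurable, and appliable per run rather than
globally).

Per column i, the entropy is `E_i = -sum_a p_a ln p_a` over non-gap
frequencies (we report the conventional non-negative sign; the printed
form `sum P log P` is its negative), in nats by default with the base
configurable. The variability `V_i` counts residue types with frequency
strictly greater than 0.5%. Columns with more than 50% gaps are invalid
and excluded from distributions. The EV plane is divided into five boxes
(11 main site, 12 support, 22 communication, 23 modulation, 33 no known
function; coloured red/orange/yellow/green/blue). Published EV analyses
never state numeric sector boundaries, so the defaults are terciles of
both axes (`v_lo = 4`, `v_hi = 12`, `e_lo = ln(20)/3`,
`e_hi = 2 ln(20)/3`), which reproduce the two-digit naming structure;
every threshold is configurable and recorded in outputs. "Conserved"
summaries pool boxes 11+12+22.

`region_box_distribution()` joins column statistics to structure residues
through `map_columns()` (columns where the reference is gapped are
unmapped) and tabulates box percentages for the whole structure, strands,
turns, loops, the long/short loop split, the constriction loop, and the
inward/outward strand faces; `interface_conservation_summary()` reduces
this to conserved fractions and flags outward-facing conservation above a
floor (default 0.1), the oligomer-interface signature.

## The synthetic-data generator

`generate_barrel()` places C-alpha atoms on the standard sheared barrel
lattice: with n strands, shear number S, rise a = 3.3 A and inter-strand
spacing b = 4.4 A (standard beta-sheet constants, configurable), the
radius is `R = sqrt((S a)^2 + (n b)^2) / (2 pi)` and the strand tilt is
`atan(S a / (n b))`. Backbone N/C/O are placed so the Kabsch-Sander ladder
forms between adjacent strands, including the closure seam. Several
idealizations make the ground truth exact rather than approximate:

* per-strand lattice row offsets distribute the shear at slope S/n and are
  parity-adjusted so each strand's bottom row hydrogen-bonds to the
  preceding strand and its top row to the following one - every strand
  residue then has a ladder partner (for even strand lengths; odd lengths
  fray one terminal residue per strand). The shear must be even so the
  carbonyl alternation closes consistently at the seam.
* loop interior carbonyls point at the sheet plane, so rebuilt loop amide
  hydrogens point away from it and loops cannot donate into the ladder;
  the final loop residue's carbonyl steers the next strand residue's
  rebuilt amide H and carries a near-degenerate dipole length so it cannot
  itself act as an acceptor.

Loops are smooth Bezier arcs bulging out of the slab; a configured
constriction loop is routed inside the barrel at a given depth fraction.
C-beta atoms are placed radially with the beta-pleat alternation, giving
exact inward/outward ground truth. `generate_msa()` draws sequences
column-independently from per-column profiles (dominant residue,
alternatives, gap rate) with analytic entropy/variability/box labels
attached; `generate_study_fixture()` combines both, planting strong
conservation on configured structural positions (inward faces, long
loops, or the constriction loop).

What the generator does not emulate: real side chains beyond C-beta,
experimental noise and missing density, beta-bulges and tilted
non-ideal strands, and - most importantly - phylogenetic correlation
between alignment columns. EVA itself treats columns independently, so the
generator matches the method's own model; passing tests therefore
demonstrate algorithmic correctness under the stated model, not
performance on real structures and real alignments, where secondary
structure assignment and side selection are the fragile steps.

## Numerical choices and test design

Problem sizes throughout the suite were chosen at desk scale: barrels of
8-26 strands with 8-10 residue strands, alignments of 50-500 sequences,
and 150-column tiered profiles. Tolerances: superposition identities are
exact to 1e-9 on rigid copies; pore values are compared at the 0.05 A
grid tolerance; entropy matches a counting oracle to 1e-12. Parameter
recovery for the entropy estimator compares the Miller-Madow
bias-corrected column mean against the closed form within three standard
errors - the raw plug-in mean is biased low by (K-1)/(2n), which exceeds
the sampling noise for near-uniform columns, so the uncorrected
comparison would be ill-posed rather than informative. Pipeline outputs
print percentages to one decimal and are byte-identical across re-runs
with the same configuration; the run manifest records the package
version, seed, thresholds and table checksums, and deliberately no
timestamps.

## Known limitations

* Sequence-seeded superposition degrades when core identities fall toward
  the twilight zone; a structural aligner would be needed there.
* The Kabsch-Sander parameters (cutoff, bridge distance, extension rule)
  were tuned for idealized and well-resolved structures; NMR ensembles and
  low-resolution models will fray.
* The pore profiler reports the best sphere per slice; it does not trace a
  connected channel, so disconnected side pockets can in principle inflate
  a slice radius within the search disc.
* Box boundaries are a declared convention, not a fitted quantity;
  cross-study comparisons must state the scheme.
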