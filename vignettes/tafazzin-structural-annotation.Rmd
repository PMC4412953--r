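---
title: "Structure-based annotation of tafazzin missense variants: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based annotation of tafazzin missense variants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taz3d)
```

# The scientific problem

Tafazzin (TAZ) is a mitochondrial phospholipid transacylase; missense
mutations in the *TAZ* gene cause Barth syndrome, an X-linked disease with
cardiomyopathy and neutropenia. Because no experimental structure of
tafazzin exists, structural interpretation of its disease mutations rests on
homology models built on the distantly related glycerol-3-phosphate
acyltransferase (G3PAT) fold, at sequence identities far below the usual
modelling comfort zone. `taz3d` implements the analysis chain that supports
that interpretation:

1. solvent accessibility, burial and the connected *structural core*;
2. pairwise target-template alignment with gap penalties driven by template
   solvent accessibility;
3. geometric detection of the substrate-binding cleft, its openness
   ("mouths") and the exon decomposition of its lining;
4. membrane-association signals: net formal charge, exposed basic patches,
   a hydropathy transmembrane scan and a charge-hydropathy disorder
   heuristic;
5. phosphate-spacing geometry of cardiolipin-like dimeric phospholipids and
   its compatibility with basic residue pairs in the cleft;
6. classification of missense mutations into location classes with
   electrostatic/stability flags and proposed functional effects.

Every stage is testable offline through deterministic synthetic generators.

# Solvent accessibility and the structural core

Solvent-accessible surface area is computed with the Shrake-Rupley
point-sampling method: each heavy atom is inflated by the probe radius
(default 1.4 Å, water) and sampled with a deterministic Fibonacci lattice
(default 960 points); points falling inside any neighbouring inflated atom
are occluded. Van der Waals radii follow a standard element table (C 1.70,
N 1.55, O 1.52, S 1.80, P 1.80 Å); unknown elements fall back to 1.70 Å
with a warning.

**Numerical choice — rigid-motion invariance.** A fixed laboratory-frame
point lattice makes point-sampled areas change by a few tenths of Å² when
the molecule is rotated. `computeSasa()` therefore rotates coordinates into
a canonical principal-axis frame (axis signs fixed by third moments) before
sampling, which makes areas exactly invariant under rigid motion. For
highly symmetric inputs the canonical frame is arbitrary among symmetric
alternatives, but any choice then yields the same areas.

Relative accessibility divides residue SASA by a per-residue-type
theoretical maximum (Tien et al. values; `maxAsaTable()`). A residue is
**buried** when its relative accessibility is strictly below 0.1 — the
boundary value itself is *not* buried. The **structural core** is the set
of connected components (minimum heavy-atom contact distance <= 4.5 Å) of
the contact graph induced on buried residues; isolated buried residues are
discarded, because a core is defined by mutual contact. Both thresholds are
arguments, not constants.

# Accessibility-weighted alignment

Low-identity target-template alignment benefits from a structural prior:
insertions and deletions land on the exposed surface, not in the buried
core. `gapProfile()` encodes this as a per-template-position gap-open
penalty interpolated linearly between `gMax` (relative accessibility 0,
default 12) and `gMin` (>= 1, default 4), with a single extension penalty
(default 1) and BLOSUM62 scores. The original penalty function of the
accessibility-weighted alignment literature is not published in reusable
form; the linear form is this package's own choice and all four parameters
are exposed.

`alignPair()` implements the full Gotoh three-state recursion with the
position-specific open penalties, including direct insertion-deletion state
transitions, so its optimum provably equals exhaustive enumeration over all
global alignments (the test suite checks this exactly on random short pairs,
and checks the uniform-profile case against an independent affine aligner).
A deletion run starting at template position *j* pays `open(j)`; an
insertion run following template position *j* pays `open(j+1)` (last
position's penalty at the template end). Terminal gaps are penalized like
internal ones; traceback ties prefer match over insertion over deletion,
making output deterministic.

`alignmentStats()` reports percent identity over both-aligned columns only,
optionally restricted to a region (e.g. an acyltransferase domain);
`coreConservation()` counts template core positions aligned to hydrophobic
target residues, the classical sanity check that a low-identity alignment
still conserves the buried core.

# Cleft detection and exon tabulation

The published analysis used an external cleft server; `taz3d` replaces it
with an in-package grid method in the LIGSITE tradition so results are
reproducible offline. The structure is embedded in a regular grid (default
spacing 1.0 Å); voxels within vdW + probe of an atom are protein. Every
solvent voxel is scanned along 7 directions (3 axes, 4 body diagonals); a
voxel enclosed by protein on both sides in at least 4 of 7 directions is a
pocket voxel. Pocket voxels are clustered by 26-connectivity, clusters
below 30 voxels are dropped, and pockets are ranked by volume
(`n_voxels * spacing^3`).

**Mouths.** Openness is qualitative in the literature ("one open end",
"two open ends"); here it is defined operationally: bulk solvent is the
solvent component touching the bounding box, and the mouth count is the
number of 26-connected components of pocket voxels adjacent to bulk
solvent. A fully enclosed cavity has 0 mouths, a cup-shaped well 1, an
open tube 2 — the geometry that distinguishes the two-open-ended tafazzin
cleft from the single-ended G3PAT cleft.

**Lining and exons.** Cleft-forming residues are those with a heavy atom
within 4.0 Å of a pocket voxel. `tabulateByExon()` counts them per exon
with one-decimal percentage fractions; residues outside every exon range go
to an explicit `unassigned` row with a warning.

**Invariance caveat.** The 7-direction scan is closed under axis
permutations, so pocket volume is exactly invariant under 90-degree
grid-preserving rotations (asserted in the tests). Under arbitrary
rotations the digitization of elongated voids can shift by more than a few
voxels; users comparing pocket volumes should keep a consistent frame.

# Membrane association and disorder

Net formal charge sums K/R as +1 and D/E as -1; histidine contributes 0 to
sums but forms its own *charge class* for mutation flags (see below) — the
only scheme that reproduces both the published net-charge values and the
published electrostatic marks on His substitutions.

Exposed basic patches are single-linkage clusters of non-buried Lys/Arg
whose side-chain terminal nitrogens lie within 15 Å; clusters of >= 3 are
reported with centroids. Transmembrane segments are maximal runs of
19-residue Kyte-Doolittle window means >= 1.6 (gap <= 3 merged). Disorder
uses the charge-hydropathy plane: a 21-residue window is disordered when
its mean absolute net charge exceeds `2.785 * <H> - 1.151` (strictly), with
`<H>` the window hydropathy rescaled to 0-1. These are deliberately simple,
published heuristics standing in for multi-predictor consensus servers;
external annotations can always be supplied instead of the heuristics'
output, since every downstream function takes plain segment/location
arguments.

# Mutation classification

`classifyLocation()` assigns each mutated position one class with the
precedence **catalytic > cleft > buried > surface**; catalytic positions
default to the HX4D motif hit (His69/Asp74 in tafazzin numbering), cleft
membership comes from the pocket lining, burial from the accessibility
profile, and a surface residue more than 10 Å from any basic patch keeps a
`"distal"` qualifier.

`effectFlags()` derives two flags. *Electrostatic*: the charge class of
reference and alternate residues differ (negative D/E, positive K/R,
histidine, neutral). *Stability*: any of (a) substitution to Pro; (b)
substitution to Gly at a cleft/buried site; (c) substitution of Gly; (d) a
charge-class change at a buried site; (e) a side-chain volume change of at
least 20 ų (Zamyatnin volumes) at a cleft/buried site; (f) a
hydrophobic-to-polar change at a surface site. Each fired rule is reported
in a trace so every flag is auditable. `proposeEffect()` maps location to
the proposed functional effect (catalytic activity, substrate binding,
membrane association, destabilization). With the packaged 39-row mutation
table and its printed location labels, these rules reproduce the printed
flags and effect labels for all 39 rows; that reproduction is pinned by the
acceptance tests, which is what fixes the default thresholds.

# Ligand geometry

Cardiolipin is dimeric, with two phosphate groups. "Distance between the
phosphate groups" is ambiguous at the atom level; the package's convention
is the distance between the oxygen centroids of the two groups, with
minimum O-O and P-P distances available as alternatives. `matchBasicPairs()`
scores pairs of basic residues by minimal terminal-N distance and flags
them compatible within `reference mean +- tolerance` (default 3.0 Å around
the cardiolipin survey mean of 8.1 Å, wide enough to cover the 9.2-13.9 Å
amino-group separations seen in the modelled cleft).

# Synthetic data: what it emulates, and what it does not

The generators provide every geometry the tests need:

* `buildHelix()` — ideal backbones at fixed torsions (standard bond
  lengths/angles, omega 180), with optional pseudo terminal nitrogens for
  basic residues. It emulates local backbone geometry, not side-chain
  packing.
* `buildPocketConstruct()` — pseudo-atom shells with a known void: a closed
  spherical cavity (0 mouths), a cylindrical well (1) and an open tube (2),
  each atom its own residue so lining recovery is scorable against the
  designed wall. Near an opening the protein-solvent-protein criterion
  stops short of the rim by up to about one pocket radius, which is why
  lining recovery is scored by Jaccard overlap (>= 0.8) rather than
  equality.
* `makeClLigands()` — two-phosphate ligands whose centroid spacing is drawn
  from `Normal(8.1, 0.4)` Å, the survey statistics for cardiolipin in
  deposited structures; n = 78 mirrors that survey's size where the
  acceptance script reports recovered statistics.
* `tazSyntheticSequence()` — a 292-residue construct carrying the
  documented tafazzin anchors (single N-terminal hydrophobic stretch, the
  only HX4D motif at 69/74, the basic cleft/patch residues, a charged
  exon-5 region 125-154 with Phe128, modeled-domain net charge +5). It is
  a *synthetic stand-in*: filler positions are not the biological sequence,
  so sequence-identity benchmarks against real homologs are out of reach by
  design, and passing tests demonstrate the machinery, not biology.

All generators are deterministic under a fixed seed. Passing tests on these
constructs show the algorithms recover designed ground truth; they do not
show that a homology model of a real protein is accurate, and quantities
that depend on the original model coordinates (e.g. regenerated cleft
tables for the true tafazzin model) are deliberately not claimed.

# Packaged fixtures and the exon map

The packaged mutation table transcribes the 39 published Barth-syndrome
missense mutations with their printed exon, location, flag and effect
columns; 33 unique positions across eight exons. The published text counts
8 exon-2 sites while the table's own assignments give 9 (Gly80 sits at the
exon 2/3 boundary); the fixture keeps the table's assignment and the
discrepancy is documented here rather than resolved. The exon map is exact
for exon 5 (125-154) and otherwise approximate, chosen consistent with
every printed residue-exon assignment; it is a fixture convention, not an
annotation of record. Model numbering follows full-length numbering with
the Δ5 isoform obtained by `mapNumbering()` (subtract 30 beyond exon 5,
undefined inside it).

# Problem sizes and degenerate inputs

The test and acceptance workloads use constructs of a few hundred atoms,
alignment pairs up to length 30 (plus exhaustive enumeration up to length
6), grids of roughly 40^3-60^3 voxels and 78-200 synthetic ligands — sizes
chosen so the whole suite runs in well under a minute while every assertion
still exercises the full algorithm. Degenerate inputs are defined rather
than accidental: empty mutation tables produce empty reports, empty
residue sets produce all-zero tabulations, a contact distance of 0 yields
an empty lining, a single ligand reports sd 0 with n = 1, and boundary
relative accessibility (exactly 0.1) is exposed, not buried.

# Known limitations

* Homology model building, model-quality Z-scores, Poisson-Boltzmann
  electrostatics and multiple sequence alignment are out of scope; the
  pipeline annotates a *given* structure.
* The disorder and TM heuristics are single-scale stand-ins for consensus
  predictors; they are calibrated for clear-cut cases (long charged
  stretches, long hydrophobic stretches).
* The grid cleft detector's volumes are digitization-dependent; compare
  volumes only at matched grid spacing and orientation.
* Secondary-structure assignment is torsion-window based and needs
  complete backbones; missing atoms demote residues to coil with a
  warning.
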