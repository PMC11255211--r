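---
title: "Mining alternate backbone conformations from crystal structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining alternate backbone conformations from crystal structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(altlocr)
```

## The problem

X-ray crystal structures are refined against electron density averaged over
every molecule in the crystal. Where that density supports two or more
discrete conformations, atoms are deposited in *alternate locations*
(altlocs), labelled `A`, `B`, and so on, each with its own coordinates,
occupancy and B-factor. Most structure-reading software keeps only the first
location by default, so altlocs — direct experimental evidence of
conformational heterogeneity, including in the backbone — are easy to
overlook. altlocr parses coordinate files with every location retained and
derives a per-residue feature table and a per-chain metadata table that
describe this heterogeneity quantitatively.

## The procedure, stage by stage

**Parsing and canonicalization.** Every ATOM/HETATM record becomes one atom
location; waters and hydrogens are kept but flagged, and all downstream
stages exclude them. Deposited labels are occasionally non-standard (a lone
`Z`, or `{Y, Z}`); per residue, any label set that is not a prefix of
`A, B, C, ...` is sorted lexicographically (raw character order) and
reassigned from `A`, with the original labels retained so emitters can
render provenance as `A(Z)`. The relabeling scope is *per residue*: label
sets vary residue by residue in real files, so a chain-wide remapping would
couple unrelated residues. Relabeling is idempotent and never touches
coordinates, occupancies or B-factors.

**Dihedral angles per altloc.** For each residue, phi/psi/omega are computed
once with every atom at its *default* location ("ignoring altlocs") and once
per backbone altloc label. At altloc `X`, atoms of the flanking residues that
do not carry `X` fall back to their default location — the single modelled
position when the neighbour has one, which is the common case. Two
conventions had to be fixed where the tables alone do not pin them down:

* *Default position* means the blank-label location when one exists,
  otherwise altloc `A`. This matches what conventional parsers return when
  altlocs are ignored.
* *Omega* for residue *i* is the torsion of the peptide bond arriving at
  *i*: `CA(i-1), C(i-1), N(i), CA(i)`. The alternative (the departing bond)
  is equally defensible; the choice is documented rather than guessed
  differently per chain.

Angles are IUPAC-signed degrees in `(-180, 180]`, computed internally at
full precision and rounded to 3 decimals only at emission. Chain termini and
author-numbering gaps leave the affected angles undefined rather than
spanning a non-bonded junction. Degenerate geometry (collinear points)
yields an undefined angle, not an error.

**B-factors and positional uncertainty.** The per-residue B-factor is the
mean over the backbone N, CA, C atoms; at a specific altloc it is defined
only when all three atoms carry that label. The isotropic B-factor converts
to a positional standard deviation via `sigma = sqrt(B / (8 * pi^2))`
(so `B = 8 * pi^2 ~ 78.96` squared Angstroms corresponds to 1 Angstrom).
For every unordered pair of CA altlocs, the inter-conformer distance
`d = ||p_X - p_Y||` is reported both raw and normalized as
`d / sqrt(sigma_X * sigma_Y)`, using each CA atom's own B-factor (not the
residue mean). When either sigma is zero the normalized distance is emitted
empty, not infinite. Anisotropic (ANISOU) records are ignored; the isotropic
field is authoritative.

**Contacts.** All locations of all heavy, non-water atoms — across every
chain and hetero component of the structure — are indexed on a uniform grid
with cells at the threshold spacing, so each query inspects only 27 cells.
Per source residue and altloc, the minimum atom-pair distance to every
(target residue, target altloc) is kept and pairs strictly below 5 Angstroms
are classified: hetero components anywhere are ligand contacts; amino acids
split into same-chain and out-of-chain lists. Single-location targets carry
the pseudo-label `~`, and a source at altloc `B` still sees *every* altloc
of the target, which is what the published record format implies. Three
details are deliberate:

* Sequence-adjacent residues are *not* excluded, so covalent neighbours
  always appear in the same-chain list; consumers should filter by sequence
  distance if they want non-bonded contacts only.
* `contact_smax` (the maximum sequence separation among contacts) uses
  same-chain amino-acid contacts only, since sequence distance is undefined
  across chains.
* Distances are rounded to 2 decimals at rendering only; the grid result is
  identical to an exhaustive all-pairs scan, which the test suite asserts on
  randomized structures.

**Sequence alignment and codons.** Chain sequences are aligned globally
(Needleman–Wunsch) to UniProt records under BLOSUM80 with an affine gap
costing `10 + 0.5 * k` for length `k`. Global rather than local alignment is
used because the purpose is end-to-end residue indexing of the whole chain.
Codon assignment translates each coding sequence with the standard genetic
code (the first stop terminates translation), aligns the translation to the
chain with the same scoring, and per residue takes the most common aligned
codon; the codon score is the proportion of contributing sequences carrying
it. The denominator is the number of coding sequences that contributed *any*
codon at that position, which keeps the score meaningful when some CDSs do
not cover a position. Ties break to the lexicographically smallest codon so
the output is deterministic. Chains mapping to zero or several UniProt
identifiers (synthetic or chimeric constructs) are excluded before emission.

**Quality filter.** A structure is admissible iff `R_work <= 0.98 * R_free`
and `R_free <= min(0.3, max(0.2, cutoff(resolution)))`. The
resolution-dependent cutoff is the 90th percentile of `R_free` in 12
equiprobable resolution bins over 0.5–3.5 Angstroms, fitted by a cubic
polynomial constrained to be monotone non-decreasing (non-negative
derivative on a dense grid, enforced by a quadratic penalty refined from the
unconstrained least-squares fit; degree 3 is the smallest degree that
follows the gentle curvature of the percentile trend without oscillating on
12 points). Each bin is represented by its median resolution; percentiles
interpolate linearly between order statistics. Whatever the fit does, the
min/max composition keeps the effective bound inside `[0.2, 0.3]`. The
fitted model serializes to a JSON sidecar so a filtering run is reproducible
without refitting.

**Segmentation.** A residue *harbors* a backbone altloc when its CA atom is
modelled in at least two locations — the CA-based criterion mirrors how
backbone altloc segments are counted in practice, and deliberately ignores
side-chain-only altlocs. Maximal runs of sequence-adjacent harboring
residues are numbered `1, 2, ...` from the chain start. Both an unmodelled
gap and an intervening single-conformer residue split a run: a region whose
second conformer is missing for a few residues therefore counts as two
segments.

**Clustering.** Chains are grouped into non-redundant clusters at minimum
sequence identity 0.5 and bidirectional coverage 0.8. When an external
clustering tool (`mmseqs`) is on the PATH it is used through its standard
FASTA-in/TSV-out interface; otherwise a built-in greedy centroid algorithm
applies: sequences are visited longest-first (ties by identifier, making the
partition independent of input order), each unassigned sequence seeds a
cluster, and later sequences join when global-alignment identity
(matches / alignment columns) and the aligned fraction of *both* sequences
pass the thresholds against the centroid. The two paths share one output
contract: a dense integer cluster id per chain.

**Emission.** The per-residue table has one row per chain sequence position,
including unmodelled positions inferred from numbering gaps (insertion-code
column `M`, geometry empty). Altloc-suffixed columns exist for labels A–D
and the six unordered pairs; labels beyond `D` are dropped from suffixed
columns with a warning. `rel_loc = (pdb_idx + 1) / seq_len` lies in
`(0, 1]`; terminal distances count modelled residues only and are therefore
under-estimates when termini are unmodelled. In-cell lists keep their own
delimiters (contacts `,`, altloc names `;`, codon options `/`) and survive
inside the comma-delimited CSV through quoting. Default numeric precision is
3 decimals for angles, distances, sigmas and codon scores, 2 for contact
distances inside rendered lists. `seg_id` is empty, not zero, outside
segments. Peptide-bond lengths across altloc pairs are computed by the
geometry stage and can be emitted to a separate `peptide_bonds.csv` behind a
flag, since the fixed residue-table schema has no column for them.

## The synthetic-structure generator

Every stage is testable without downloads through `make_structure()`: an
ideal-geometry backbone (standard bond lengths N–CA 1.458, CA–C 1.525,
C–N 1.329 Angstroms and planted phi/psi/omega torsions, so dihedral recovery
is an exact test), altloc segments duplicated at a planted displacement
(making the inter-conformer CA distance exact by construction), unmodelled
gaps, B-factor plans, ligands, waters and hydrogens. Ground truth is derived
arithmetically from the plant, never by the code under test. Two dedicated
stand-ins, `synthetic_contact_showcase()` and `synthetic_broken_segment()`,
realize published-style worked examples — a two-chain contact topology with
planted distances of 3.05/4.32 (out-of-chain) and 2.54/4.13 Angstroms
(two-conformer ligand), and an altloc region interrupted between residues 37
and 41 that must count as two segments. They are synthetic coordinates, not
deposited entries.

What the generator does *not* emulate: side chains, realistic packing
density, occupancy imbalance between conformers, anisotropic displacement,
correlated noise in coordinates, or crystal-lattice symmetry mates. Passing
tests therefore demonstrate the correctness of the extraction arithmetic and
bookkeeping, not robustness to every pathology of deposited files.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| contact threshold | 5.0 | Angstroms | published contact definition (exclusive) |
| altloc label limit | A–D | — | fixed column schema |
| collection criteria | X-ray, res <= 3.5, R_free <= 0.33, <= 20 chains | — | collection conditions |
| alignment scoring | BLOSUM80, gap 10 + 0.5k | — | published alignment options |
| cluster identity / coverage | 0.5 / 0.8 | fraction | published redundancy thresholds |
| cutoff fit | 12 equiprobable bins, 90th percentile, cubic | — | quality-filter construction |

## Problem sizes in the test and acceptance runs

The suite exercises chains of 3–30 residues, randomized contact structures
of up to a few hundred atom locations (40–100 structures per
oracle-equivalence check), 4000 simulated (resolution, R_free) points for
cutoff recovery, and alignment oracles over all pairs up to length 2 plus
120–180 random longer pairs. These sizes were chosen so that the exhaustive
oracles (all-pairs contact scans, dynamic-programming alignment) remain the
clearly-correct reference while still covering every code path, including
altloc fallbacks, gaps, ligands, waters and hydrogens.

## Known limitations

* Only the asymmetric unit is analysed; symmetry-mate and lattice contacts
  are absent by design.
* Occupancies are parsed but never used; no occupancy-weighted averaging.
* DSSP is invoked only when its executable is installed; otherwise
  secondary-structure labels are blank (with a warning) and the run
  proceeds.
* Side-chain (chi) torsions and side-chain-only altloc segments are out of
  scope.
* mmCIF input is not yet supported; the PDB dialect is the reference format.

## A minimal worked run

```{r example, eval = FALSE}
fx <- make_structure(fixture_spec(
  10, altloc_segments = data.frame(start = 4, end = 6,
                                   dx = 0.6, dy = 0, dz = 0)))
res <- run_pipeline(pipeline_config(fx$path, tempdir()))
res$data[5, c("pdb_idx", "seg_id", "num_altlocs", "dist_CA_AB",
              "sigma_CA_A", "phi_A", "phi_B")]
```
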