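---
title: "Peptide/HLA-I backbone analysis and template ranking: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peptide/HLA-I backbone analysis and template ranking: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phlatlas)
```

## The problem

Class I HLA molecules present short peptides (mostly 8-10 residues) in a
groove formed by the alpha1/alpha2 domains of the heavy chain -- the
*platform*, here always the first 180 residues.  The peptide docks through
anchor residues in the B and F pockets; its central residues bulge toward
the T-cell receptor and carry most of the conformational diversity that
matters for recognition.  This package provides the quantitative machinery
for analyzing that diversity from crystal structures and for ranking
candidate template-based models of new peptide/HLA complexes:

1. **Curation** of raw coordinate files into a standardized form.
2. **Anchor classification** in the groove frame.
3. A **dihedral-space dissimilarity** (the D-score) between peptide
   backbones.
4. **Greedy reduction** of a structure set to discrete representative
   backbones.
5. **Sequence-bias analysis** of backbone-constrained sequence spaces.
6. **Regression-based template ranking** from per-residue energy features.

## Curation

A raw entry is classified chain by chain: a chain with more than 50%
global-alignment identity (Needleman-Wunsch, BLOSUM62, gap open 10 / extend
0.5, identity = matches over reference length) to the 180-residue reference
heavy chain is the HLA heavy chain; similarity to beta-2 microglobulin marks
b2m; an 8-10-residue chain is a peptide; everything else is "other".  An
entry is kept when its resolution is at or better than 3.0 Angstrom (read as
quality at least that of 3.0), no "other" chain has an atom within 5
Angstrom of the peptide (a contacting extra chain -- a TCR, an antibody --
would perturb the peptide conformation), and the peptide backbone is
complete with positive occupancies.  Zero-occupancy heavy-chain atoms are
reported but tolerated; one or two missing N-terminal heavy-chain residues
set a flag (`rebuilt_nterm_needed`) rather than triggering a rebuild, which
is left to external modeling tools.  Accepted entries are trimmed to the
platform, renumbered 1-180 (chain A) and 1-n (peptide, chain C), and typed
against a user-supplied allele reference FASTA by the same alignment
identity, ties resolving to the lexicographically smallest allele name.

Design choices where the procedure was genuinely open: alternate locations
other than blank/'A' are dropped before occupancy checks; when an
asymmetric unit contains several copies of the complex, the first complete
assembly in chain order is curated; beta-2 microglobulin presence is not
required (the platform plus peptide suffice for every downstream
computation).  Curation is idempotent: re-curating a curated file returns
the same record, which the tests assert.

## Anchor classification

Rather than classifying by peptide length, peptides are classified by the
sequence separation of their anchors.  The B- and F-pocket probes are the
Calpha atoms of platform residues 24 and 123; the b (f) anchor is the
peptide position whose Calpha is nearest the respective probe.  The anchor
class is `f - b` (Delta-6/7/8 in curated data) and the anchor distance is
the Calpha-Calpha distance between the anchors.  All peptide positions are
searched; on a distance tie the lower index wins for b and the higher for f,
so pathological ties cannot produce a non-classification silently.

## Internal-coordinate building and the ideal PPII chain

`build_backbone()` constructs a chain from phi/psi by sequential
natural-extension-reference-frame (NeRF) placement with fixed ideal
geometry and a trans peptide bond (omega = 180).  The constants are
Engh-Huber-style bond lengths (N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom)
with a tetrahedral alpha-carbon angle (N-CA-C 109.5 degrees), CA-C-N 116.2
and C-N-CA 121.7.  The angle set was fixed once by a physical calibration:
a polyproline-II nonamer (phi = -75, psi = +145 everywhere) must show a
P2-P9 anchor distance of 21.4 +/- 0.2 Angstrom, the published value for an
ideal PPII chain; the shipped constants give 21.48.  A slightly larger
alpha-carbon angle (111 degrees) would land at 21.67, outside that band,
which is why the tetrahedral value was preferred.  Torsion signs follow the
IUPAC convention and are cross-checked against bio3d in the test suite;
the build-measure round trip is exact to better than 1e-6 degrees.

The anchor-distance Ramachandran surface (`rama_anchor_surface()`) builds a
uniform-dihedral nonamer for every (phi, psi) pair on a 1-degree lattice
(both -180 and +180 endpoints kept for plotting symmetry; they describe the
same torsion) and masks the band of distances observed for Delta-7 peptides,
17.5-20.0 Angstrom.  For uniform dihedrals each residue is carried onto the
next by one rigid transform, so the distance is computed from a 4x4
transform power rather than a full build -- roughly an order of magnitude
faster over the 361x361 lattice; the fast path is verified against direct
builds in the tests.  The ideal PPII point lies *outside* the band (21.48 >
20.0): a real Delta-7 nonamer cannot be uniformly PPII and must bend locally
in its central residues, which is the structural origin of the diversity the
rest of the package quantifies.

## The D-score

Backbone dissimilarity is measured in dihedral space.  For one angle pair,

\[ D(\theta_1, \theta_2) = 2\,(1 - \cos(\theta_1 - \theta_2)), \]

a cyclic quantity in [0, 4].  The D-score between two backbones sums
`D(phi_p) + D(psi_p)` over the central window: P4-P7 for Delta-7 (8 angle
terms), P4-P6 for Delta-6, P4-P8 for Delta-8.  Two Delta-7 backbones are
*neighbors* when their D-score is at most 1.5, a criterion designed so that
neighbors show sub-angstrom central backbone RMSD; windows with fewer or
more angles scale the threshold proportionally (1.125 for Delta-6, 1.875
for Delta-8).  The scaled values follow from the stated proportionality and
are flagged to users as an inference, not published constants.  The
comparison is "at or below" 1.5; the metric depends only on dihedrals and
is therefore exactly invariant to rigid-body motion, which Cartesian RMSD
in a global frame is not.

`per_position_dscore()` returns the window profile (summing to the total),
used to localize where two backbones diverge.

## The greedy atlas

From the pairwise adjacency (D-score at or below threshold, self excluded)
the structure with the most neighbors is selected as a *discrete peptide
backbone*; it and its neighbors are removed, and the procedure repeats on
the reduced matrix until nothing remains.  Neighbor counts are recomputed
on the reduced matrix at each iteration.  Zero-neighbor structures survive
as singleton representatives -- deliberately, because a structure set this
size underestimates the frequency of rare conformations and discarding them
would truncate the conformational space.  Ties on the neighbor count break
to the lexicographically smallest structure id, making the atlas
deterministic and invariant to input order (asserted by a property test
against a brute-force reimplementation).  The historical analysis reruns
the full greedy selection on each cumulative yearly subset, and
`pca_features()` embeds backbones by the standardized sines of the window
dihedrals (sine rather than the raw angle avoids the -180/+180 wrap;
features with numerically zero variance are centered but not rescaled, so
floating-point noise cannot masquerade as signal).

## Sequence-bias analysis

For a fixed backbone, the space of plausible central sequences (P3-P8) is
the Cartesian product of per-position alphabets.  The shipped alphabet
table restricts each position to 8-12 residues, proline always included for
its backbone-restraining effect; its sizes (11, 9, 10, 11, 9, 8) multiply
to 784,080, the size of the enumerated space per backbone, and the table is
plain-TSV configuration the user can replace.  Models are scored externally
(energy-function scoring is outside this package's scope; a deliberately
non-physical surrogate scorer ships for tests) and the top 1% by energy --
`floor(0.01 * N)`, so 7,840 of 784,080 -- define the backbone's sequence
space.  A position probability matrix is built from the retained sequences
with zero cells floored at 0.02; columns are *not* renormalized after
flooring, because only zeroes are adjusted -- the downstream KL divergence
therefore uses a very slightly improper distribution, exactly as the
flooring rule implies, and this is documented rather than silently
corrected.  Per-position Kullback-Leibler divergence
\(\sum_a p(a)\ln(p(a)/q(a))\) (natural log) quantifies the bias of a
backbone's sequence space against a reference peptide set.

## Template ranking by regression

Candidate models for a target are built on representative backbone
templates.  Filters: templates whose peptide differs from the target's at
three or fewer of nine positions are *homologs* and removed (a
benchmarking guard against sequence leakage); a relaxed model that drifts
more than a D-score of 1.5 from its template crystal backbone is dropped;
when screening the template set itself, relaxations moving more than 1.0
disqualify the template and the atlas is reselected.  Training rows with a
true D-score above 7 are excluded as uninformative outliers.

Each model carries a fixed-length vector of per-residue energy features
(the pipeline treats it opaquely; the default width is 129 to match
practice, but any width works).  Features are mapped through a uniform
quantile transform fitted on the training rows only -- each feature's
empirical CDF, interpolated between stored quantile landmarks, forward and
reverse interpolants averaged so tied runs map to the midpoint of their
probability mass, out-of-range values clamped, constant features sent to
0.5.  An RBF support-vector regression predicts the true D-score; cost and
epsilon are grid-searched over powers of ten spanning 1e-4 to 1e4, selected
by 5-fold inner cross-validated R-squared on the training split.  The grid
granularity and the inner CV are this package's choices (the selection
criterion and the grid range are given, the folds are not; selecting by
training-set R-squared would degenerately favor the largest cost).  For a
target, the candidate with the lowest predicted D-score is reported; in
abstention mode (used for allotypes outside the dominant A02 supertype,
threshold 2.0) no model is reported when even the best prediction reaches
the threshold.

The leave-one-out benchmark removes *all* rows of one target, refits the
transform and the grid search on the rest (no leakage, asserted by a test),
ranks the held-out candidates and scores success as a selected model with
true D-score at or below 1.5.  It reports overall accuracy, accuracy within
the most common backbone class versus the rest, and a seeded
random-selection baseline.  On synthetic tables the target's "class" is its
nearest template by true D-score; the neighborhood-based grouping used with
real data needs real models.

## What the synthetic data does and does not show

The fixture generator emulates: a 180-residue platform with the pocket
probes at renumbered positions 24 and 123 (a rigid dummy ribbon -- only the
probe positions, sequence and chain lengths matter to the code under test);
peptides with per-position Gaussian dihedral sampling around PPII; families
of backbones with controlled spread; and candidate-model feature tables
with a planted monotone feature-to-D-score relation (each target given one
near-native template, true D-score 0.3-1.2, against a background of
1.8-6.5).  Defaults -- nonamers, PPII center, Delta-7 anchors at P2/P9, the
17.5-20 Angstrom band, 129-width-compatible opaque features -- mirror the
study conditions for Delta-7 analysis.

Passing tests on these fixtures demonstrate algorithmic correctness
(metrics, selection, filters, regression plumbing, determinism), not
physical accuracy: the scaffold is not an HLA fold, the surrogate scorer is
not an energy function, and the planted feature relation is far cleaner
than Rosetta-derived energies.  Consequently the published real-data
benchmark accuracies (63% for A02 targets, 60% for non-A02) are *not*
reproduced here -- they require externally generated structural models --
and the corresponding dataset-level checks run only when the user supplies
the curated corpus (`options(phlatlas.corpus_dir = ...)`) and the worked
crystal-structure pair (`options(phlatlas.pdb_dir = ...)`).

## Numerical choices and problem sizes

Tolerances: dihedral round trips are asserted at 1e-6 degrees; superposition
RMSD identities at 1e-6 Angstrom; the PPII anchor distance at +/-0.2
Angstrom (bond-constant uncertainty).  Degenerate inputs: empty matrices
give empty atlases; an empty candidate list yields an abstention with
reason; fewer than 10 training rows is an error; undefined window dihedrals
exclude a structure from the matrix rather than being imputed.  The test
suite runs at deliberately small problem sizes (20-node graphs, 15-32
synthetic targets, reduced 5x4 hyperparameter grids, coarse Ramachandran
lattices) chosen so the full suite completes in a few minutes while still
exercising every code path; the defaults exposed to users are the
full-scale ones (9x9 grid, 5 folds, 1-degree lattice).

## Known limitations

- Template ranking is limited to Delta-7 nonamers, as the window and
  thresholds assume that class; other lengths are classified but not
  modeled.
- Decamers that could be truncated to Delta-7 nonamers are only flagged;
  truncation is manual curation by design.
- The mmCIF reader covers the standard whitespace-delimited atom_site
  loops written by the PDB, not the full CIF grammar.
- Energy scoring, relaxation and threading are external: this package
  consumes their outputs through the feature-table and scorer contracts.
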