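---
title: "Designing C3-symmetric beta-trefoils by ancestral reconstruction"
author: "TrefoilForge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing C3-symmetric beta-trefoils by ancestral reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TrefoilForge)
```

## The problem

Beta-trefoil lectins such as the mussel galactose-binding lectin family
fold from three tandem repeats of roughly 47 residues, each a
four-stranded beta-sheet, arranged with approximate (pseudo) threefold
symmetry about a central axis. The repeats of a natural trefoil are
similar but not identical, and the asymmetry often serves other
functions -- in the mussel lectin it helps form a dimer interface. A
perfectly symmetric monomer built from a single repeated sequence is an
attractive design target: it removes the dimer dependence, and a single
47-residue repeat determines the whole protein.

`TrefoilForge` implements that design route as a tested pipeline:

1. extract the three repeats and superpose them (`extractRepeats`,
   `kabsch`, `trimmedSuperpose`);
2. fit the pseudo-threefold axis (`fitC3Axis`);
3. reconstruct the most probable common ancestor of the three repeat
   sequences by maximum likelihood, and sample a pool of candidate
   ancestral repeats (`inferTree`, `marginalPosterior`,
   `sampleCandidates`);
4. build an exactly C3-symmetric backbone from one repeat
   (`symmetrize`), optionally grafting a donor linker segment from a
   previously designed symmetric trefoil into each junction
   (`graftLinker`);
5. thread every candidate repeat (concatenated with junction linkers)
   onto each backbone variant, score it with a coarse contact energy,
   and select designs by total energy, C-alpha RMSD to the natural
   template, and internal cavity volume (`threadSequence`,
   `scoreDesign`, `rankAndSelect`, `cavityVolumeForDesign`);
6. backtranslate the chosen sequence to an expression-ready gene with
   flanking NdeI/XhoI sites, no internal sites, and no self-annealing
   segments (`backtranslate`, `removeInternalSites`,
   `fixSelfAnnealing`, `buildConstruct`).

`runDesign` orchestrates the whole study; `designReport` writes the
candidate table, the energy-versus-RMSD scatter data and a JSON summary.

## Superposition and the symmetry axis

Rigid superposition uses the Kabsch algorithm: SVD of the covariance
matrix of the centred point sets with a determinant sign correction, so
the rotation is always proper. `trimmedSuperpose` iterates
superposition and removal of pairs beyond a distance cutoff (default
3.5 Angstrom, the conventional C-alpha equivalence threshold). Per
iteration at most the worst 10% of over-cutoff pairs are dropped; pairs
are never re-admitted, making the retained count non-increasing. The
gradual schedule matters: when gross outliers skew the first fit,
dropping everything beyond the cutoff at once can discard genuine
equivalences.

The threefold axis is fitted from the two repeat-to-repeat rotations
(A to B and B to C), averaged as sign-aligned quaternions. The
reported `angle` is the pre-projection mean of the two rotation angles
-- a diagnostic of how threefold the arrangement really is (the fit
refuses inputs outside 120 +/- 40 degrees) -- while construction always
uses exactly 120 degrees about the fitted axis. The axis anchor point is
the grand centroid of the three repeats, which lies on the axis exactly
for any C3 orbit and within noise otherwise.

Structure-guided sequence identity (`structureGuidedIdentity`) pairs
residues one-to-one in sequence order whenever their C-alpha atoms lie
within 5 Angstrom after superposition (a dynamic programme maximises the
number of pairs, then minimises total distance), and reports identical
pairs over paired positions -- the convention of structure-based
alignments, where quoted identities refer to structurally equivalent
positions rather than full-length sequences.

## Ancestral reconstruction

The three aligned repeat sequences are treated as leaves of a
three-leaf star tree (three leaves admit no other unrooted topology).
Branch lengths are fitted by cyclic golden-section maximisation of the
Felsenstein pruning likelihood to a 1e-6 log-likelihood tolerance.
The substitution model is JTT by default (WAG selectable): published
exchangeabilities and equilibrium frequencies, assembled into a
reversible rate matrix normalised to one expected substitution per
site, with transition matrices computed exactly through the symmetric
eigendecomposition of the similarity-transformed rate matrix. No
among-site rate heterogeneity is used -- with three short repeats there
is little power to estimate it, and the reconstruction target is the
posterior mode rather than branch-length accuracy.

Marginal root posteriors are computed per site
(`P(root = a | data) proportional to pi_a prod_k (P(t_k) L_k)_a`), gaps
and unknown residues entering as missing data. Candidate repeats are
drawn site-independently from these posteriors; the
maximum-a-posteriori (MAP) sequence can be included explicitly and is
tagged in the candidate table. Joint (path-consistent) sampling is a
deliberate non-goal: for a star tree with a concentrated posterior the
marginal pool is an adequate stand-in for the server-based
reconstruction it replaces, and its log-posterior bookkeeping is exact.

The default candidate pool in the full protocol is 2000 sequences; the
bundled tests and the acceptance script run 50 per backbone variant so
that a complete study stays in the minutes range -- the selection logic
is invariant to pool size.

## Symmetrisation, linkers and grafting

`symmetrize` stores one repeat unit plus the axis; subunits are
generated by rotation, so subunit equivalence is exact by construction
(the validity invariant checks subunit-versus-rotated-subunit RMSD
below 1e-6 Angstrom). The optional rigid-body placement search scans
the unit's spin about the axis (0-119 degrees, 1-degree steps) and its
axial and radial offsets (+/-3 Angstrom, 0.25 steps) against a coarse
packing objective -- soft-sphere clash (pairs under 4 Angstrom,
quadratic) minus an interface contact count (4.5-8 Angstrom) -- as a
staged cyclic search (spin, then axial, then radial, two cycles) rather
than the full cross-product; the objective is cheap but the
cross-product would be ~75k evaluations for no practical gain on these
landscapes. An interface C-alpha distance under 2.5 Angstrom at the
optimum is a hard packing error.

Two junction schemes are implemented, because the design protocol's two
descriptions differ: Gly-Asp-Gly tripeptide linkers (repeat length 47
gives a 147-residue chain, linkers at 48-50 and 98-100) and single
glycines at the junctions (143 residues, glycines at 48 and 96). The
single-glycine scheme is the default; the discrepancy is surfaced in
the documentation rather than resolved. Note the tripeptide arithmetic:
with 47-residue repeats the second linker necessarily occupies 98-100,
not 97-99 -- position 97 is the last residue of the second repeat.

`graftLinker` replaces the junction-proximal `k` residues (k = 6 or 9)
of the repeat unit with a donor segment. The donor is anchored by the
three residues on each side of its segment, superposed onto the host
anchors (the three residues before the replaced stretch and the first
three of the next symmetry mate); an anchor RMSD above 1.5 Angstrom
rejects the graft. Because the graft edits the stored unit, all three
junctions carry it identically and C3 symmetry is preserved exactly.
Grafted residues are tracked by per-residue provenance, and the
threading stage keeps donor positions fixed at the donor sequence --
candidate sequences fill only the template-derived positions.

`regularizeBackbone` polishes geometry by gradient descent on harmonic
consecutive-C-alpha bond terms (ideal 3.8 Angstrom) plus a soft-sphere
clash term, with a backtracking step size so the objective never
increases. Explicit angle restraints are omitted by design: a
C-alpha-level representation has no single ideal pseudo-angle, and any
fixed target would distort already-acceptable geometry.

## Coarse threading energy

The scoring function is deliberately coarse and documented, not a
reproduction of any all-atom design score; energy-based rankings are
therefore comparable within a run, never against published design
scores. Terms:

* **contact** -- sum over pseudo-C-beta contact pairs (8 Angstrom
  cutoff, sequence neighbours excluded) of a 20x20 additive
  hydrophobicity potential `e(a,b) = -0.3 (h_a + h_b)` built from the
  Fauchere-Pliska octanol scale (glycine = 0 by that scale's
  convention). Additive hydrophobicity terms are the dominant component
  of knowledge-based contact potentials, and the additive form keeps
  the scale fully transparent.
* **burial** -- minus hydrophobicity times neighbour count (C-alpha
  atoms within 10 Angstrom), rewarding buried hydrophobics.
* **clash** -- quadratic soft-sphere penalty on non-bonded C-alpha
  pairs under 4 Angstrom.
* **cavity** -- the design's internal cavity volume in cubic Angstrom.

Default weights are 1 / 1 / 10 / 0.05; the total is the weighted sum
and lower is better. Pseudo-C-beta points sit 1.5 Angstrom from the
C-alpha along the local chain bisector (glycine and degenerate
geometry use the C-alpha itself), so designed backbones without side
chains score consistently. Selection picks three designs: lowest total
energy, lowest C-alpha RMSD to the natural template, and smallest
cavity, with lexicographic tie-breaks and candidate-id as the final
tie-break, making selection a deterministic function of the design set.
The galactose-binding motifs (HxDxH, HPxGG) are checked per repeat and
flagged, not enforced -- in this design philosophy the reconstruction
itself is expected to retain functional sites.

## Cavity detection

`detectCavities` is a dual-probe grid method. Voxels within
(vdW + small probe) of an atom are protein; the bulk solvent is the
region swept by a large probe rolled from outside (flood fill of
large-probe-accessible space from the box faces, then Euclidean
dilation by the large-probe radius, implemented by FFT convolution with
a ball kernel); whatever is neither protein nor bulk is cavity.
Components are 6-connected; those below 5 cubic Angstrom are
discarded. Defaults: small probe 1.4 Angstrom (water), large probe 4.0,
spacing 0.6 -- the conventions of grid cavity detectors. Per-element
vdW radii (C 1.70, N 1.55, O 1.52, S 1.80) serve atomic models; for
C-alpha-only design models each residue gets an effective radius
`(3V/4pi)^(1/3)` from standard mean residue volumes (glycine 2.43 to
tryptophan 3.79 Angstrom).

Two properties deserve care. First, volumes are grid-quantised; the
hollow-shell fixture shows sub-1% error at 0.6 Angstrom spacing against
the analytic eroded-ball volume, but irregular protein cavities should
be compared across structures at a fixed spacing. Second, cavity
volume is monotone in atom radii only while the cavity's topology is
unchanged: growing radii can close a channel against the large probe
and so create cavity volume where there was bulk. The packaged tests
exercise monotonicity on a sealed fixture for exactly this reason.

## Gene design

`backtranslate` maps the protein to codons either by
highest-frequency codon (ties alphabetical) or by sampling the codon
usage table (a representative E. coli K-12 table ships with the
package; frequencies are renormalised per amino acid and users can
supply their own). `removeInternalSites` breaks every internal
NdeI/XhoI occurrence (both strands; both sites are palindromic) with
the highest-frequency synonymous codon swap that removes it.
Self-annealing is operationalised as an exact reverse-complement match
of length at least 10 nucleotides between two positions of the coding
sequence -- the stems of hairpins and the seeds of mispriming -- found
by k-mer hashing and broken by next-most-frequent synonymous swaps,
iterating to a fixpoint; edits that would create a restriction site are
rejected, every edit is logged, and unrepairable residues are reported
with a warning rather than an error. The assembled construct is
`CATATG` + coding + `TAA` + `CTCGAG`, the NdeI site supplying the
initiator ATG.

## The synthetic fixtures, and what passing tests do not show

`makeC3Backbone` builds each repeat as four zig-zag strand walls
(exact 3.8 Angstrom C-alpha spacing, single-residue turns) standing
parallel to the symmetry axis at a 6.2 Angstrom radial offset, so the
three walls pack with contact-range interfaces and enclose an axial
void whose detected volume is stable across grid spacings. The noise
parameter sigma is the RMS total displacement per atom (per-coordinate
standard deviation sigma/sqrt(3)), making the expected pairwise repeat
RMSD of two noisy copies sqrt(2) sigma -- the scale used in the noise
band checks. The fixture deliberately has no hydrogen-bond-realistic
sheet geometry, no side chains and no loops between subdomains; tests
passing on it demonstrate the *algorithms* (superposition, axis
recovery, symmetrisation, cavity arithmetic, selection logic), not that
the coarse energy would rank real trefoil designs as an all-atom
method would. `makeShell` tiles a Fibonacci sphere densely enough to
seal against the water probe (the seal is verified, and refused if
broken, unless a deliberate polar aperture is requested) and records
the analytic interior volume `(4/3) pi (r_inner - probe)^3` for use as
an exact oracle. `evolveSequences` simulates substitution along the
star tree from a known root, giving ground truth for ancestor
recovery; with 47-141 sites and branch lengths 0.2 the MAP
reconstruction recovers the root at roughly 90-95% identity, which is
the regime the acceptance checks assert.

## Problem sizes and determinism

The bundled test-suite and the acceptance script run: 10-point
superposition oracles (a quaternion grid search refined locally);
20-seed axis-recovery and ancestor-recovery ensembles; a
~3000-atom shell at 0.6 and 0.3 Angstrom spacing; and a full design
study of 50 candidates across three backbone variants on a 141-residue
template -- sizes chosen so a complete run finishes in a few minutes on
one core. Every stochastic step takes an explicit seed; `runDesign`
records the seed and a configuration hash, and reruns with the same
configuration write byte-identical candidate tables.

## Known limitations

* The energy is a ranking heuristic; absolute values have no physical
  unit and no claim of equivalence to any published design score.
* Backbone relaxation is C-alpha-level with bond and clash terms only;
  side chains are never modelled.
* Ancestral sampling is marginal (per-site independent), not joint.
* Repeat boundaries are user input; automatic repeat detection is out
  of scope.
* Structure-guided identity assumes a one-to-one, order-preserving
  pairing; circular permutations would defeat it.
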