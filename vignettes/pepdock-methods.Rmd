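---
title: "Methods: scoring protein-peptide docking predictions and probing their inputs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring protein-peptide docking predictions and probing their inputs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepdockeval)
```

`pepdockeval` evaluates predicted structures of protein–peptide complexes
against experimental references and computes the alignment- and
library-level statistics used to interpret *why* such predictions succeed
or fail. This vignette documents the models implemented, the parameters
that matter, the numerical choices made where the design was genuinely
open, and what the synthetic-data generators do and do not emulate.

## The complex model

A complex is two chains: a folded *receptor* and a short *peptide*.
Structures are read from PDB or mmCIF; hetero residues, waters and
hydrogens are dropped on read (all metrics are defined over heavy atoms or
backbone atoms, and ligands/PTMs are out of scope), only the first model
of a multi-model file is used, and alternate conformations are collapsed to
the highest-occupancy conformer with ties broken by first occurrence — a
deterministic single-conformer model. Chains are addressed by author ids
(the `"ENTRY_XY"` naming convention); for mmCIF a flag accepts
`label_asym_id` values and translates them. Residues are indexed 1..n in
file order (the R convention), with author numbering and insertion codes
preserved alongside.

mmCIF `_atom_site` loops are parsed by header-field name rather than by
position, because column order differs between writers (RCSB, gemmi, ...).
PDB files are parsed and written via bio3d.

## Docking accuracy

**DockQ.** Native contacts are residue pairs with any heavy-atom
inter-chain distance < 5 Å; interface residues are those with any heavy
atom within 10 Å of the other chain, evaluated on the native. Both cutoffs
are the conventions of the published DockQ method and are exposed as
arguments. The score is

\[
\mathrm{DockQ} = \tfrac13\left(F_\mathrm{nat}
  + \frac{1}{1+(i\mathrm{RMSD}/1.5)^2}
  + \frac{1}{1+(L\mathrm{RMSD}/8.5)^2}\right),
\]

with iRMSD computed over interface backbone atoms after superposing on
exactly those atoms, and LRMSD over peptide backbone atoms after
superposing the receptors. Categories: poor < 0.23 ≤ acceptable ≤ 0.49 <
medium ≤ 0.80 < high. A pair with zero native contacts has no defined
score and is an error, not a zero. Residue correspondence defaults to
identical order with equal counts per chain; RMSD terms use the atoms
present in both structures, so a prediction missing a few atoms degrades
gracefully rather than failing.

**Backbone definition.** The peptide backbone RMSD uses N, CA, C, O per
residue by default, with a CA-only switch (`ca_only`), since published
figures describing "backbone residues" are ambiguous between the two.

**Atomic accuracy** is the conjunction Fnat > 0.9 (strictly, per
"more than 90%"), zero inter-chain heavy-atom pairs < 2.0 Å (the clash
rule: simple, deterministic, catches interpenetration; the threshold is an
argument), peptide all-atom RMSD < 2 Å in the receptor-aligned frame, and
interface all-atom RMSD < 3 Å in the interface-aligned frame — the
all-atom analogues of the LRMSD and iRMSD frames.

**Superposition** is the closed-form Kabsch fit (SVD with a
determinant-sign correction so the rotation is always proper). Degenerate
(collinear) reference clouds are flagged; the fit is still returned but
the rotation is not unique.

**TM-score** uses `d0 = 1.24·(L−15)^{1/3} − 1.8` floored at 0.5 and the
standard iterative search: fragment seeds of lengths L, L/2 and 4 starting
at every 4th residue, each refined up to 20 iterations by refitting on the
residues within `d0 + 1` (the inclusion cutoff widens only when fewer than
3 residues qualify). This is checked against an independent
numerical-optimization oracle in the tests rather than bit-for-bit against
any particular implementation. Only same-protein comparisons (equal-length
correspondence) are supported; flexible alignment is out of scope.

**Secondary structure** is a deliberately simplified dihedral-region rule,
not DSSP: H for φ ∈ (−100°, −30°), ψ ∈ (−80°, −5°) in runs of ≥ 4; E for
φ ∈ (−170°, −40°), ψ ∈ (90°, 180°] in runs of ≥ 3; else L, with chain
termini L. It classifies ideal helices and strands correctly and is used
only for coarse interface characterization; hydrogen-bond energetics are
intentionally omitted.

## Distogram comparison (RMSD_map)

Distograms hold representative inter-residue distances over the
concatenated chains; the representative atom is Cβ with Cα substituted for
glycine (the AlphaFold distogram convention). Bin-probability distograms
are collapsed to expected distances by probability-weighted bin midpoints;
an open final bin contributes its lower edge plus half the preceding bin
width. The comparison statistic is

\[
\mathrm{RMSD_{map}} = \sqrt{\tfrac{1}{N_c}\textstyle\sum_{(i,j)}
  (D_{\mathrm{nat},ij} - D_{\mathrm{pred},ij})^2},
\]

where the pair set is always defined on the *native* side: inter-chain
pairs with native distance ≤ 12 Å. The 12 Å default spans the
near-interface block of the contact map and is an argument, as is the
representative-atom rule, since neither is pinned down by the figure
defining the statistic. Success thresholds: RMSD_map < 2.5 Å (strict), and
peptide RMSD < 12 Å for the coordinate-based route; both exposed.

## Binding-site matches against a dated library

The search asks whether a query complex's binding site was visible in a
training set: (1) entries released on or after the cutoff date are
excluded — the date rule is strict; (2) homology by *either* arm: global
sequence identity ≥ 30% (BLOSUM62-scored Needleman–Wunsch, identity over
the alignment length) *or* receptor TM-score ≥ 0.5 — these are
conventional homology-detection bounds, exposed as arguments, with no
claim that they replicate any specific study's tooling; (3) the entry
receptor is superposed onto the query receptor (structure-based Cα fit for
structural hits, alignment-correspondence Kabsch for sequence-only hits);
(4) the partner RMSD is the Cα RMSD between the query peptide and the
entry's partner in that *fixed* frame — when lengths differ, the shorter
chain slides along the longer and the minimum-RMSD contiguous window is
used without re-superposition, a deterministic rule that avoids alignment
heuristics; (5) a match requires partner RMSD < 10 Å. Binding sites
themselves are receptor residues with any heavy atom < 5 Å from the
peptide, matching the Fnat contact convention so that "binding site" and
"contact" are mutually consistent; site identity is declared at Jaccard
overlap ≥ 0.25.

## MSA statistics

A3M input drops lowercase insertion states so columns index query
positions; because the query row carries no gaps, trimming a
context-extended MSA to the peptide span is a pure column slice. Species
tags are parsed from headers by configurable regex (UniProt `OX=` first,
then an `_SPECIES` suffix); untagged rows are never paired. Within each
shared species, rows are ranked by percent identity to their query and
paired rank-to-rank (the AF2-Multimer convention); leftovers and untagged
rows are placed block-diagonally, gap-filled in the other chain's block.
The shuffle null permutes the peptide halves of the paired rows uniformly
at random (seeded), leaving the query row and the unpaired blocks
untouched, so every block keeps exactly the same multiset of sequences.

Mutual information between two columns is the plug-in estimate in bits
over rows with no gap in either column; gaps are not a 21st symbol by
default (a flag adds them) and no pseudocount or APC correction is applied
by default — the statistic is meant to mirror a straightforward
coevolution readout, and corrections are layered choices better left to
the caller. Conservation is the Jensen–Shannon divergence between column
composition and a background (uniform over 20 by default; a
BLOSUM62-derived background is selectable, as both appear in the
conservation-scoring literature), multiplied by (1 − gap fraction);
all-gap columns score 0 and are flagged. The peptide-depth predicate (≥ 50
sequences) is exposed with both sides of the boundary tested.

## Confidence summaries

Ranking confidence is `0.8·ipTM + 0.2·pTM`, the multimer ranking
convention, reported under the label "ipTM+pTM"; weights `(1, 1)` give the
literal sum. iPAE averages both off-diagonal blocks of the PAE matrix.
pDockQ uses the published sigmoid constants (L = 0.724, x0 = 152.611,
k = 0.052, b = 0.018) with `x = mean interface pLDDT · ln(contacts)`,
contacts under the same 5 Å heavy-atom rule and interface pLDDT averaged
over the residues participating in those contacts.

## What the synthetic generators emulate

`make_toy_complex()` builds ideal-geometry backbones (N–CA 1.458 Å,
CA–C 1.525 Å, C–N 1.329 Å, standard angles, constant helical φ = −60°,
ψ = −45° or extended φ = −120°, ψ = 135° dihedrals, Cβ stubs except
glycine) and docks the peptide against the receptor face by a
deterministic bounded search (approach distance from 3.2 Å down to 2.4 Å,
four peptide spins, three axial shifts) until the requested number of
native contacts exists without clashes. `perturb_prediction()` emulates
the error spectrum of real predictions: rigid translation (recovered
exactly by the peptide-RMSD metric, which the tests exploit), rigid
rotation, per-atom Gaussian noise, and wrong-site relocation to the
opposite receptor face near the far end of the chain (≥ 20 Å centroid
displacement, disjoint binding site, poor DockQ by construction).

`make_synthetic_msas()` plants per-column structure: conserved columns put
90% of their mass on one symbol; coevolving column pairs are drawn from a
mixture of a perfectly-correlated and an independent component over a
4-symbol alphabet, with the mixing weight solved by bisection (80
halvings) so the analytic mutual information of the joint equals the
requested target. The 4-symbol alphabet keeps the plug-in MI estimator's
finite-sample bias around 10⁻³ bits at the depths used, so empirical
estimates can be compared to analytic targets within 0.05 bits. Each row
pair shares a unique species tag by default, so species pairing
reconstitutes the generating pairs exactly.

These generators are sufficient to validate the *metrics*; they do not
emulate side-chain packing, realistic energetics, sequence–structure
consistency, phylogenetic correlation between MSA rows, or the long-tailed
error modes of real predictors. Green tests therefore certify the
computations, not predictor performance on real data.

## Problem sizes and numerical choices

The test suite runs 40-residue receptors with 10-residue peptides,
MSAs up to depth 5,000, 100-seed shuffle replicates, and a 30-complex ×
4-perturbation-level batch — sizes chosen so the full suite completes in
about a minute on one core while leaving the statistics well-resolved
(e.g. the planted 1-bit MI is estimated to ±0.05 bits at depth 5,000).
Other numerical choices: distogram symmetry is enforced to 1e-6 and
bin-probability sums to 1e-4; the scramble ablation rejects the identity
permutation whenever a distinct permutation exists; RNG use is always
wrapped so generators are pure functions of their seed and never disturb
the caller's RNG stream; all boundary comparisons (category thresholds,
success classifiers, depth filter, date filter) are strict as documented
and tested on both sides.

## Known limitations

Two-chain complexes only; first NMR model only; no symmetry mates or
assemblies. TM-score requires equal-length correspondence. The
binding-site-match search scales as (library × window positions) and is
meant for curated libraries, not PDB-scale sweeps. The simplified
secondary-structure rule disagrees with DSSP near helix/strand termini.
Confidence records are read from AF-style JSON only.
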