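---
title: "Rule-based typing of bacterial PET hydrolases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based typing of bacterial PET hydrolases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petasetyper)
```

## The scientific problem

Bacterial PET-degrading alpha/beta hydrolases (PETases) have traditionally
been sorted into types I, IIa and IIb by a small set of active-site features:
the number and position of disulfide bonds, the amino-acid occupation of the
two substrate-binding subsites, and the presence of an extended loop flanking
the active site. Halotolerant enzymes from the marine *Halopseudomonas*
lineage do not fit this scheme: they combine an atypical lipase-box motif
(G-H-S-Q-G instead of G-H-S-M-G or G-W-S-M-G), a missing aromatic
"pi-stacking clamp" (a threonine replaces the first aromatic anchor), two
disulfide bonds at non-canonical positions, a five-residue insertion in one
active-site loop and a five-residue deletion in another. These enzymes
motivate a third type (type III).

`petasetyper` turns that typing argument into a reproducible pipeline:

1. **Evidence extraction** — from a query sequence (and optionally a crystal
   structure), extract the lipase-box pentapeptide, clamp status, subsite
   residues, disulfide pairs and loop-length deltas, all anchored to an
   annotated reference by global alignment.
2. **Typing** — evaluate per-type gate predicates and scored positions,
   producing an auditable call (I / IIa / IIb / III / unclassified).
3. **Mining** — build a simplified profile HMM from a seed family, score
   candidates in bits, apply the strict >100-bit hit rule and the 200-bit
   low/high grouping.
4. **Phylogeny** — p-distances, neighbor joining, column-resampling
   bootstrap, Newick export.
5. **Assay reductions** — DSC crystallinity, residual activity, total
   product release.

## Classification model

A query is aligned globally (Needleman–Wunsch, BLOSUM62, affine gaps: a gap
of length $k$ costs $10 + 0.5k$) to an annotated reference. Annotated
reference positions are transferred through the alignment; a reference
position opposite a gap is reported *unalignable* rather than forced (the
real type III enzymes genuinely lack an equivalent of the reference's
subsite-I glutamine on loop 2, and the pipeline reproduces exactly that as
an unalignable position).

The gate predicates are conjunctive:

| type | gates |
|------|-------|
| I    | exactly 1 disulfide pair, extended loop absent |
| IIa / IIb | 2 disulfide pairs at canonical positions, extended loop present |
| III  | lipase box `GHSQG`, clamp absent, ≥2 pairs all non-canonical, loop-3 delta ≥ +3 |

Among gate-passing templates the highest fraction of matching scored
residues wins; IIa versus IIb is decided *only* by scored residues in
subsite II and the extended loop, since the literature separates them by
composition rather than by an enumerated rule. A tie or an empty passer set
yields `unclassified` — a first-class outcome, mirroring the fact that the
type III founders could not be placed in the old scheme. The type III gate
is conjunctive because its defining features are presented as co-occurring;
the template file (`inst/extdata/type_templates.json`) is editable for
exploratory "k-of-n" use.

Structure evidence, when coordinates are supplied, always supersedes
sequence inference: the catalytic serine comes from the geometric triad and
disulfide pairs from SG–SG distances.

## Tunable parameters

* **Disulfide SG–SG threshold, 2.3 Å** (canonical bond ≈ 2.05 Å): permissive
  enough for refinement noise, tight enough to exclude free cysteine pairs.
* **Triad thresholds, 3.5 Å** for Ser OG–His NE2 and His ND1–acid oxygen:
  hydrogen-bond range; among candidate triples the minimal distance sum wins,
  a deterministic stand-in for visual identification. Glutamate is accepted
  as the acid with a flag.
* **Superposition, 5 cycles / 2 Å rejection**: least-squares (SVD/Kabsch with
  reflection correction); each cycle drops *all* pairs deviating by more than
  the cutoff at once, then refits — the batch-rejection reading of the usual
  structure-viewer `align` protocol.
* **Canonical-disulfide tolerance, ±2 alignment positions**: "same position"
  is judged qualitatively in the literature; a small window makes the rule
  testable.
* **Hit threshold 100 bits (strict >) and group boundary 200 bits**: the
  boundary value 200.0 itself joins the high group, a decision the interval
  notation "[<200] / [>200]" leaves open.
* **Identity denominator**: matches over aligned columns (not
  shortest-sequence length); conventions differ, so the convention is stated
  here and reports carry it.
* **Signal peptides**: cleavage lengths are caller inputs (`trim_signal`);
  the structure-alignment workflow convention is 40 N-terminal residues.
  Author residue numbering is preserved through trimming via a numbering
  offset so reports can cite residues as the field does (S156, D206, H236).

## The profile HMM

`build_profile` is a deliberately simple formulation: columns with gap
fraction < 0.5 become match states; emissions and transitions use Laplace
(+1) pseudocounts; insert states emit from the null model; the null model is
the overall residue frequency of the seed alignment (pseudocounted); scoring
is glocal (Begin through all match states to End, with insert/delete
detours) in log space, reported as log2 odds. It makes no claim of numeric
parity with HMMER bit scores — the mining thresholds are exercised on this
model's own scale. Forward and Viterbi are both available; forward ≥ Viterbi
is a tested invariant, and forward probabilities are verified against
exhaustive path enumeration on toy models. X residues score with zero
log-odds contribution (their emission cancels against the null), a
convenience for partially determined sequences.

One consequence of the MSA-frequency null worth knowing: on tiny,
compositionally skewed seed alignments the null can be far from uniform, so
absolute bit values on toy fixtures are only meaningful relative to that
null. The accession identifiers of the real comparison proteins are carried
in data files, never in code, since one printed accession
("A0K8P6T7") does not match the canonical accession format and may need
correcting by the user.

## The synthetic study set

Real deposited records (a 1.16 Å crystal structure and database sequences)
are not redistributable inputs of this package, so every stage runs on a
seeded synthetic study set that plants the *published feature geometry*
exactly; all stand-ins are labelled `synthetic_*`:

* a **IIb-like reference** (320 aa) with the literature's IsPETase-style
  numbering for the planted features: clamp Y87/W185, subsite-II serine S93,
  loop-2 glutamine Q119, lipase box G158–G162 with S160 and M161, D206,
  H237, canonical disulfides 203–239 and 273–289;
* **type I and IIa archetypes** derived from it (extended-loop deletion and
  one disulfide removed for type I; IIa-scored subsite letters for IIa);
* a **type III archetype** derived by an edit script that reproduces the
  published numbering offsets (87→88 giving T88, 160→156 giving S156 and
  Q157, 206→206, 237→236) together with the five-residue loop-2 deletion
  and five-residue loop-3 insertion (carrying L163), cysteines moved to
  64–126 and 273–276, and the clamp anchor mutated to threonine;
* a **PmC-like stand-in** derived from the type III archetype by an *exact
  count* of substitutions (120 of 319 unprotected sites) so the pairwise
  identity is 62.4% of aligned columns by construction — deterministic
  across seeds because the two sequences are equal length and the alignment
  stays gapless;
* **toy coordinate files**: an extended Cα trace with side-chain
  pseudo-atoms placed so the triad (OG–NE2 3.0 Å, ND1–OD2 2.8 Å) and
  disulfide (SG–SG 2.05 Å) geometry holds exactly. These are geometric
  scaffolds, not folds — sufficient because every structure operation in the
  package is a local-geometry predicate.

Two deliberate deviations from the real system, made once and documented
here:

* **Background divergence.** The derived type III archetype is mutated at
  rate 0.35 outside protected feature neighborhoods (roughly 60% residual
  identity), milder than the real family's <34% identity to types I/II. The
  reason is methodological: this package anchors position mapping in
  *sequence* alignment, whereas the original analysis anchored it in
  *structure* superposition, which tolerates far deeper divergence. At the
  fixture's divergence the sequence anchor is reliable; at realistic
  divergence it would not be, and a structure-based correspondence would be
  required (see Limitations).
* **The second clamp anchor.** Reproducing *every* published author number
  simultaneously would require adjacent insertions and deletions that any
  affine-gap aligner rightly merges; the edit script therefore keeps indels
  well separated, which lands the aromatic second anchor at query position
  186 rather than the published 180. The anchor's *role* (aromatic, opposite
  a threonine, clamp absent) is unaffected.

Random fixture residues are drawn from a cysteine-free background alphabet
so disulfide evidence stays entirely under generator control; mutation draws
likewise never introduce cysteines. Planted features are protected with ±2
flanks, the way real motifs are conserved. Passing tests on this set show
the *logic* is right — they do not show robustness to real-data divergence,
low-complexity regions, or fragmented inputs.

## Numerical choices

* Alignment traceback ties break diagonal > up > left; NJ label ties break
  lexicographically (taxa are sorted before tree building); both make every
  output byte-reproducible.
* The linear-gap case of the aligner is verified against an independent
  plain DP oracle, and the affine case against an independent
  implementation (Biostrings) on random pairs.
* Negative NJ branch lengths are clamped to zero with the clamped deficit
  recorded as an attribute.
* p-distance (1 − identity over mutually ungapped columns) is the default
  tree distance; a Kimura protein correction is available behind a flag
  because the settings of the original tree program are not stated.
* Crystallinity values outside [0, 100] warn rather than error (DSC
  baselines can produce slight excursions) and carry a `nonphysical`
  attribute.
* PDB reading keeps MODEL 1 only and the highest-occupancy alternate
  location per atom (ties by altloc letter).

## Problem sizes used by the packaged checks

The test suite and the acceptance script run entirely on the synthetic
study set: 300–320-residue sequences, profile HMMs up to 320 match states,
alignments of up to ~10 sequences, NJ recovery on up to 8 taxa, 200–1000
bootstrap replicates, 50 mutation replicates per rate for the
classification-accuracy curve, and toy HMMs (≤3 match states, two-letter
emission support) for the enumeration oracles. These sizes were chosen as
the smallest at which every property is informative.

## Known limitations

* Sequence-anchored mapping degrades below roughly 40% identity; the real
  type III vs type II comparison sits below that, where the original
  analysis used structural superposition. The `superpose` operation is
  provided, but correspondence generation from structure alone is not.
* The profile HMM is not HMMER: no Dirichlet mixture priors, no local
  alignment mode, no E-values; bit scores are comparable only within this
  implementation.
* The progressive MSA is a plain guide-tree scheme (UPGMA + profile–profile
  Needleman–Wunsch, gaps never removed); it is not consistency-based and is
  not intended beyond ~200 sequences. Precomputed alignments can be
  imported instead.
* mmCIF structures, nucleotide inputs and flat-file database formats are out
  of scope; users supply FASTA/PDB.
* Subsite membership tables are transcribed defaults and explicitly
  provisional; they live in editable TSVs, not in code.
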