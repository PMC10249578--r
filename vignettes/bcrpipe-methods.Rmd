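---
title: "Isotype-resolved BCR repertoire analysis with bcrpipe: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotype-resolved BCR repertoire analysis with bcrpipe: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcrpipe)
```

## Scope

bcrpipe implements an isotype-resolved B-cell receptor (BCR) repertoire
analysis for antibody amplicon data in which both the variable domain and
the 5' of the constant region are sequenced in the same molecule — the
setting of single-/few-cell sorted memory B cells and bulk long-read tissue
repertoires. The pipeline covers germline reference modelling, V(D)J gene
assignment with junction extraction and productivity calling, isotype
assignment from the constant fragment, region-resolved silent/replacement
(S/R) mutation profiling, CDRH3 clonotyping, germline-rooted lineage trees
with intra-clone class-switch detection, detection of two receptor-revision
processes (VH replacement and secondary lambda-locus rearrangement), CDR3
biophysical descriptors, and the repertoire statistics used to compare
compartments. A simulator with complete per-read ground truth provides the
test bed for every stage.

## Germline model and locus geometry

A `locus_model` holds germline V/D/J alleles of IGH, IGK and IGL plus the
nine IGH constant genes. Two pieces of geometry drive all mechanistic
reasoning:

* every allele carries a rank P (1 = most 5', i.e. distal/upstream within
  its locus and segment class); `relative_position()` compares genes by P.
  VH replacement requires the invading gene upstream of the invaded one,
  and a same-chromosome secondary lambda rearrangement requires the
  secondary V upstream of the primary V;
* the constant genes are ordered IGHM, IGHD, IGHG3, IGHG1, IGHA1, IGHG2,
  IGHG4, IGHE, IGHA2. Class-switch recombination (CSR) is deletional, so a
  cell can only switch to genes later in this order.

Locus positions are loaded as data (a locus-table TSV), not hard-coded:
reference releases differ, so positions are the caller's statement about
their reference. Coordinates are 0-based and half-open in all external
files; FASTA input may be IMGT-gapped (`.`), in which case region offsets
are recomputed on the de-gapped sequence.

The package ships a small synthetic demo reference
(`demo_locus_model()`) so that every example and test runs without any
download. Its V genes are generated from a per-locus common ancestor with
~12% divergence between families and ~5% within a family — the realistic
regime in which a hybrid (revised) V region still aligns end-to-end against
the invader's germline. Each heavy V gene carries the cryptic
recombination-signal heptamer CACAGTG at the 3' end of CDR2, where cryptic
heptamers concentrate in real IGHV genes. The reference is synthetic: gene
names and locus ranks are realistic, sequences are invented.

## Alignment conventions

All alignments use match +5 / mismatch −4 / gap open 10. Two gap-extension
settings coexist, deliberately:

* `align_pair()` and the revision module's crossover analysis use gap
  extension 0.5 (EMBOSS Needle-like), because percent similarity —
  identical columns / alignment length × 100, gap columns counted in the
  denominator — is defined under that convention;
* gene assignment uses gap extension 4. With extension 0.5 a local V
  alignment can bridge from the V across the junction into J or C territory
  through long, cheap gaps, which corrupts the region coordinates of
  receptor-revised reads. Immunoglobulin V genes do not contain long indels
  relative to reads, so a stiffer extension is the correct prior for
  assignment.

V and J are assigned by best local alignment score against each candidate
allele (ties broken by lower P, then name); D by the best ungapped match of
at least 8 nt inside the junction interior. The CDR3 is delimited by the
conserved V-end cysteine codon and the J-frame tryptophan (heavy) or
phenylalanine (light) codon; `junction` includes both anchors and `cdr3_aa`
is the translated interior. Anchor positions are mapped through the
alignment; positions outside the locally aligned region are extrapolated
colinearly, so a terminal mismatch clipped by the local aligner does not
lose the anchor.

A rearrangement is productive iff both anchors are intact, the junction
length is 0 mod 3, and no in-frame stop occurs from the first read position
in the V frame through the J end; the failure reason is recorded with
precedence missing_anchor > frameshift > stop_codon. The simulator applies
the identical rule to its final (mutated) sequences, so truth and
annotation are compared on the same definition.

Mutation profiling re-aligns the read's V region to its assigned germline
and classifies every aligned mismatch S/R by codon translation in the
germline frame (all mutations in a codon applied jointly) and FR/CDR by the
germline region boundaries. The percent of total mutations uses the
aligned V length as denominator — the aligned-portion convention; the full
germline length is not used because local alignments may not cover it.
R/(R+S) is reported as 0 for unmutated sequences. Counts from alignments
under 50 nt are flagged unreliable.

## Clonotyping

Clones are built on the CDRH3 amino-acid sequence: normalized Levenshtein
distance (edit distance divided by the longer length), single-linkage
hierarchical clustering, tree cut at 0.05. The cut is inclusive — a pair at
exactly the threshold shares a clone — and single linkage makes the result
exactly the connected components of the threshold graph, hence invariant to
input order. Identical V/J is deliberately **not** required within a clone:
receptor revision produces clone members with different V genes, and a
V-identity constraint would hide exactly the events the revision module
looks for. A `strict_vj = TRUE` mode splits clones by gene-level V/J for
users who want classical clonotypes. Normalization by the longer length is
a package choice (a raw edit-distance cut of 0.05 would be meaningless);
both it and the inclusive boundary are configuration, not claims about any
particular published pipeline.

## Lineage trees

Per clone, members sharing the dominant variable-domain length are placed
on a scaffold (assigned germline V + member consensus beyond the V) and a
maximum-parsimony tree rooted at the germline is searched: exhaustively
over all topologies for up to 6 members (7 tips, 945 trees), by parsimony
ratchet above that. The exhaustive bound is 6 rather than larger because
topology count explodes combinatorially (9 tips already mean 135,135
trees) with no gain at tested clone sizes. Ancestral sequences use Fitch
state sets with a germline-anchored top-down pass: the root state **is**
the germline, and a child keeps its parent's state whenever the parent
state is in its Fitch set. Every edge then carries the exact mutations
separating parent from child, mutations along any root-to-leaf path sum to
the leaf's differences from the germline, and internal nodes whose
incoming edge carries no mutation are collapsed — inferred intermediates
survive only where at least two descendants share a mutation. Trees export
as Newick (branch length = mutation count, NHX-style edge annotations)
plus a JSON mutation sidecar.

Intra-clone CSR is reported for every isotype pair co-occurring in a clone,
directed by the constant-gene order (never upstream). When a lineage tree
with node isotypes is available, clones whose tree would require an
upstream switch along some parent-to-child edge are flagged inconsistent.

## Receptor-revision detection

**VH replacement.** Candidate groups are sequences with *identical* CDR-H3
amino-acid sequence but different V calls (replacement leaves DJ — hence
CDR3 — unaltered while rewriting the V 5' of a cryptic heptamer). Within a
group, each read is tested as a hybrid of its own V call (candidate
invader, 5') and a partner's V call (candidate invaded gene, 3'):

1. the read's V region — from the V start to the junction cysteine, not
   merely the locally aligned extent, which stops at the crossover for
   strongly diverged gene pairs — is globally aligned to both germlines,
   giving per-position match indicators;
2. the crossover is the changepoint maximizing prefix agreement with the
   invader plus suffix agreement with the invaded gene. Sliding 15-nt
   windows vote on local allegiance, but windows where the two germlines
   are locally identical abstain, so the acceptance requirement is a
   cumulative advantage of at least one informative position on each side.
   Changepoint ties — flat stretches where the germlines agree — are
   resolved toward the nearest cryptic heptamer, the biologically
   distinguished point;
3. a cryptic heptamer (CACAGTG, ≤1 mismatch, CAC core intact, after Itoh
   et al.'s convention) must lie within ±10 nt of the crossover on the
   invaded germline;
4. the invader must be strictly upstream of the invaded gene.

The evidence score is the summed allegiance advantage normalized by the V
length. A read can never be called with a downstream invader: the test is
only performed in the upstream direction (a hard invariant, also asserted
in the test suite).

**Secondary lambda rearrangement.** A cell (or, in bulk mode, a lambda
clonotype group used as a documented proxy for a cell) yields an event iff
it carries ≥2 lambda chains with the same J family, different V genes, and
at least one unproductive chain. Locus feasibility on the same chromosome
requires the secondary V upstream of the primary; pairs failing this are
still reported, flagged `locus_feasible = FALSE` (the
alternative-chromosome interpretation). Kappa chains are ignored.

**Frequencies.** The per-sample frequency is revised sequences / qualifying
sequences (heavy for VH replacement, lambda for the lambda assay), on the
unique-sequence set. Published numbers of this kind do not state whether
events or sequences are counted; this package counts the revised sequence
only (the read carrying the hybrid V, or the secondary rearrangement), so
the estimator targets the per-sequence event rate.

## CDR3 descriptors

Kidera factors — ten orthogonal physicochemical descriptors per amino
acid — are averaged over CDR3 residues; the 20×10 table is packaged with a
frozen MD5 checksum and `kidera_table()` refuses a silently altered copy.
Group-level structure is summarized by PCA on the 10-dimensional vectors
(centered; standardization off by default since the factors are already
variance-normalized) with signs fixed by forcing the largest-magnitude
loading of each component positive, and per-group medians/IQRs of PC1/PC2.
Secondary-structure preferences assign each residue to the argmax of its
Chou–Fasman helix/strand/turn propensities (α: A,R,Q,E,H,K,M; β:
C,I,L,F,T,W,Y,V; coil: N,D,G,P,S; the single tie, cysteine, breaks toward
strand); proportions sum to 1 by construction. The residue→class mapping is
a swappable table — no claim is made that any particular published analysis
used exactly this scale.

## Statistics

* `proportion_ztest()`: pooled two-sample proportion z-test,
  p̂ = (n_T p_T + n_B p_B)/(n_T + n_B),
  Z = (p_T − p_B)/√(p̂(1−p̂)(1/n_T + 1/n_B)), two-sided normal p-value;
  degenerate pooled proportions return a flagged p = 1.
* `permutation_ratio_test()`: an observed two-group statistic (default:
  ratio of group means) against a null from `n_perm = 1000` random label
  reassignments. Two-sidedness is absolute deviation from the null mean,
  and the empirical p uses the add-one correction
  (1 + #{more extreme})/(n_perm + 1), so p is never 0. Both conventions are
  package choices where the underlying method family leaves them open.
* `bootstrap_ci()`: percentile bootstrap (n = 1000, 95%) — the plain
  percentile interval, matching error-bar usage, not BCa.
* `usage_tables()` and `repertoire_summary()` produce the gene-usage,
  gene-pairing, gene×isotype and per-isotype summary tables (isotype
  distribution, % unproductive, % total V mutations, R/(R+S)), with z-tests
  across two compartments reported raw and Benjamini–Hochberg adjusted —
  whether multiplicity correction is wanted across a gene panel is left to
  the reader, so both are printed.

## The simulator: what it emulates, and what it does not

`simulate_repertoire()` generates cells in clones whose sizes follow a
truncated power law (default exponent 2.5, max 50 — a heavy-tailed
clone-size law with roughly 60% of cells in non-singleton clones). Each
cell emits a heavy read (full V, N-inserted trimmed D, trimmed J, 60 nt of
its constant gene — enough that isotype assignment is exercised but not
trivial) and a light read; clone members share both founder junctions.
Founder isotypes follow a class-switched memory-like prior (IgG1 35%, IgA1
18%, IgM 15%, IgG2 14%, ...), and each member switches downstream with
probability 0.2. Cells emit an additional frameshifted or stop-containing
heavy rearrangement with probability 0.08. SHM is i.i.d. per base (default
0.02/base, CDR1/2 ×3, transitions 50%) — there is no hotspot-motif model;
the i.i.d.-with-CDR-multiplier design gives the S/R and FR/CDR structure
that the profiler must recover without claiming motif realism.

SHM is confined to the V region: the junction and J are spared. This is a
deliberate simplification with a methodological reason: the revision
detector and the clonotype-recovery checks group sequences by *identical*
CDR-H3, and junction mutations at the configured rates would make the
intended detection targets mostly unobservable (at 0.02/base the
probability of an intact 39-nt junction is ≈0.45). Consequences for
interpretation: passing tests show the detectors work when clonal identity
of the CDR3 is exact; on real data, SHM inside the CDR3 will fragment
same-CDR3 groups and the measured sensitivities are upper bounds.

Receptor-revision events are simulated mechanistically: a VH replacement
picks the cryptic heptamer nearest the CDR2 end of the founder V (the
simulator verifies it exists), a uniformly chosen upstream invader, and
rewrites the read's V as invader-5' + founder-3'; a secondary lambda event
adds an unproductive lambda read with the same J gene and a different,
preferentially upstream V. Draws whose founder V has no upstream neighbor
are infeasible on the reference and are skipped with a warning — so the
realized event fraction is systematically below the nominal rate (about
10% of draws on the demo reference, whose most-distal gene founders cannot
be invaded), and sibling/unproductive emissions enlarge the sequence
denominator further. Parameter-recovery checks therefore compare the
detector against the *realized* event fraction recorded in the truth
table, with the configured tumor>blood ordering asserted on top. When
every member of a clone draws a replacement, one unrevised sibling read is
emitted so the event remains detectable in principle; real repertoires
offer no such guarantee, and fully-revised clones would be silent there.

Not modelled: sequencing error, UMI structure, paired-end reads, indel
SHM, allele polymorphism, kappa-locus editing.

## Problem sizes and numerical choices

The test suite and the acceptance script choose sizes that make the
statistical checks sharp while staying lightweight: revision-recovery
cohorts of 5 tumor-like + 9 blood-like samples at 2,000 cells each in the
test suite (3+4 samples at 1,000 cells in the acceptance script, which
also reports detection sensitivity and calibration figures); permutation
calibration over 2,000 replicates of n = 1000 permutations; bootstrap
coverage over 500 replicates; annotation recovery on ≥1,000 reads.
Numerical conventions collected in one place: inclusive clonotype cut;
add-one empirical p; percentile bootstrap; PCA sign fixing by
largest-magnitude loading; assignment tie-breaks by locus rank P, then
name; D-call minimum ungapped match 8 nt; isotype call margin 5 score
units, else `unassigned`; mutation counts flagged unreliable under 50
aligned nt.

## Known limitations

The demo reference is synthetic and small; absolute alignment scores and
score floors are tuned to full-length, high-quality amplicons and would
need revisiting for fragmented reads. Lineage reconstruction assumes
equal-length members (no indel SHM). The bulk-mode lambda proxy (clonotype
groups standing in for cells) is an explicit design decision, not an
inference about how any published bulk estimate was computed, and its
output is kept separate from single-cell calls. Detection of VH-replacement
footprints from isolated sequences (without a same-CDR3 partner) is out of
scope.
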