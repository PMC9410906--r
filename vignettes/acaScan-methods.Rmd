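---
title: "Methods: models, parameters and design choices in acaScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in acaScan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and biological setting

Anti-CRISPR (*acr*) genes on phages and mobile genetic elements are commonly
co-transcribed with a downstream *aca* gene encoding a small helix-turn-helix
autorepressor. The Aca protein binds inverted-repeat (IR) operators within the
operon's promoter and damps *acr* expression. acaScan implements the
computational side of characterising such loci: finding Aca-family homologs,
reconstructing their operon and neighborhood context, classifying their
association with *acr* genes, and dissecting their promoters (σ70 core
elements, IRs, shared motifs), with family-level statistics on top. A
synthetic-genome generator with a ground-truth manifest makes every stage
testable in isolation and end to end.

# Family profiles and scanning

A family is modelled as a position-specific log-odds profile over the 20
amino acids. For column $k$ with observed residue frequencies $c_{k,a}/n_k$
($n_k$ = non-gap count), the scored frequency is the pseudocount blend

$$f_{k,a} = \frac{c_{k,a}/n_k + \lambda\, b_a}{1 + \lambda},
\qquad S_{k,a} = \log_2 \frac{f_{k,a}}{b_a}\ \text{(bits)},$$

with $\lambda = 1$ and uniform background $b_a = 1/20$ by default. Working on
relative frequencies (rather than raw counts) makes the profile invariant to
sequence copy number, so over-represented seed sequences do not sharpen the
model artificially. Columns that are gapped in more than half the seed
sequences are dropped. Full profile-HMM machinery (insert/delete states,
forward/Viterbi) is deliberately out of scope: Aca proteins are short
single-domain proteins, and ungapped window scanning keeps two properties
exact that the test suite leans on — the consensus is provably the maximal
scoring sequence, and scores are additive per column.

Scanning slides the profile ungapped along every CDS translation and keeps
the best window (proteins shorter than the profile slide inside it, yielding
coverage < 1). Because no public database is involved, e-values are
meaningless here; instead per-family bit-score thresholds are **calibrated
empirically**: all ORFs of a background-only synthetic genome are scored, and
the threshold is the 99.9th percentile of per-CDS best scores plus a 10-bit
safety margin. The margin absorbs the sampling noise of an extreme-tail
quantile estimated from a few hundred null scores; true family members score
hundreds of bits above the null (a 70-aa reference at 20 % divergence still
scores ≈ 175 bits against a ≈ −15 bit null maximum), so the margin costs no
sensitivity. Setting it is a specificity decision, not a tuning knob: during
development a 57-aa background ORF at 0.52 coverage cleared a 2-bit margin by
2 bits, which motivated the wider default.

Pairwise identity uses Needleman–Wunsch global alignment (match +1, mismatch
0, linear gap −1) through `Biostrings::pairwiseAlignment`. Identity is
matches over columns of the mutually aligned span (terminal overhangs
excluded, internal gap columns counted); the alignment is computed in a
canonical argument order so identity is exactly symmetric. Coverage — the
fraction of the reference covered by aligned residue pairs — feeds the strict
`> 0.4` filter used by the family summaries. Greedy clustering follows the
CD-HIT idea (longest first, join the first representative at ≥ threshold,
else found a cluster) with one algorithm for both alphabets: protein at 0.8,
nucleotide at 0.9.

# Operons, neighborhoods and association

Operons are maximal runs of same-strand CDS with at most 55 strictly
intervening bases between consecutive features (`next_start − prev_end − 1`
on 1-based inclusive coordinates; overlapping CDS merge). Two choices the
gap rule alone does not settle: an intervening opposite-strand CDS breaks a
run even when the flanking same-strand genes are within the gap
(read-through across an opposing gene is implausible, and this is the common
operon heuristic), and the operon leader is the 5′-most member *on the coding
strand* — first member for `+`, last for `−`. Internally all coordinates are
1-based inclusive throughout, the native convention of IRanges/GRanges and
GFF3; adopting it end to end removes the conversion layer rather than adding
one.

Each *aca* hit's neighborhood is its CDS ± 5000 bp, clipped at contig edges,
with membership by ≥ 1 base overlap. Association is hierarchical: a labelled
*acr* in the same operon ⇒ `acr_associated`; else anywhere in the
neighborhood ⇒ `proximal`; else `solo`. Any operonic co-membership counts as
associated regardless of gene order (the order is recorded, so stricter
filters can be layered on). The reported class is the best among linked acrs
(`known` > `candidate` > `putative`). The association network adds, per
associated record, one count to the edge between the aca family and each
*distinct* linked acr family, so total edge weight equals the number of
distinct-family links — an invariant the tests check.

# Promoter dissection

**Extraction.** 400 bp upstream of the operon leader, reverse-complemented
for `−` operons so the sequence always reads 5′→3′ on the coding strand with
position −1 adjacent to the start codon; shorter clipped regions are flagged
rather than discarded.

**σ70 core elements.** A transparent consensus-matrix stand-in for
closed-source promoter predictors: hexamer log-odds matrices from TTGACA and
TATAAT with consensus-base probability 0.7 (match ≈ +1.49 bits, mismatch
≈ −1.32 bits), spacer 15–19 bp with a penalty of 0.5 bits per base of
deviation from the 17 bp optimum, searched within the 3′-most 150 bp (where
such elements concentrate upstream of *acr* start codons). Only the relative
placement of IRs versus the core matters downstream, which this scanner
resolves reliably. Ties break to the 3′-most −10, then the longest spacer —
a fixed, documented rule rather than an arbitrary argmax. Significance, when
wanted, comes from an empirical null (`calibrateCoreThreshold()`, 99th
percentile of background scores); the maximal-score call itself is always
returned.

**Inverted repeats.** An IR is a pair of equal-length arms whose left arm
differs from the reverse complement of the right arm at ≤ `maxMismatch`
positions (default 1), with arm length 4–10 and spacer 0–12 by default (the
tools behind published IR screens do not state their bounds; these defaults
are declared, not reproduced). All candidates are enumerated; only *maximal*
IRs are reported. Maximality is concretised as: no single base-pair extension
— outward (arms grow away from the spacer) or inward (arms grow into the
spacer, spacer −2) — stays within the arm/spacer/sequence/mismatch bounds.
This suppresses nested sub-IRs deterministically. The detector is validated
by exact set equality against a brute-force enumerator over hundreds of
random sequences and five parameter settings, and by a reverse-complement
mirror symmetry property. Classification relative to a core call: `IR1` if
the IR span overlaps the −35…−10 span by ≥ 1 base, `IR2` if disjoint,
`unclassified` without a core call. The default search window is the
3′-most 150 bp (`fullRegion = TRUE` lifts it).

**Motif discovery.** A site-sampling Gibbs sampler stands in for EM-based
motif discovery: one sequence's site is resampled from the posterior given
the motif built from the others (pseudocount 0.25 per base, uniform
background by default), on both strands. ZOOPS is the default mode (a
sequence may hold no site; prior 0.9), since not every promoter need contain
the operator; OOPS is available when every sequence is known to carry one. A
deterministic phase-shift move (±1, ±2, every 10 sweeps) removes the phase
wander Gibbs samplers are prone to, and each restart ends with a
deterministic argmax polish; the best of 4 restarts × 80 sweeps by (total
information content × site count) wins. Those sizes are convergence defaults:
a strong planted signal (18-mer, ≤ 2 substitutions per site, 20 sequences of
150 bp) locks in well before 80 sweeps. Determinism is part of the contract:
all randomness flows through one integer seed, iteration order is fixed, and
two runs with the same seed produce identical motifs. Because both strands
are searched, a motif may be recovered in reverse-complement orientation;
consumers compare against both. Motif significance is by empirical contrast
(information content against background-only runs), not e-values; motif
comparison maximises mean per-column Pearson correlation of frequency
columns over all offsets (≥ 4 aligned columns) and both orientations, with
zero-variance column pairs scored 1 if identical, else 0.

# Family statistics

Hits filtered to coverage strictly > 0.4 are split into Acr-associated vs
solo (proximal excluded by default — the contrast is binary); per group the
mean and t-distribution 95 % CI half-width of protein length and
identity-to-reference are reported. The two-sample test is Welch's
unequal-variance t-test with Welch–Satterthwaite degrees of freedom —
implemented from the formulas and cross-checked against `stats::t.test` to
1e-9 — because small, unbalanced per-family groups make the equal-variance
assumption untenable; "unpaired t-test" without qualification is read as
Welch and flagged here. Distances for trees are `1 − identity` from the
pairwise global alignments (a documented stand-in for a multiple-alignment
pipeline: neighbor joining only needs a distance matrix, and this preserves
the qualitative deliverable — family grouping — with exactly testable
machinery). Trees are standard Saitou–Nei neighbor joining via `ape::nj`,
exact on additive matrices (verified on random binary trees by topology and
path-length recovery to 1e-9), with negative branch-length estimates clamped
to zero and flagged. Approximate-ML trees, bootstrap and tree rendering are
out of scope.

# The synthetic data generator

The generator emulates what the analysis consumes, not phage biology.
Background DNA is i.i.d. per base with P(G) = P(C) = GC/2 — the simplest
null for intergenic sequence (real MGE regions have composition structure,
codon bias and repeats that this does not model; the generator's role is
planted-truth recovery, so passing tests demonstrate algorithmic
correctness, not performance on real genomes). Background genes are random
ORFs (ATG…stop, 50–300 aa, no internal stops) giving the scanner realistic
negatives. Planted cassettes are assembled in a forward frame — 400 bp
promoter, acr gene(s), configured intergenic gap, aca gene — and placed on a
random strand; family members derive from per-family random reference
proteins by per-site substitution (`member_sub_rate`, `solo_sub_rate`), so
identity contrasts between groups are constructible by design.

The planted promoter lays out, 5′→3′: optional IR2, background, −35,
17 bp spacer, −10, and 11 bp before the start codon. The first IR's left arm
is anchored at the −35 start and its right arm is written as the exact
reverse complement into the core spacer, so IR1 overlaps the core promoter
by construction — the configuration described for Aca operators; IR2 reuses
the same arm consensus upstream of the core. `ir_mismatches` substitutions
are then applied to each right arm; `mutation_rate` core-hexamer
substitutions are applied after IR planting (and may therefore add IR
mismatches, which is documented behaviour). Geometry requires
`2·arm + ir_spacer ≤ 6 + spacer`; violations raise a footprint error, and
contigs that cannot hold their elements with 200 bp minimum spacing raise a
capacity error rather than silently overlapping.

One placement rule matters for ground truth: operon cassettes (which carry
*acr* genes) and solo-aca cassettes are placed on **disjoint contig sets**
(≥ 2 contigs required when both are requested). Without this, a "solo" aca
can legitimately fall within 5 kb of another cassette's acr, and the
pipeline's correct `proximal` call would contradict the manifest — the
generator must enforce what "solo" asserts.

All randomness flows from the single config seed; nested stages derive
sub-seeds by a documented hash of (seed, stage label) (`deriveSeed()`), so
no two stages share a stream, nothing touches the caller's RNG state, and
identical seeds give byte-identical FASTA/GFF3/JSON outputs.

# Numerical and degenerate-input conventions

- Score/correlation tie-breaks are always fixed and documented (core scan:
  3′-most −10 then longest spacer; IR sort: arm desc, mismatches asc,
  position asc, spacer asc; motif comparison: forward before reverse, then
  smallest |offset|; profile consensus and motif consensus: alphabetical).
- Floating-point comparisons in tie-breaking use a 1e-12 guard; invariants
  are asserted to 1e-9 in tests.
- Empty inputs return empty, well-typed tables (empty genome → valid empty
  report); genuinely impossible requests (capacity, footprint, ragged
  alignments, unknown CDS ids, asymmetric or negative distance matrices)
  raise errors.
- A leader flush with a contig edge yields an empty, flagged promoter, not
  an error; shorter-than-requested promoters are flagged `clipped`.
- Welch's test refuses the fully degenerate case (both variances zero and
  equal means); identical non-constant groups return t = 0, p = 1.

# Problem sizes used by the shipped tests

The suite exercises the pipeline at deliberately desk-scale sizes chosen to
make the properties sharp rather than the datasets large: communities of
4–10 contigs of 12–25 kb with 2–5 operons, 2–5 solo acas and 8–50 background
ORFs; calibration genomes of 120–300 background ORFs; 200 random 150-mers
across five IR parameter settings; 10³ random operon layouts; 50 Gibbs
recovery seeds (20 × 150 bp promoters, 18-mer, ≤ 2 substitutions per site)
with paired background controls; 50 random additive trees (4–12 leaves); 10³
random Welch inputs. The acceptance script mirrors these conditions and
reports recovery percentages, information contents and discrepancies as
JSON.

# Known limitations

- The i.i.d. background and random-ORF negatives understate the difficulty
  of real genomic sequence; calibrated thresholds would need re-calibration
  against a realistic background for use on real data.
- Ungapped profile scanning cannot model indels within a family; strongly
  gappy families would need the out-of-scope profile-HMM extension.
- Identity-based distances compress at high divergence (no multiple
  alignment, no substitution-model correction); the NJ tree is a grouping
  device, not a publishable phylogeny.
- The σ70 scanner knows only the canonical −35/−10 consensus; extended −10
  promoters and alternative sigma factors are not modelled.
- Motif discovery assumes a single shared motif of fixed width per run; the
  width sweep (`sweepMotifWidth`, 10–24 by IC per column) mitigates but does
  not remove the fixed-width assumption.
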