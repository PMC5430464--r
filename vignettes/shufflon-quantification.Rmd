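---
title: "Quantifying whole-shufflon structural variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying whole-shufflon structural variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shufflonq)
```

## The biological problem

Shufflons are multiple DNA inversion systems of IncI-family conjugative
plasmids.  A shufflon locus consists of one or more invertible segments
lying between the 3' constant region of the *pilV* gene and the *rci*
recombinase gene.  Each segment is bounded by short (~20 bp) imperfect
inverted repeats; the Rci tyrosine recombinase recombines any pair of these
sites and thereby inverts everything between them.  Because most segments
carry two oppositely oriented partial *pilV* ORF 3' ends, rearrangement
swaps the C-terminal part of the PilV tip adhesin, which sets the
lipopolysaccharide receptor specificity of conjugative transfer.  A clonal
culture therefore carries a *population* of plasmid structures, and the
quantity of interest is the abundance distribution over all possible
whole-shufflon arrangements in a single isolate.

## The arrangement model

We model the locus as an alternating skeleton

```
pilV_anchor  J0  S1  J1  S2 ... Sn  Jn  rci_anchor
```

where `S_k` are repeat-free segment bodies and `J_i` are junction elements
composed of the annotated inverted-repeat sites.  An *arrangement* is a
permutation of the `n` segments together with an orientation sign per
position.  For a locus whose segments all carry two ORF ends the number of
distinct whole-shufflon structures is

\[ N(n) = 2^n \, n! \]

(2, 8 and 48 for n = 1, 2, 3).  Two details deserve emphasis:

* **Why block reversals generate the whole space.**  An inversion bounded
  by the left site of position p and the right site of position q reverses
  the block p..q and flips each of its orientation signs.  Signed block
  reversals generate the full signed symmetric group, so the
  breadth-first closure of the reference state under single inversions
  (`inversion_closure()`) reaches exactly \(2^n n!\) states.  The package
  uses this closure as an independent oracle for the direct enumeration.
* **One-ORF segments.**  The closed form counts *sequence* structures for
  two-ORF loci only.  A segment carrying a single ORF end (such as segment
  D of the R64 IncI1 plasmid) still has two sequence-level orientations but
  only one of them presents an ORF to *pilV*; the published variant count
  is therefore \(2 \times \#\text{two-ORF} + 1 \times \#\text{one-ORF}\)
  (`count_pilv_variants()`, 7 for the R64 configuration).  For mixed loci
  we enumerate exhaustively and deduplicate by sequence rather than trust
  the formula.

### Repeat layout

Inverted-repeat sites flank *each segment end* (2n sites for n segments; a
3-segment locus has six).  Because the ~20-bp consensus is not palindromic,
a single shared junction repeat cannot read as consensus for both of its
neighbouring segments; interior junction elements are therefore modelled as
two abutting sites, the left-hand one annotated on the minus strand.  The
repeat-analysis functions always compare sites in consensus orientation
(minus-strand sites reverse-complemented), which is also how the per-end
sequences in `repeat_set()` are returned.

### Candidate sequences

`build_candidate_sequence()` keeps anchors and junction elements fixed and
permutes/reverse-complements only the segment bodies.  The reference
arrangement reproduces the annotated plasmid substring byte-for-byte.  The
junction detail lost by fixing the sites in place is at most a few bases of
a ~20 nt near-identical repeat and is irrelevant for read assignment, which
is dominated by the ~10^2-10^3 nt segment bodies.

## Read assignment

`quantify_structures()` implements a BLASTN candidate search: every
candidate arrangement sequence is searched against the reads (BLAST+ must
be on the PATH), HSPs are chained collinearly per read/candidate/strand,
and a read is counted only when its best chain covers the shufflon-adjacent
part of **both** the pilV and rci anchors — i.e. only reads spanning the
whole locus are informative for a whole-shufflon structure.  Default
parameters:

| parameter | default | rationale |
|---|---|---|
| `min_identity` | 0.80 | chain-level identity floor for indel-dominated long reads |
| `margin` | 0.02 | best candidate must beat the runner-up by 2% of its score, otherwise the read is reported `ambiguous` |
| `min_anchor_cov` | 50 nt | anchor evidence required on each side; 50 nt makes a random match (4^-50) impossible and survives end clipping of local alignments |
| `anchor_extent` | 150 nt | anchor length retained in the search database; anchors beyond this carry no arrangement information |
| scoring | 1/-2, gap 2+2 | gap-tolerant scheme suited to ~9% insertion / ~4% deletion error profiles |

Ambiguous reads are excluded from the ratio denominator and reported in the
table totals.  Reads are never split; one read contributes at most one
count.  The independent oracle `reconstruct_from_markers()` locates exact
anchor/body marker matches and reads the arrangement off their order — it
shares no code or alignment machinery with the BLASTN route and is used in
the tests to confirm assignments on clean reads.

## pilV variant typing

A read is informative for the *pilV* variant when it contains part of the
pilV 3' constant region, an inverted-repeat site and part of a segment end
(`type_read()`).  The pilV anchor tail is located by exact 16-mer seeding
(at a per-base error rate of ~15% a 100-nt tail still yields ~7 clean
16-mers in expectation), then each ORF-end junction reference is aligned
across the repeat with an indel-tolerant local alignment.  Thresholds
default to 20 nt of aligned pilV-side and segment-side sequence and 10 nt
of repeat overlap — each far beyond random-match probability — with
identity floors of 0.90 (short reads) and 0.80 (long reads).  Paired-end
mates are typed independently; a pair counts once and only when the typed
mates agree.  `compare_platforms()` reports the squared Pearson correlation
of per-variant ratios between two platforms.

## Coverage and copy number

Plasmid copy number is the plasmid's mean per-base coverage divided by the
chromosome's, rounded half-up to one decimal (`copy_number()`), the
convention of printed genome-report tables.  `pair_class_coverage()`
classifies mapped pairs as proper (same replicon, FR orientation, insert
within bounds) or broken and accumulates per-position coverage for each
class; when a mapping reference carries one fixed arrangement, broken-pair
coverage concentrates over the shufflon and flags its heterogeneity.
Insert bounds default to mean ± 4 SD of the FR pairs, overridable.

## The synthetic-data generator

`make_locus()`, `sample_population()`, `simulate_long_reads()` and
`simulate_short_pairs()` emulate the statistical structure of a clonal
isolate sequenced on a long-read and a short-read platform:

* a 60 kb circular single-copy plasmid with a shufflon of 300 nt two-ORF
  segments, 500 nt anchors and repeats drawn from the consensus
  `GTGCCAATCCGGTNNGTGGA` (N positions randomised per site);
* a population heterogeneous over arrangements, either explicit or drawn
  from a symmetric Dirichlet;
* long reads with log-normal lengths (mean 8 kb) and a
  1.5%/9%/4% substitution/insertion/deletion error model — an
  SMRT-subread-like profile; runs of the real instrument do not publish
  their per-base rates, so these are defaults, not measurements;
* 2 x 300 bp pairs from Normal(400, 40) inserts with 0.5% substitutions.

Reads may wrap the circular origin; every read carries a ground-truth
record; all generators are deterministic functions of their seeds.

What the generator does **not** emulate: chimeric/adapter artefacts,
ZMW-subread duplication, quality-value structure, context-dependent error
hotspots, or between-plasmid sequence sharing.  Passing recovery tests on
synthetic data therefore demonstrates correctness of the counting machinery
under a realistic error magnitude, not performance on any particular real
run.

## Problem sizes and numerical choices

The bundled checks run the full path at desk scale: mixture recovery uses a
3-segment locus (48 candidate structures) with 2,000 spanning long reads
and verifies total-variation distance < 0.05 against the realised
ground-truth composition of the simulated reads.  We compare against the
realised composition rather than the latent Dirichlet vector deliberately:
multinomial noise alone at n = 2,000 over 48 categories contributes an
expected TV of about 0.05 against the latent vector, which would measure
the sample, not the assigner.  Platform consistency uses 2,000 reads per
platform, with short pairs drawn from a window around the pilV junction —
emulating the junction-covering fraction of a deep short-read run rather
than wasting simulated reads on loci that cannot inform the variant call.
Unit tests use a miniature locus (120 nt segments and anchors on an 8 kb
plasmid) to keep alignment work small.

Other numerical conventions: deterministic lexicographic ordering of the
arrangement space and label-sorted tie-breaks in tables and in the Kruskal
construction of the minimum spanning network; the epsilon-0 network keeps
every non-tree edge whose weight ties the maximum edge weight on the tree
path between its endpoints; gap-free repeat comparison (the sites are
fixed-length and their published alignments are ungapped); the conserved
repeat window defaults to 23 positions (the 20-nt site extended 3 nt into
the segment end, the exact offset being configurable because published
window boundaries are not printed).

## Known limitations

* Read assignment requires NCBI BLAST+ on the PATH; there is no pure-R
  fallback for the candidate search (the marker oracle is exact-match based
  and not a substitute under heavy noise).
* Candidate labels collapse one-ORF segment orientations; for such loci the
  sequence-level space should be inspected via `enumerate_arrangements()`
  directly.
* ZMW deduplication of long reads is not performed; if multiple subreads of
  one polymerase read are present, deduplicate upstream or accept the
  pseudo-replication.
* `pair_class_coverage()` consumes alignments from an external mapper; the
  package deliberately does not map reads itself.
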