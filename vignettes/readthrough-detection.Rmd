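---
title: "Detecting read-through chimeric RNAs without alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting read-through chimeric RNAs without alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtchimera)
library(dplyr)
```

## The problem

When RNA polymerase fails to terminate at a gene boundary it can continue
into the next gene on the same strand; splicing then joins an exon of the
upstream gene to an exon of the downstream gene. The resulting
*read-through* (cis-SAGe) chimeric RNA has no underlying genomic
rearrangement, which is exactly why rearrangement-oriented fusion callers
tend to discard it. Detecting read-throughs reliably requires a method that
treats them as first-class events.

rtchimera takes a database-search view of the problem. Every read-through
junction that respects exon boundaries is enumerable in advance from the
annotation: it joins the last base of some exon of a 5′ gene to the first
base of some exon of a downstream same-strand 3′ gene. If we precompute the
short sequence context around every such hypothetical junction, a
sequencing read that truly spans the junction must contain that context
verbatim — no alignment needed, and no alignment artifacts introduced.

## The junction database

For a donor breakpoint $b_5$ (last transcribed base of the 5′ exon) and an
acceptor breakpoint $b_3$ (first transcribed base of the 3′ exon), the
junction sequence is

$$ J = g[b_5 - f + 1 \,..\, b_5] \;\oplus\; g[b_3 \,..\, b_3 + f - 1], $$

taken in transcribed orientation (reverse complement of the genomic slices
on the minus strand), with flank $f = 20$ nt, giving a 40-nt string. Gene
pairs qualify when they share chromosome and strand, the acceptor lies
strictly downstream of the donor in transcription direction, and
$|b_3 - b_5| \le D$ with $D = 70$ kb by default — the distance that
captures the large majority of experimentally validated read-throughs.
Pair adjacency is deliberately *not* required: intervening genes do not
disqualify a pair, because polymerase read-through can span them; the
distance cap is the operative criterion.

Combinations are deduplicated by breakpoint pair. Isoforms often share a
splice site while differing at the exon's other end; those variants have
the *same* junction sequence, so one record per (donor breakpoint,
acceptor breakpoint) is kept, with all contributing exon ids retained and
the longest contributing exon as the representative interval (relevant
only for the flank-length test and reporting).

```{r figure-combos}
world <- simulate_world(tempfile("vig"), seed = 1, n_pairs = 1)
nrow(enumerate_exon_combinations(world$exons))  # 5 x 4 exons -> 20
```

## Pre-filters

Five filters remove junction sequences that would attract reads for
reasons other than read-through transcription. Each is a pure per-record
predicate, so the surviving set does not depend on the order in which they
run (the per-stage tallies do; the canonical order is the one below).

1. **Paralog filter.** Paralogous gene pairs share sequence by descent;
   reads from one gene can contain an apparent junction into the other.
   Pairs listed in the paralog relation are dropped. Membership is tested
   on stable gene ids, unordered.
2. **Flank-length filter.** An exon shorter than $f$ cannot supply a full
   flank; the boundary is exact (a 19-bp exon fails, a 20-bp exon passes).
3. **Same-isoform filter.** Overlapping genes can share exons; a read
   covering two consecutive exons of one transcript then looks like a
   read-through between the two genes. A combination is dropped when an
   exon with the acceptor's exact coordinates is the donor's immediate
   successor in a transcript of the 5′ gene, or symmetrically for the
   donor in the 3′ gene. Adjacency is evaluated per transcript, which is
   why the annotation model keeps duplicate exon coordinates per
   transcript chain.
4. **Exon filter.** A junction 40-mer that matches *any* annotated exon at
   ≥ 90 % identity over ≥ 90 % of the junction would collect reads from a
   contiguous exonic region. Identity is computed over aligned columns
   (gaps count against identity) and coverage over the query (the
   junction). Because coverage must reach 36 of 40 bases, a junction's own
   20-nt halves can never trigger the filter, so no self-hit exclusion is
   needed.
5. **Cross-similarity filter.** If the donor exon resembles an exon of the
   3′ gene (or the acceptor an exon of the 5′ gene) at ≥ 70 % identity and
   ≥ 70 % coverage of the probed exon, the "junction" is more plausibly an
   alternative splice form or local duplication. The coordinate-identical
   exon is skipped when probing the partner gene (degenerate overlap).

Filters 4–5 use Smith–Waterman local alignment with a blastn-like scheme:
match +1, mismatch −2, gap open 5, gap extend 2. The original tool family
delegates this step to BLAST without publishing its exact scoring, so the
scheme is exposed in the run configuration (`align_config`) and the tests
rely on constructed cases (verbatim copies, ~50 % identity) that are robust
to small scheme changes; genuinely borderline hits (e.g. 89.9 % identity)
may differ from any particular BLAST build.

```{r cascade}
decoy <- simulate_world(tempfile("vigdec"), seed = 2, n_pairs = 1,
                        decoys = c("paralog", "short_exon", "same_isoform",
                                   "exon_copy", "similar_exons"))
cascade <- run_prefilter_cascade(
  enumerate_exon_combinations(decoy$exons), decoy$exons, decoy$genome,
  load_paralogs(decoy$paralogs))
cascade$tally
```

## Common-SNP variants

Exact matching misses a junction when the sequenced individual carries a
variant inside either 20-nt window. For every single-nucleotide variant
with alternate-allele frequency ≥ 0.10 falling inside a junction window,
one variant record is added: same breakpoints, one substituted base
(complemented on the minus strand). Choices made here, where the method
description leaves room:

* The frequency is interpreted as the *alternate*-allele frequency (dbSNP
  CAF lists the reference allele first; `AF` fields are per-alt). The
  threshold is configurable (`min_caf`).
* One variant per alternate allele; combinations of several SNPs inside
  one junction are not enumerated by default (rare at ≥ 10 % frequency and
  multiplicative in database size); `expand_snp_pairs = TRUE` enables
  pairwise double-substitutions.
* Variants inherit the parent's filter status rather than re-entering the
  cascade: expansion happens after filtering, and a one-base change cannot
  meaningfully change a 90 %/70 % similarity verdict.
* A variant whose stated reference allele disagrees with the genome is
  still emitted, with a warning — annotation/genome build mismatches
  should be visible, not silent.

## The read scan

A read supports a junction iff it contains the junction 40-mer or its
reverse complement as an exact, contiguous substring. All unique 40-mers
(both orientations) are compiled into a constant-width pattern dictionary
and all reads are streamed against it. Consequences of exact containment
semantics, all tested:

* reads shorter than 40 nt can never match — at 36-nt read length the
  method is structurally blind, which is why short-read libraries lose
  sensitivity;
* N never matches (no wildcard semantics); junctions whose own 40-mer
  contains N are excluded from the index, with a logged count;
* matching is case-insensitive (reads are alphabet-normalised on input);
* paired-end mates are independent reads for support counting, with read
  ids normalised to a `fragment/mate` key (`/1`, `/2` and Casava-style
  `1:N:0:...` conventions recognised). A fragment whose two mates both
  span the junction therefore contributes 2 supporting reads; the read
  ids in the report make this transparent.

The pattern set is split into balanced chunks sized from a user-provided
memory budget (`memory_budget_gb`, using a deliberately generous
per-pattern footprint estimate), processed sequentially or across worker
processes. The hit set is a pure function of (reads, index): invariant
under chunk count, thread count and file order — a property the tests
check against a naive per-pattern substring oracle on seeded random
worlds.

## Post-filters and reporting

Hits are first collapsed to *events*: SNP variants and both orientations
of one junction are evidence for the same biological breakpoint pair. The
ambiguity filter then discards any read whose event set has more than one
element and recounts support; events left with no reads are dropped. Two
design choices matter:

* Ambiguity is evaluated at the collapsed event level, not the raw pattern
  level — otherwise every read matching a parent *and* its SNP variant
  would destroy itself, inverting the purpose of expansion.
* Removal is single-pass, which is also a fixed point: surviving reads
  have singleton event sets by construction, so the filter is idempotent
  (asserted in the tests).

An optional minimum-support cutoff (`min_support`, default 1 = identity)
follows. The report carries 1-based breakpoint coordinates (genome-browser
convention; internals use the same 1-based inclusive convention as the
Bioconductor ranges infrastructure, converted only at the BEDPE boundary,
which is 0-based half-open), distances, support counts, capped read-id
lists (full lists in a sidecar file), matched parent/variant sequences and
full donor/acceptor exon sequences in transcribed orientation for primer
design. Rows sort by (chromosome, donor breakpoint, acceptor breakpoint)
and the table contains no timestamps, so identical inputs give
byte-identical files.

## The synthetic-world generator

`simulate_world()` lays out same-strand gene pairs (by default a 5-exon
and a 4-exon gene, exons 80–200 bp, introns 300–900 bp, intergenic gap
6–12 kb) on a random-sequence chromosome, alternating strands across
pairs, with successive regions separated by 80 kb so regions cannot
cross-pair under the 70 kb cap. One read-through event per pair is planted
(rank-2 exon of each gene) and written to a truth table mirroring the
report schema. Decoy regions can be requested, one per pre-filter: a
paralog-listed pair, a 19-bp donor exon, an overlapping-gene shared exon,
a junction 40-mer embedded verbatim in a distant exon, and a 90 %-identity
exon copy. A small SNP table (one common variant at frequency 0.30, one
rare at 0.05, one indel) targets the first planted junction's donor
window.

`simulate_reads()` draws error-free reads uniformly along every normal and
chimeric transcript (default 101 nt, 150 reads per transcript — at those
sizes the probability that a planted junction has no covering read is
below $10^{-6}$ per event, so end-to-end recovery tests are stable for any
seed). Reads can be drawn from an ALT haplotype by substituting chosen SNP
alleles into the genome first; a per-base substitution error rate is
available but off by default, since the method is exact-match and error
simulation only demonstrates sensitivity loss.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: realistic expression distributions (uniform
coverage only), sequencing-error profiles, intronic/intergenic background
reads, multi-isoform genes beyond the decoy cases, repeat families and
pseudogenes at genome scale, and the sheer pattern count of a mammalian
annotation (millions of junctions vs hundreds here). Scale-sensitive
behaviour — chunked memory use, multi-core throughput — is tested for
correctness (invariance), not for performance.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive throughout the package, matching
  IRanges/GenomicRanges and GTF; BEDPE output converts to 0-based
  half-open at the boundary. Breakpoints printed in reports are 1-based
  genomic positions.
* All serialized outputs use a fixed C-locale sort; ties break on junction
  id, which embeds gene ids and breakpoints and is unique.
* A best local alignment with non-positive score has zero aligned columns
  and reports identity 0, coverage 0; empty queries and subjects likewise.
* `max_distance = 0` yields an empty database (no error); an empty
  paralog table makes that filter the identity; `min_reads = 1` makes the
  support filter the identity; a budget below one pattern's footprint is
  an error.
* Genome slicing is strictly bounds-checked; out-of-range exon or window
  coordinates raise errors naming the offending interval rather than
  clamping.
* Test and acceptance problem sizes — toy chromosomes of roughly 0.1–1 Mb,
  one to ten gene pairs, 150–4500 reads — were chosen so the full suite
  exercises every stage, including the alignment filters, in a few
  minutes on one core.

## Known limitations

* Only exon-boundary junctions are enumerable: breakpoints inside exons,
  or pairs beyond the distance cap, are invisible by construction.
* Exact matching tolerates no sequencing error inside the 40-nt window;
  high-error long reads (Oxford Nanopore) will lose sensitivity, though
  low-error long reads work since matching is containment-based and
  length-agnostic (FASTA input is accepted).
* The alignment-based filters reproduce thresholds, not a specific BLAST
  build; borderline similarity calls can differ from other tool chains.
* Support counting is per read with no fragment-level deduplication or
  expression normalisation; candidates carry no statistical confidence
  score beyond the support count.
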