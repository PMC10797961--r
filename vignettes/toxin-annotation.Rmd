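---
title: "Annotating toxin genes with toxannot: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating toxin genes with toxannot: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(toxannot)
```

## The annotation problem

Toxin genes are among the hardest targets for automated genome annotation.
They expand by in-locus duplication into tandem arrays of near-identical
paralogs, accumulate mutations quickly, and their loci are littered with
orphan exons and truncated copies that retain a complete exon–intron
structure but carry a premature stop codon. General annotators, trained on
genome-wide gene statistics, routinely fragment, merge or misname these
genes. `toxannot` instead anchors annotation on *known full-length toxin
coding sequences* (CDSs): the user supplies a database of validated toxin
CDSs (optionally extended from the species' own venom-tissue
transcriptome), and the pipeline finds, models and classifies every genomic
locus matching a full-length entry.

A *full-length CDS* in this package always means: starts with ATG, ends
with TAA/TAG/TGA, length a multiple of 3, no internal in-frame stop, and at
least `min_cds_len` nucleotides. `validate_cds()` enforces this grammar;
database records failing it are dropped with a warning rather than aborting,
since public sequence sets are noisy.

## Pipeline stages and their assumptions

**Similarity search** (`search_hits()`). An exact k-mer index over the
forward strand of each contig seeds gapped local alignments; the reverse
strand is searched by aligning the reverse-complemented query, so minus
hits are reported on forward coordinates with query intervals in
query-forward orientation. Seeds are merged per diagonal, clustered within
a 32-diagonal band and a 40-bp target gap (below the minimum intron length,
so distinct exons stay distinct hits), and each cluster is aligned by
windowed Smith–Waterman with affine gaps, growing the window when the
alignment touches its edge. E-values are not computed; filtering is by
score and identity only, because identity is the user-facing knob. An
adapter (`read_blast_hits()`/`write_blast_hits()`) converts BLAST
outfmt-6 tables to the same internal convention, so an external aligner
can substitute the built-in engine.

All internal coordinates are 0-based half-open on the forward strand;
conversion to 1-based inclusive happens exactly once, at GTF emission.

**Chaining** (`chain_hits()`). Within each (query, contig, strand) group,
maximal-score collinear chains are found by exact dynamic programming: for
every candidate head hit the DP maximizes the sum of hit scores minus join
costs, under strict collinearity in transcription order, at most 15 bp of
overlap between consecutive hits on query and target, and a genomic span of
at most `max_gene_size` measured from the head. Chains are peeled greedily
by score, so each hit belongs to at most one locus per query — while one
query may still seed several loci on a contig, which tandem arrays require.

The join cost is `join_penalty + gap/gap_scale` (defaults 10 and 1000).
The gap term is deliberately weak — an intron-sized gap of 3 kb costs 3
points — but it is essential: with a purely constant join cost, the best
chain for a query can *bridge two same-family tandem copies* that lie
within `max_gene_size` of each other, taking 5' exons from one copy and 3'
exons from the other. Such a chimeric chain starves the second copy's locus
and merges both copies into one matched region. A cross-copy jump of
20–50 kb now costs 20–50 points, which reliably tips the balance toward
single-copy chains without affecting genuine multi-exon genes.

**Full-length selection** (`classify_locus()`). A locus is full-length when
its chain covers ≥ 95% of the query CDS (`min_coverage`) and reaches both
query termini within 10 bp (`end_tolerance`). Demanding exactly 100%
coverage would be brittle: local alignments routinely shed a few terminal
bases at mismatches, and the model finalization step re-derives the exact
boundaries anyway. Partial loci are dropped — partial-gene annotation on
fragmented contigs is explicitly out of scope — but every full-length locus
is written to `matched_regions.gtf` whether or not a model is eventually
built there, giving curators the "matched but not annotated" surface to
inspect.

**Spliced alignment** (`spliced_align()`). A dynamic program over states
{exon match/mismatch, affine exon gap, intron} aligns the query CDS to the
locus region (span ± 500 bp flank, reverse-complemented for minus loci).
The intron state has a constant cost, is bounded to `[min_intron,
max_intron]` = [50 bp, `max_gene_size`], and can only bridge region
segments that start GT and end AG — the canonical-splice-site restriction
that is a stated limitation of the whole method. The alignment is global in
the query and local in the region. Exon scoring defaults (+5/−4, gap
−12/−2, intron −40) make one intron cheaper than a ~7-bp exon gap, so true
introns are never absorbed as deletions, while spurious short introns are
dearer than a few mismatches.

By default the exon states are banded to the target intervals implied by
the hit chain ± 2 kb (`band_slack`), bounding memory and time at
`O(|cds| × |band|)`; `unbanded = TRUE` runs the full quadratic program and
is what the junction-recovery tests exercise. Intron placement at repeats
is resolved deterministically (latest donor wins ties); note that
alternative placements with identical spliced sequence are biologically
indistinguishable — the CDS round-trip, not the junction coordinates, is
the meaningful invariant when the query is diverged from the locus.

**Finalization and classification** (`finalize_model()`,
`classify_annotation()`). Exon segments are mapped to genome coordinates.
If the aligned CDS does not begin with ATG, the first exon boundary is
scanned in-frame within ± `rescue_codons` (30) codons for an ATG, nearest
candidate first (ties prefer the upstream one); the 3' boundary is
analogously adjusted to the nearest in-frame stop that keeps the spliced
length a codon multiple. Models failing to find either signal, or ending
below `min_cds_len`, are rejected with a typed reason and leave their locus
visible only in the matched regions. A finalized model is `warning` iff its
CDS contains an in-frame internal stop (candidate truncated paralog or
pseudogene — also a frequent signature of assembly error), else `reliable`.
Warning models are written both to the annotation GTF (with a `status`
attribute) and to `annotation_warning.txt`, since both classes count as
annotations in the evaluation.

**Overlap resolution** (`resolve_overlaps()`). Models whose exon footprints
overlap by > 30% of the shorter footprint on the same strand compete;
the winner is chosen by score, then identity, then CDS length, then
lexicographic source query — a total order, so the output is invariant
under input permutation. Opposite-strand overlaps never compete, which
preserves inverted gene pairs (a real arrangement of C-type lectins).

## Transcript screening and databases

`screen_transcripts()` implements custom-database construction: the
database CDSs are searched against the assembled transcripts; a transcript
qualifies when its best database entry is hit at ≥ 80% identity with ≥ 50%
of the entry covered (defaults chosen to admit cross-species homologs while
excluding spurious hits); the ORF best overlapping the hit footprint —
ATG-to-stop, all six frames, nested ORFs collapsed to the longest per
stop — becomes a record labeled with the best hit's family (ties broken by
identity, then id). Exact duplicates are deduplicated, and
`merge_databases()` resolves id collisions deterministically by suffixing.

`cluster_by_identity()` reduces database redundancy greedily: records
sorted by decreasing length, each joining the first cluster whose
representative it matches at ≥ 99% global identity. Identity is
*nucleotide* identity of a plain global alignment (matches / alignment
columns, terminal gaps penalized and counted) — nucleotide rather than
translated identity was chosen because the databases are nucleotide CDS
sets and the search engine operates in nucleotide space.

## Evaluation metrics

The toxin recovery rate (TRR) of a family is the number of annotations
divided by the number of loci reported in the reference annotation: 1 is an
exact match, > 1 more loci than reported, < 1 fewer; a family with zero
reported loci has undefined TRR (`NA`, excluded from summaries). Per-gene
labels against a reference partition it into `matched_and_annotated`
(a final model overlaps ≥ 50% of the reference CDS footprint on the same
strand), `matched_but_not_annotated` (only a matched region overlaps so),
and `not_matched`. Automatic precision is the annotated fraction;
supervised precision additionally counts matched-only genes, since a
curator recovers those from `matched_regions.gtf` — supervised ≥ automatic
by construction. The 50% single-direction overlap rule is this package's
operationalization of what is otherwise a manual judgment; it is exposed as
a threshold. Percentages render at one decimal, rounding half away from
zero.

## The synthetic fixture: what it emulates, what it does not

`make_fixture()` generates the benchmark conditions used by the test suite:
a 1-Mb background (two contigs, GC 0.42, i.i.d. bases) carrying 20
implanted genes from 5 families — within-family paralogs diverged to ~90%
identity by substitutions, 1–8 exons with introns of 60–3000 bp and exons
≥ 40 bp (the lower end of real toxin exon sizes), both strands, and 2
pseudogenes. A pseudogene is modeled as a *recently inactivated copy*: its
CDS derives from a functional family member at 98% identity plus exactly
one interior stop codon, matching the truncated-paralog pattern of toxin
arrays (a pseudogene is never a family's only member — its detectability
comes from its functional sibling). The database holds the exact functional
CDSs (`db_identity` lowers this to emulate a cross-species database), and
the transcripts are the CDSs wrapped in 50–150 bp random UTRs. Everything
is a deterministic function of one integer seed.

The fixture deliberately omits several features of real genomes: repeats
and low-complexity sequence (no spurious seed clusters), indel divergence
(substitution-only keeps the identity oracle exact; an indel-bearing
homolog exercises the same gapped aligner but without a closed-form truth),
orphan exons, GC heterogeneity, and assembly gaps. Passing tests therefore
demonstrate the correctness of the algorithms under clean conditions and
their calibration on realistic gene geometry — not robustness to repeat
landscapes, which on real data is mitigated upstream (repeat masking) and
by the identity/score thresholds.

Test problem sizes were chosen so the whole suite runs in a few minutes:
the full 1-Mb/20-gene fixture appears twice (recovery and determinism),
smaller 0.2–0.4-Mb fixtures elsewhere; the chaining oracle enumerates all
subsets of ≤ 8 hits; spliced-alignment oracle cases use single genes with
one or two introns.

## Numerical and degenerate-input choices

* Alignment scores are integers; chain scores are reals (gap term). All
  tie-breaks (clustering order, chain head order, rescue-candidate order,
  overlap resolution, output sort) are total orders, so every output is
  bit-stable given identical inputs; `threads` is accepted for interface
  compatibility and can never change results.
* An empty hit set, an empty locus list and an empty annotation set are
  valid values and produce valid (empty) outputs; an empty database or
  genome is a typed input error (CLI exit code 2).
* The seed index skips k-mers containing N; N in the genome never matches
  any base. N is forbidden in CDSs.
* `max_intron` always tracks `max_gene_size`, so raising the gene-size
  limit transparently admits the long-intron genes that motivate it.
* In the threshold-narrative experiment the under-sized CDS is 198 nt:
  the smallest codon-multiple length under the 200-bp threshold (a 196-nt
  sequence cannot satisfy the full-length CDS grammar).

## Known limitations

Non-canonical starts and splice sites are not modeled; partial genes are
not annotated; one annotation may overlap two closely spaced reference
genes and be counted for only one of them under the 50% rule; equivalence
with any particular external aligner's output is not claimed (the
outfmt-6 adapter exists precisely so one can be substituted and compared).
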