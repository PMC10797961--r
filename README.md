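# toxannot

Automated annotation of **toxin genes** in genome assemblies of venomous
lineages (snakes, stingrays, scorpions, hymenopterans, sea anemones, ...).

Toxin loci defeat general-purpose genome annotators: venom gene families
arise by repeated in-locus duplication, sit in tandem arrays of highly
similar paralogs, and are littered with orphan exons and truncated copies
carrying premature stop codons. `toxannot` attacks the problem the way a
venomics curator does — with a database of known full-length toxin coding
sequences (CDSs) — and automates the steps around it:

1. **Detection of putative toxin loci.** Every database CDS is searched
   against both strands of every contig with a seed-and-extend gapped local
   aligner (exact k-mer seeds, k = 11 by default; hits filtered at score ≥ 50
   and identity ≥ 0.80).
2. **Selection of bona fide loci.** Local hits are chained into collinear
   candidate loci by exact dynamic programming (genomic span ≤ 50 kb by
   default). Only loci whose chain covers ≥ 95% of a query CDS and reaches
   both CDS termini within 10 bp — i.e. loci matching a *full-length* toxin
   CDS — go forward; all of them are reported in `matched_regions.gtf`.
3. **Gene-model building.** Each full-length locus is realigned with a
   spliced dynamic program whose intron state is restricted to canonical
   GT..AG splice sites, then the model is finalized: canonical ATG start and
   stop codon (rescued by an in-frame scan of ±30 codons when the alignment
   boundary is off), per-exon phases, CDS and peptide extraction.
4. **Classification.** A model with a clean full-length CDS is `reliable`;
   a model with a premature in-frame stop — a candidate truncated paralog or
   pseudogene — is `warning`. Overlapping competing models are resolved
   deterministically by score, identity, CDS length.

The package also implements the surrounding toolkit: database loading,
validation and greedy 99%-identity clustering; screening of assembled
venom-gland transcripts for full-length toxin CDSs to build a custom
database; evaluation metrics (per-family **toxin recovery rate**,
TRR = annotated/reported, and automatic vs supervised annotation
**precision**); and a deterministic synthetic-fixture generator with
machine-readable truth used throughout the test suite.

## Worked example

Build a small synthetic genome (six multi-exon toxin genes from three
families, one of them a pseudogene with a premature stop) and annotate it
with its exact-CDS database:

```r
library(toxannot)

fx  <- make_fixture(seed = 42, genome_length = 2e5, n_contigs = 1,
                    n_genes = 6, n_families = 3, n_pseudogenes = 1)
res <- annotate_genome(fx$genome, fx$db, log = message)
#> search: 5 queries vs 1 contigs -> 60 hits
#> chaining: 10 loci (10 full-length, 0 partial)
#> matched regions: 6
#> gene models: 10 built, 0 rejected
#> final annotation: 6 models (5 reliable, 1 warning)

print(res$models[[1]])
#> gene model SVMP-1 [SVMP] contig_1:9696-19130(-): 8 exon(s), CDS 840 bp, reliable

ev <- evaluate_annotation(res$models, res$regions, reference_from_truth(fx))
print(ev)
#> evaluation: 6/6 annotated (automatic 100.0%), +0 matched only (supervised 100.0%)
#> TRR: PLA2=1.00, SVMP=1.00, SVSP=1.00
```

The five queries are the implanted functional CDSs (the pseudogene's
stop-containing sequence is not a valid database record); ten loci arise
because paralogous queries also match each other's gene copies, and overlap
resolution keeps the best model per locus. All six implanted genes are
recovered — each reliable CDS byte-identical to the implanted one — the
pseudogene is flagged `warning`, and the toxin recovery rate is exactly 1
for every family. `run_pipeline()` does the same from FASTA files and
writes `toxin_annotation.gtf`, `matched_regions.gtf`, `toxins_cds.fasta`,
`toxins_pep.fasta`, `annotation_warning.txt` and a run log.

## Limitations

Only canonical coding signals are considered (ATG start, TAA/TAG/TGA stop,
GT..AG introns); partial genes on fragmented contigs are not annotated
(they remain visible in `matched_regions.gtf`); annotation quality is
bounded by the similarity of the database to the target species — building
a custom database from venom-tissue transcripts with
`screen_transcripts()` and merging it is the recommended remedy.
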