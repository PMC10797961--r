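# a minimal in-memory locus for region extraction
fake_locus <- function(contig, strand, span_start, span_end,
                       hits = NULL, query = "q") {
  structure(list(query_id = query, contig_id = contig, strand = strand,
                 hits = hits, span_start = span_start, span_end = span_end,
                 query_coverage = 1, qstart_min = 0, qend_max = 0,
                 query_length = 0, score = 0),
            class = "candidate_locus")
}

test_that("region extraction clips at contig bounds and round-trips coordinates", {
  g <- c(chr = rand_dna(20000, seed = 900))
  l <- fake_locus("chr", "+", 10000, 12000)
  r <- extract_region(g, l, flank = 500)
  expect_equal(c(r$g_start, r$g_end), c(9500, 12500))
  expect_equal(r$seq, substr(g[["chr"]], 9501, 12500))

  l2 <- fake_locus("chr", "+", 100, 700)
  r2 <- extract_region(g, l2, flank = 500)
  expect_equal(r2$g_start, 0)

  # minus strand: double reverse-complement recovers the genomic bases
  l3 <- fake_locus("chr", "-", 5000, 6000)
  r3 <- extract_region(g, l3, flank = 100)
  gi <- region_to_genome(r3, 10, 25)
  seg <- substr(g[["chr"]], gi[1] + 1, gi[2])
  expect_equal(rc(seg), substr(r3$seq, 11, 25))
})

test_that("spliced alignment recovers exact CDS and implanted canonical introns", {
  cds <- random_cds(120, seed = 910)  # 360 nt

  # region equal to the CDS: one exon, no introns, identity 1
  a <- spliced_align(cds, cds, unbanded = TRUE)
  expect_equal(nrow(a$segments), 1L)
  expect_equal(a$identity, 1.0)
  expect_equal(unname(a$segments[1, ]), c(0L, 360L, 0L, 360L))

  # one implanted 500-bp GT..AG intron at a recorded interior position
  gene <- generate_toxin_gene(cds, intron_lengths = 500, seed = 911)
  flanked <- paste0(rand_dna(200, seed = 912), gene$seq,
                    rand_dna(200, seed = 913))
  a2 <- spliced_align(cds, flanked, unbanded = TRUE)
  expect_equal(nrow(a2$segments), 2L)
  got <- a2$segments
  expect_equal(got[, "rstart"], gene$exons[, "start"] + 200L)
  expect_equal(got[, "rend"], gene$exons[, "end"] + 200L)
  spliced <- paste0(substr(flanked, got[1, "rstart"] + 1, got[1, "rend"]),
                    substr(flanked, got[2, "rstart"] + 1, got[2, "rend"]))
  expect_equal(spliced, cds)

  # the same implant with its splice sites edited to CT..AC is not an intron
  splitpos <- gene$exons[1, "end"]
  broken <- gene$seq
  substr(broken, splitpos + 1, splitpos + 2) <- "CT"
  substr(broken, splitpos + 500 - 1, splitpos + 500) <- "AC"
  a3 <- spliced_align(cds, broken, unbanded = TRUE)
  expect_true(nrow(a3$segments) != 2L ||
                a3$segments[2, "rstart"] - a3$segments[1, "rend"] != 500L)
})

test_that("finalize_model maps exons to the genome and rescues canonical boundaries", {
  cds <- random_cds(110, seed = 920)  # 330 nt
  gene <- generate_toxin_gene(cds, intron_lengths = c(300, 700), seed = 921)
  bg <- rand_dna(8000, seed = 922)
  genome <- c(ctg = paste0(substr(bg, 1, 2000), gene$seq,
                           substr(bg, 2001 + nchar(gene$seq), 8000)))
  db <- toxin_db("q|FAM", "FAM", cds, min_cds_len = 30)
  res <- annotate_genome(genome, db,
                         toxannot_config(min_cds_len = 60, min_score = 40))
  expect_length(res$models, 1)
  m <- res$models[[1]]
  expect_equal(m$cds, cds)                       # byte-exact round trip
  expect_equal(nrow(m$exons), 3L)
  expect_equal(m$status, "reliable")
  expect_equal(m$family, "FAM")
  # re-splicing the emitted exons from the genome reproduces the CDS
  expect_equal(splice_cds_from_genome(genome, m$contig_id, m$strand, m$exons),
               m$cds)

  # start rescue: alignment starting 2 codons downstream still finds the ATG
  # (constructed so the true ATG is the only one inside the rescue window)
  cdsR <- paste0("ATG", strrep("CCT", 8), substr(cds, 28, nchar(cds)))
  region <- structure(list(seq = paste0(strrep("G", 100), cdsR,
                                        rand_dna(100, seed = 924)),
                           contig_id = "ctg", strand = "+",
                           g_start = 0L,
                           g_end = 200L + nchar(cdsR)),
                      class = "oriented_region")
  aln <- spliced_align(substr(cdsR, 7, nchar(cdsR)), region, unbanded = TRUE)
  qrec <- data.frame(id = "q", family = "FAM", stringsAsFactors = FALSE)
  m2 <- finalize_model(aln, qrec, region, min_cds_len = 60)
  expect_s3_class(m2, "gene_model")
  expect_equal(m2$cds, cdsR)

  # no stop codon within the rescue window: typed rejection
  stopless <- substr(cds, 1, nchar(cds) - 3)
  region3 <- structure(list(seq = paste0(rand_dna(100, seed = 925), stopless,
                                         strrep("C", 200)),
                            contig_id = "ctg", strand = "+", g_start = 0L,
                            g_end = 300L + nchar(stopless)),
                       class = "oriented_region")
  aln3 <- spliced_align(stopless, region3, unbanded = TRUE)
  r3 <- finalize_model(aln3, qrec, region3, min_cds_len = 60)
  expect_s3_class(r3, "model_rejection")
  expect_equal(r3$reason, "no_terminal_stop")
})

test_that("annotation classification keys on in-frame internal stops only", {
  mk <- function(cds) structure(list(cds = cds), class = "gene_model")
  clean <- random_cds(80, seed = 930)
  expect_equal(classify_annotation(mk(clean)), "reliable")
  pseudo <- mutate_cds(clean, 1.0, seed = 931, pseudogenize = TRUE)
  expect_equal(classify_annotation(mk(pseudo)), "warning")
  expect_true("internal_stop" %in% validate_cds(pseudo, min_len = 30)$reasons)
  # TGA spanning codons 2-3 (out of frame) is not a premature stop
  offframe <- paste0("ATG", "CTG", "AAA", "GCA", "TAA")
  expect_equal(classify_annotation(mk(offframe)), "reliable")
})

test_that("overlap resolution is deterministic and permutation invariant", {
  mk <- function(id, score, identity, start, end, query = id,
                 strand = "+", contig = "c") {
    structure(list(id = id, contig_id = contig, strand = strand,
                   exons = cbind(start = start, end = end),
                   phases = 0L, cds = strrep("A", sum(end - start)),
                   peptide = "", status = "reliable", source_query = query,
                   family = "F", score = score, identity = identity),
              class = "gene_model")
  }
  a <- mk("a", 500, 0.95, 1000, 2000)
  b <- mk("b", 450, 0.99, 1500, 2500)    # overlaps a by 500/1000
  kept <- resolve_overlaps(list(a, b))
  expect_length(kept, 1)
  expect_equal(kept[[1]]$id, "a")        # higher score wins

  c1 <- mk("c1", 500, 0.97, 1000, 2000)
  c2 <- mk("c2", 500, 0.92, 1500, 2500)  # equal score: identity decides
  kept2 <- resolve_overlaps(list(c2, c1))
  expect_equal(kept2[[1]]$id, "c1")

  d <- mk("d", 100, 0.9, 9000, 9600)     # disjoint: both kept
  kept3 <- resolve_overlaps(list(a, d))
  expect_length(kept3, 2)

  # permutation invariance
  ms <- list(a, b, c1, c2, d)
  ids <- function(x) vapply(x, `[[`, character(1), "id")
  base <- ids(resolve_overlaps(ms))
  for (s in 1:5) {
    set.seed(s)
    expect_equal(ids(resolve_overlaps(sample(ms))), base)
  }
})

test_that("translation follows the standard code and marks internal stops", {
  expect_equal(translate_cds("ATGAAATAG"), "MK")
  expect_equal(translate_cds("ATGTGAAAATAG"), "M*K")
  expect_error(translate_cds("ATGAA"), "multiple of 3")
  cds <- random_cds(90, seed = 940)
  expect_equal(nchar(translate_cds(cds)), nchar(cds) / 3 - 1)
})

test_that("peptide best-match report picks the right subject", {
  cds1 <- random_cds(90, seed = 950)
  cds2 <- random_cds(90, seed = 951)
  m <- structure(list(id = "m1", peptide = translate_cds(cds1)),
                 class = "gene_model")
  prot <- c(p1 = translate_cds(cds1), p2 = translate_cds(cds2))
  rep <- best_match_report(list(m), prot)
  expect_equal(rep$best_subject, "p1")
  expect_equal(rep$identity, 1.0)
  expect_equal(rep$coverage, 1.0)
})
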