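mk_hits <- function(qs, qe, ts, te, score, strand = "+", query = "q",
                    contig = "c") {
  data.frame(query_id = query, contig_id = contig, strand = strand,
             qstart = qs, qend = qe, tstart = ts, tend = te,
             identity = 0.95, score = score, stringsAsFactors = FALSE)
}

test_that("collinear exon hits chain into one locus; distant groups split at the gene-size limit", {
  # three exon hits of one query spanning 4 kb
  h <- mk_hits(c(0, 100, 200), c(100, 200, 300),
               c(1000, 2500, 4700), c(1100, 2600, 4800), c(180, 180, 180))
  loci <- chain_hits(h, c(q = 300))
  expect_length(loci, 1)
  expect_equal(nrow(loci[[1]]$hits), 3L)
  expect_equal(loci[[1]]$query_coverage, 1.0)

  # two hit groups 80 kb apart cannot share a 50-kb gene
  h2 <- rbind(mk_hits(0, 150, 1000, 1150, 250),
              mk_hits(150, 300, 81000, 81150, 250))
  loci2 <- chain_hits(h2, c(q = 300), max_gene_size = 50000)
  expect_length(loci2, 2)

  # raising the limit lets them chain (monotonicity of the span rule)
  loci3 <- chain_hits(h2, c(q = 300), max_gene_size = 100000)
  expect_length(loci3, 1)
  expect_equal(nrow(loci3[[1]]$hits), 2L)

  # opposite strands never chain
  h4 <- rbind(mk_hits(0, 150, 1000, 1150, 250, strand = "+"),
              mk_hits(150, 300, 3000, 3150, 250, strand = "-"))
  loci4 <- chain_hits(h4, c(q = 300))
  expect_length(loci4, 2)
  expect_true(all(vapply(loci4, function(l) nrow(l$hits), 1L) == 1L))

  # target order contradicting query order is never chained
  h5 <- rbind(mk_hits(0, 150, 5000, 5150, 250),
              mk_hits(150, 300, 1000, 1150, 250))
  loci5 <- chain_hits(h5, c(q = 300))
  expect_true(all(vapply(loci5, function(l) nrow(l$hits), 1L) == 1L))
})

test_that("chain score equals the exhaustive collinear-subset oracle on small hit sets", {
  for (s in 1:12) {
    n <- sample(3:8, 1)
    h <- random_hits(n, seed = 700 + s)
    loci <- chain_hits(h, c(q = 500))
    expect_gte(length(loci), 1)
    best <- max(vapply(loci, `[[`, 1, "score"))
    expect_equal(best, brute_force_chain_score(h))
  }
})

test_that("minus-strand chains are collinear in transcription order", {
  # on the minus strand, later query intervals sit at smaller coordinates
  h <- rbind(mk_hits(0, 100, 5000, 5100, 180, strand = "-"),
             mk_hits(100, 200, 3000, 3100, 180, strand = "-"),
             mk_hits(200, 300, 1000, 1100, 180, strand = "-"))
  loci <- chain_hits(h, c(q = 300))
  expect_length(loci, 1)
  expect_equal(loci[[1]]$span_start, 1000)
  expect_equal(loci[[1]]$span_end, 5100)
  expect_equal(loci[[1]]$query_coverage, 1.0)
})

test_that("full-length classification requires coverage and both termini", {
  mk_locus <- function(qs, qe, qlen = 300) {
    h <- mk_hits(qs, qe, qs + 1000, qe + 1000, rep(100, length(qs)))
    chain_hits(h, setNames(qlen, "q"))[[1]]
  }
  expect_equal(classify_locus(mk_locus(0, 300)), "full_length")
  expect_equal(classify_locus(mk_locus(0, 210)), "partial")  # 70% coverage
  # 96% coverage but missing the 5' terminus beyond tolerance
  l <- mk_locus(40, 300)
  expect_equal(l$query_coverage, 260 / 300)
  expect_equal(classify_locus(mk_locus(12, 300),
                              rule = full_length_rule(min_coverage = 0.9,
                                                      end_tolerance = 10)),
               "partial")
  expect_equal(classify_locus(mk_locus(8, 300),
                              rule = full_length_rule(min_coverage = 0.9,
                                                      end_tolerance = 10)),
               "full_length")
})

test_that("matched regions merge overlapping loci per contig/strand", {
  mk_locus <- function(ts, te, query = "q", strand = "+") {
    h <- mk_hits(0, 300, ts, te, 500, strand = strand, query = query)
    chain_hits(h, setNames(300, query))[[1]]
  }
  r0 <- build_matched_regions(list())
  expect_equal(nrow(r0), 0L)

  l1 <- mk_locus(1000, 4000, "q1")
  l2 <- mk_locus(3000, 6000, "q2")   # overlaps l1 by 1 kb
  l3 <- mk_locus(20000, 23000, "q1")
  r <- build_matched_regions(list(l1, l2, l3))
  expect_equal(nrow(r), 2L)
  expect_equal(r$start, c(1000, 20000))
  expect_equal(r$end, c(6000, 23000))
  expect_equal(r$queries[1], "q1,q2")

  # opposite-strand overlap stays separate (inverted gene pairs)
  l4 <- mk_locus(1000, 4000, "q1", strand = "+")
  l5 <- mk_locus(2000, 5000, "q2", strand = "-")
  r2 <- build_matched_regions(list(l4, l5))
  expect_equal(nrow(r2), 2L)

  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_matched_regions_gtf(r, gtf)
  lines <- readLines(gtf)
  expect_length(lines, 2)
  f <- strsplit(lines[1], "\t")[[1]]
  expect_equal(f[3], "match")
  expect_equal(as.integer(f[4]), 1001L)  # 1-based inclusive
  expect_equal(as.integer(f[5]), 6000L)
})
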