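test_that("background generation is deterministic with the expected composition", {
  a <- generate_background(10000, gc = 0.4, seed = 1)
  b <- generate_background(10000, gc = 0.4, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, generate_background(10000, gc = 0.4, seed = 2)))
  expect_equal(nchar(generate_background(1, gc = 0.5, seed = 3)), 1L)

  # empirical GC within gc +/- 0.01 at large n (binomial concentration)
  big <- generate_background(3e5, gc = 0.42, seed = 4)
  gc_obs <- mean(strsplit(big, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_obs - 0.42), 0.01)
})

test_that("gene construction interleaves canonical introns with recorded layout", {
  cds <- random_cds(100, seed = 5)  # 300 nt
  g <- generate_toxin_gene(cds, intron_lengths = c(500, 800), seed = 6)
  expect_equal(nchar(g$seq), 300 + 500 + 800)
  expect_equal(nrow(g$exons), 3L)
  # splicing the layout back out returns the CDS
  expect_equal(paste(substring(g$seq, g$exons[, "start"] + 1,
                               g$exons[, "end"]), collapse = ""), cds)
  # every intron begins GT and ends AG
  for (i in 1:2) {
    istart <- g$exons[i, "end"]; iend <- g$exons[i + 1, "start"]
    expect_equal(substr(g$seq, istart + 1, istart + 2), "GT")
    expect_equal(substr(g$seq, iend - 1, iend), "AG")
  }
  # zero introns: gene equals the CDS
  g0 <- generate_toxin_gene(cds, integer(0), seed = 7)
  expect_equal(g0$seq, cds)
  expect_error(generate_toxin_gene(cds, 3L, seed = 8), "GT..AG")
})

test_that("CDS mutation hits the target identity and pseudogenization adds one in-frame stop", {
  cds <- random_cds(100, seed = 9)  # 300 nt
  expect_identical(mutate_cds(cds, 1.0, seed = 10), cds)

  m <- mutate_cds(cds, 0.90, seed = 11)
  id_real <- count_identity(cds, m)
  expect_gte(id_real, 0.88); expect_lte(id_real, 0.92)
  expect_true(validate_cds(m, min_len = 30)$valid)  # no accidental stops
  expect_identical(mutate_cds(cds, 0.90, seed = 11), m)  # deterministic

  p <- mutate_cds(cds, 1.0, seed = 12, pseudogenize = TRUE)
  v <- validate_cds(p, min_len = 30)
  expect_true("internal_stop" %in% v$reasons)
})

test_that("implantation round-trips CDSs through the genome on both strands", {
  bg <- c(ctgA = generate_background(30000, seed = 13))
  cds1 <- random_cds(90, seed = 14)
  cds2 <- random_cds(110, seed = 15)
  g1 <- generate_toxin_gene(cds1, c(200), seed = 16)
  g2 <- generate_toxin_gene(cds2, c(150, 300), seed = 17)
  fg <- implant(bg, list(g1, g2),
                data.frame(contig = "ctgA", pos = c(2000L, 12000L),
                           strand = c("+", "-"),
                           id = c("FAM1-1", "FAM2-1"),
                           family = c("FAM1", "FAM2"),
                           stringsAsFactors = FALSE))
  for (tg in fg$truth) {
    spliced <- splice_cds_from_genome(fg$genome, tg$contig, tg$strand,
                                      tg$exons)
    expect_equal(spliced, if (tg$id == "FAM1-1") cds1 else cds2)
  }
  # minus-strand truth exons are in transcription order (descending coords)
  minus <- fg$truth[[2]]
  expect_true(all(diff(minus$exons[, "start"]) < 0))

  # overlapping implants are rejected
  expect_error(
    implant(bg, list(g1, g1),
            data.frame(contig = "ctgA", pos = c(2000L, 2100L),
                       strand = c("+", "+"), stringsAsFactors = FALSE)),
    "overlap")
})

test_that("the default fixture is deterministic with disjoint truth and valid database", {
  fx1 <- make_fixture(seed = 21, genome_length = 2e5, n_genes = 8,
                      n_families = 3, n_pseudogenes = 1)
  fx2 <- make_fixture(seed = 21, genome_length = 2e5, n_genes = 8,
                      n_families = 3, n_pseudogenes = 1)
  expect_identical(fx1$genome, fx2$genome)
  expect_identical(fx1$db$records, fx2$db$records)
  expect_identical(fx1$transcripts, fx2$transcripts)
  expect_equal(length(fx1$truth), 8L)

  # truth round-trip: every implanted CDS splices back from the genome
  for (tg in fx1$truth)
    expect_equal(splice_cds_from_genome(fx1$genome, tg$contig, tg$strand,
                                        tg$exons), tg$cds)
  # pseudogenes carry an internal stop; all database records are valid
  for (tg in fx1$truth)
    expect_equal("internal_stop" %in%
                   validate_cds(tg$cds, min_len = 30)$reasons,
                 tg$is_pseudogene)
  for (i in seq_len(nrow(fx1$db$records)))
    expect_true(validate_cds(fx1$db$records$cds[i], min_len = 30)$valid)

  # written fixture: truth GTF re-splices byte-exactly via the GTF reader
  dir <- withr::local_tempdir()
  paths <- write_fixture(fx1, dir)
  models <- read_annotation_gtf(paths[["truth"]],
                                genome = read_genome(paths[["genome"]]))
  cds_by_id <- setNames(vapply(models, `[[`, character(1), "cds"),
                        vapply(models, `[[`, character(1), "id"))
  for (tg in fx1$truth) expect_equal(unname(cds_by_id[tg$id]), tg$cds)
})
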