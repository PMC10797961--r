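test_that("pairwise identity matches counting and alignment oracles", {
  expect_equal(pairwise_identity("ACGTACGTAC", "ACGTACGTAC"), 1.0)
  expect_equal(pairwise_identity("AAAA", "AAAT"), 0.75)

  cds <- random_cds(100, seed = 31)         # 300 nt
  mut <- sub_mutate(cds, 3, seed = 32)
  expect_equal(pairwise_identity(cds, mut), 0.99)
  expect_equal(pairwise_identity(cds, mut), count_identity(cds, mut))

  # symmetry on random pairs of unequal length
  for (s in 1:5) {
    a <- rand_dna(120 + 7 * s, seed = 40 + s)
    b <- rand_dna(150, seed = 50 + s)
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("seed index covers both strands and excludes N k-mers", {
  idx <- build_seed_index(c(chr = "ACGTACGT"), k = 4)
  q <- query_seeds(idx, "ACGT")
  plus <- q[q$strand == "+", ]
  expect_setequal(plus$pos, c(0, 4))

  # k-mers containing N are not indexed
  idx2 <- build_seed_index(c(chr = "ACGTNACGT"), k = 4)
  expect_equal(nrow(query_seeds(idx2, "GTNA")), 0L)

  # reverse-complemented genome mirrors the strands of the original index
  g <- rand_dna(200, seed = 61)
  idx_f <- build_seed_index(c(chr = g), k = 6)
  idx_r <- build_seed_index(c(chr = rc(g)), k = 6)
  kmer <- substr(g, 11, 16)
  qf <- query_seeds(idx_f, kmer)
  qr <- query_seeds(idx_r, kmer)
  expect_equal(sum(qf$strand == "+"), sum(qr$strand == "-"))
  expect_equal(sum(qf$strand == "-"), sum(qr$strand == "+"))
})

test_that("search finds verbatim and reverse-complemented insertions with exact coordinates", {
  bg <- rand_dna(5000, seed = 71)
  q <- random_cds(100, seed = 72)  # 300 nt
  genome_f <- paste0(substr(bg, 1, 1000), q, substr(bg, 1301, 5000))
  db <- toxin_db(id = "q1", family = "F", cds = q, min_cds_len = 30)

  h <- search_hits(db, c(ctg = genome_f))
  expect_equal(nrow(h), 1L)
  expect_equal(h$strand, "+")
  expect_equal(h$identity, 1.0)
  expect_equal(c(h$tstart, h$tend, h$qstart, h$qend), c(1000, 1300, 0, 300))

  genome_r <- paste0(substr(bg, 1, 1000), rc(q), substr(bg, 1301, 5000))
  hr <- search_hits(db, c(ctg = genome_r))
  expect_equal(nrow(hr), 1L)
  expect_equal(hr$strand, "-")
  expect_equal(c(hr$tstart, hr$tend, hr$qstart, hr$qend), c(1000, 1300, 0, 300))

  # a random query finds nothing in an unrelated background
  h0 <- search_hits(toxin_db("r", "F", random_cds(100, seed = 73),
                             min_cds_len = 30),
                    c(bg = rand_dna(100000, seed = 74)))
  expect_equal(nrow(h0), 0L)
})

test_that("hit coordinates round-trip to the reported identity", {
  bg <- rand_dna(8000, seed = 81)
  cds <- random_cds(150, seed = 82)          # 450 nt
  mut <- sub_mutate(cds, 20, seed = 83)      # diverged homolog in the genome
  genome <- paste0(substr(bg, 1, 3000), mut, substr(bg, 3451, 8000))
  db <- toxin_db(id = "q", family = "F", cds = cds, min_cds_len = 30)
  h <- search_hits(db, c(ctg = genome))
  expect_gte(nrow(h), 1L)
  for (i in seq_len(nrow(h))) {
    tseg <- substr(genome, h$tstart[i] + 1, h$tend[i])
    if (h$strand[i] == "-") tseg <- rc(tseg)
    qseg <- substr(cds, h$qstart[i] + 1, h$qend[i])
    expect_equal(count_identity(qseg, tseg), h$identity[i])
  }
})

test_that("strand symmetry: reverse-complementing the genome flips and mirrors hits", {
  bg <- rand_dna(6000, seed = 91)
  q <- random_cds(120, seed = 92)
  genome <- paste0(substr(bg, 1, 2000), q, substr(bg, 2361, 6000))
  glen <- nchar(genome)
  db <- toxin_db(id = "q", family = "F", cds = q, min_cds_len = 30)
  h1 <- search_hits(db, c(ctg = genome))
  h2 <- search_hits(db, c(ctg = rc(genome)))
  expect_equal(nrow(h1), nrow(h2))
  o1 <- order(h1$tstart); o2 <- order(glen - h2$tend)
  expect_equal(h1$tstart[o1], (glen - h2$tend)[o2])
  expect_equal(h1$tend[o1], (glen - h2$tstart)[o2])
  expect_true(all(h1$strand[o1] != h2$strand[o2]))
})

test_that("best local alignment score agrees with an independent quadratic oracle on short windows", {
  for (s in 1:4) {
    a <- rand_dna(300, seed = 200 + s)
    core <- substr(a, 51, 250)
    noisy <- sub_mutate(paste0("ATG", core, "TGA"), 12, seed = 300 + s)
    b <- paste0(rand_dna(400, seed = 400 + s), noisy,
                rand_dna(400, seed = 500 + s))
    got <- .sw_local_cpp(a, b)
    want <- biostrings_local_score(a, b)
    expect_equal(got$score, as.integer(want))
  }
})

test_that("BLAST outfmt-6 import/export round-trips the internal convention", {
  bg <- rand_dna(5000, seed = 101)
  q <- random_cds(100, seed = 102)
  genome <- paste0(substr(bg, 1, 800), rc(q), substr(bg, 1101, 2500),
                   q, substr(bg, 2801, 5000))
  db <- toxin_db(id = "q", family = "F", cds = q, min_cds_len = 30)
  h <- search_hits(db, c(ctg = genome))
  expect_setequal(unique(h$strand), c("-", "+"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_blast_hits(h, tsv)
  h2 <- read_blast_hits(tsv)
  expect_equal(h2$tstart, h$tstart)
  expect_equal(h2$tend, h$tend)
  expect_equal(h2$qstart, h$qstart)
  expect_equal(h2$qend, h$qend)
  expect_equal(h2$strand, h$strand)
  expect_equal(h2$score, h$score)
})
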