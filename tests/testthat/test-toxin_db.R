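test_that("validate_cds applies the full-length CDS grammar and reports all failures", {
  expect_true(validate_cds("ATGGCTTGA", min_len = 9)$valid)

  # a 196-nt CDS is below the 200-bp default minimum
  cds196 <- paste0("ATG", strrep("GCT", 63), "TGAT")  # 3+189+4 = 196
  v <- validate_cds(cds196, min_len = 200)
  expect_false(v$valid)
  expect_true("below_min_length" %in% v$reasons)

  v <- validate_cds("ATGTAAAAATGA", min_len = 12)
  expect_false(v$valid)
  expect_true("internal_stop" %in% v$reasons)

  # multiple simultaneous failures are all reported
  v <- validate_cds("CCCTAACCCC", min_len = 50)
  expect_setequal(v$reasons, c("no_start", "no_terminal_stop",
                               "internal_stop", "not_codon_multiple",
                               "below_min_length"))
  expect_false(validate_cds("ATGNNNTGA", min_len = 3)$valid)
})

test_that("family tags parse from pipe headers and bare ids", {
  expect_equal(parse_family("Bjar012|SVMP"), "SVMP")
  expect_equal(parse_family(c("PLA2-3", "CTL_12", "LAO")),
               c("PLA2", "CTL", "LAO"))
})

test_that("invalid records are dropped with a warning, not an error", {
  expect_warning(
    db <- toxin_db(id = c("good", "bad"), family = c("A", "B"),
                   cds = c("ATGGCTTGA", "ATGTAAGCTTGA"),
                   min_cds_len = 9),
    "internal_stop")
  expect_equal(db$records$id, "good")
})

test_that("greedy identity clustering partitions records and honors the threshold", {
  a <- random_cds(100, seed = 5)
  b <- sub_mutate(a, 1, seed = 6)    # 1 substitution: 299/300 identity
  c_ <- sub_mutate(a, 10, seed = 7)  # 10 substitutions: 290/300

  # oracle check of the derived identities
  expect_equal(count_identity(a, b), 299 / 300)
  expect_equal(pairwise_identity(a, b), 299 / 300)
  expect_equal(pairwise_identity(a, c_), 290 / 300)

  db <- toxin_db(id = c("A", "B", "C"), family = rep("F", 3),
                 cds = c(a, b, c_), min_cds_len = 30)
  cl <- cluster_by_identity(db, threshold = 0.99)
  expect_length(cl$clusters, 2)
  sizes <- sort(vapply(cl$clusters, function(x) length(x$members), 1L))
  expect_equal(sizes, c(1L, 2L))
  two <- cl$clusters[[which(vapply(cl$clusters, function(x)
    length(x$members), 1L) == 2L)]]
  expect_setequal(two$members, c("A", "B"))

  # identical records always cluster together
  db2 <- toxin_db(id = c("x", "y"), family = c("F", "F"),
                  cds = c(a, a), min_cds_len = 30)
  cl2 <- cluster_by_identity(db2, threshold = 0.99)
  expect_length(cl2$clusters, 1)

  # threshold 1 with mutually distinct records: all singletons
  cl3 <- cluster_by_identity(db, threshold = 1.0)
  expect_length(cl3$clusters, 3)

  # partition + representative-identity invariants on a random database
  set.seed(42)
  cds <- vapply(1:8, function(i) random_cds(60, seed = 100 + i), character(1))
  cds <- c(cds, vapply(1:4, function(i) sub_mutate(cds[i], 1, 300 + i),
                       character(1)))
  dbr <- toxin_db(id = sprintf("r%02d", seq_along(cds)),
                  family = rep("F", length(cds)), cds = cds, min_cds_len = 30)
  clr <- cluster_by_identity(dbr, threshold = 0.99)
  members <- unlist(lapply(clr$clusters, `[[`, "members"))
  expect_setequal(members, dbr$records$id)       # partition: every record once
  expect_equal(anyDuplicated(members), 0L)
  for (cl in clr$clusters) {                     # member-representative identity
    rep_cds <- dbr$records$cds[dbr$records$id == cl$representative]
    for (m in cl$members) {
      m_cds <- dbr$records$cds[dbr$records$id == m]
      expect_gte(pairwise_identity(m_cds, rep_cds), 0.99)
    }
  }
  # every representative is itself a valid CDS
  for (i in seq_len(nrow(clr$representatives$records)))
    expect_true(validate_cds(clr$representatives$records$cds[i],
                             min_len = 30)$valid)
})

test_that("database merging deduplicates sequences and renames id collisions", {
  a <- random_cds(80, seed = 11)
  b <- random_cds(90, seed = 12)
  db <- toxin_db(id = c("A", "B"), family = c("F1", "F2"), cds = c(a, b),
                 min_cds_len = 30)
  empty <- suppressWarnings(toxin_db(character(0), character(0), character(0)))

  m <- merge_databases(db, empty)
  expect_equal(m$records$id, db$records$id)
  expect_equal(m$records$cds, db$records$cds)

  m2 <- merge_databases(db, db)  # two copies of the same records
  expect_equal(nrow(m2$records), 2L)

  other <- toxin_db(id = "A", family = "F3", cds = random_cds(70, seed = 13),
                    min_cds_len = 30)
  m3 <- merge_databases(db, other)
  expect_equal(nrow(m3$records), 3L)
  expect_setequal(m3$records$id, c("A", "B", "A.1"))
})

test_that("FASTA round trip preserves ids, families and sequences", {
  db <- toxin_db(id = c("tox1", "tox2"), family = c("SVMP", "PLA2"),
                 cds = c(random_cds(80, seed = 21), random_cds(90, seed = 22)),
                 min_cds_len = 30)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_toxin_db(db, fa)
  db2 <- read_toxin_db(fa, min_cds_len = 30)
  expect_equal(db2$records$family, db$records$family)
  expect_equal(db2$records$cds, db$records$cds)

  man <- withr::local_tempfile(fileext = ".tsv")
  cl <- cluster_by_identity(db, 0.99)
  write_db_manifest(db, man, clusters = cl)
  tab <- read.delim(man)
  expect_equal(nrow(tab), 2L)
  expect_true(all(c("id", "family", "length", "cluster_id") %in% names(tab)))
})
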