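# run expr with a temporary, fully specified RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  expr
}

#' Generate i.i.d. background genomic sequence
#'
#' @param length Sequence length in nucleotides.
#' @param gc Expected GC fraction in (0, 1).
#' @param seed Integer seed; the output is a deterministic function of
#'   (length, gc, seed).
#' @return A nucleotide string.
#' @export
generate_background <- function(length, gc = 0.42, seed = 1L) {
  stopifnot(length > 0, gc > 0, gc < 1)
  with_seed(seed, paste(sample(c("A", "T", "G", "C"), length, replace = TRUE,
                               prob = c((1 - gc) / 2, (1 - gc) / 2,
                                        gc / 2, gc / 2)),
                        collapse = ""))
}

# random full-length CDS: ATG + non-stop codons + stop
random_cds <- function(n_codons, seed = 1L) {
  stopifnot(n_codons >= 3)
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    codons <- character(n_codons - 2L)
    for (i in seq_along(codons)) {
      repeat {
        cd <- paste(sample(bases, 3L, replace = TRUE), collapse = "")
        if (!cd %in% c("TAA", "TAG", "TGA")) break
      }
      codons[i] <- cd
    }
    paste0("ATG", paste(codons, collapse = ""),
           sample(c("TAA", "TAG", "TGA"), 1L))
  })
}

#' Build a multi-exon toxin gene around a CDS
#'
#' Splits the CDS at random interior points (not necessarily at codon
#' boundaries) and interleaves introns that begin GT and end AG with random
#' interiors, emulating the multi-exon structure of toxin genes.
#'
#' @param cds Full-length CDS string.
#' @param intron_lengths Integer vector of intron lengths (>= 4 each; one
#'   intron per internal junction). Empty for a single-exon gene.
#' @param seed Integer seed.
#' @param min_exon Minimum exon length when choosing split points
#'   (default 40 bp, the lower end of real toxin exon sizes).
#' @return List with `seq` (gene sequence), `exons` (matrix of 0-based
#'   half-open gene-local exon intervals, transcription order) and `cds`.
#' @export
generate_toxin_gene <- function(cds, intron_lengths = integer(0), seed = 1L,
                                min_exon = 40L) {
  L <- nchar(cds)
  k <- length(intron_lengths)
  if (k > 0 && any(intron_lengths < 4L))
    stop("introns shorter than 4 bp cannot carry GT..AG")
  with_seed(seed, {
    if (k > 0) {
      slack <- L - (k + 1L) * min_exon
      if (slack < 0L) stop("CDS too short for requested exon count")
      # k split points with every exon >= min_exon, by direct construction
      splits <- min_exon * seq_len(k) +
        sort(sample.int(slack + 1L, k, replace = TRUE) - 1L)
    } else splits <- integer(0)
    bounds <- c(0L, splits, L)
    exon_seqs <- substring(cds, bounds[-length(bounds)] + 1L, bounds[-1L])
    introns <- vapply(intron_lengths, function(il) {
      interior <- if (il > 4L)
        paste(sample(c("A", "C", "G", "T"), il - 4L, replace = TRUE),
              collapse = "")
      else ""
      paste0("GT", interior, "AG")
    }, character(1))
    pieces <- character(0)
    exons <- matrix(0L, nrow = length(exon_seqs), ncol = 2,
                    dimnames = list(NULL, c("start", "end")))
    cur <- 0L
    for (i in seq_along(exon_seqs)) {
      exons[i, ] <- c(cur, cur + nchar(exon_seqs[i]))
      pieces <- c(pieces, exon_seqs[i])
      cur <- cur + nchar(exon_seqs[i])
      if (i <= length(introns)) {
        pieces <- c(pieces, introns[i])
        cur <- cur + nchar(introns[i])
      }
    }
    list(seq = paste(pieces, collapse = ""), exons = exons, cds = cds)
  })
}

#' Mutate a CDS to a target identity
#'
#' Substitution-only divergence (no indels) at positions outside the start
#' codon and the terminal stop. Substitutions that would create an in-frame
#' stop are re-drawn, so a non-pseudogenized output is still a valid
#' full-length CDS. With `pseudogenize = TRUE`, exactly one interior codon
#' is additionally rewritten to a stop codon, emulating a truncated paralog
#' or pseudogene.
#'
#' @param cds Full-length CDS string.
#' @param target_identity Fraction in `[0.5, 1]`; realized identity is
#'   within 0.02 of the target (exact when the substitution count rounds
#'   cleanly).
#' @param seed Integer seed.
#' @param pseudogenize Insert one premature in-frame stop.
#' @return The diverged CDS string.
#' @export
mutate_cds <- function(cds, target_identity = 0.9, seed = 1L,
                       pseudogenize = FALSE) {
  stopifnot(target_identity >= 0.5, target_identity <= 1)
  L <- nchar(cds)
  stops <- c("TAA", "TAG", "TGA")
  with_seed(seed, {
    x <- strsplit(cds, "")[[1]]
    n_sub <- round((1 - target_identity) * L)
    mutable <- seq.int(4L, L - 3L)
    if (n_sub > 0L) {
      pos <- sort(sample(mutable, min(n_sub, length(mutable))))
      for (p in pos) {
        x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1L)
      }
      # repair accidental in-frame stops (keep the position substituted)
      repeat {
        codon_starts <- seq.int(4L, L - 5L, 3L)
        codons <- vapply(codon_starts, function(s)
          paste(x[s:(s + 2L)], collapse = ""), character(1))
        bad <- codon_starts[codons %in% stops]
        bad <- bad[vapply(bad, function(s) any(pos >= s & pos <= s + 2L), TRUE)]
        if (length(bad) == 0L) break
        for (s in bad) {
          p <- pos[pos >= s & pos <= s + 2L][1L]
          orig <- substr(cds, p, p)
          for (alt in setdiff(c("A", "C", "G", "T"), c(orig, x[p]))) {
            x[p] <- alt
            cand <- paste(x[s:(s + 2L)], collapse = "")
            if (!cand %in% stops) break
          }
        }
      }
    }
    if (pseudogenize) {
      codon_idx <- sample(seq.int(2L, L %/% 3L - 1L), 1L)
      s <- (codon_idx - 1L) * 3L + 1L
      x[s:(s + 2L)] <- strsplit(sample(stops, 1L), "")[[1]]
    }
    paste(x, collapse = "")
  })
}

#' Implant genes into a background genome
#'
#' Replaces disjoint background segments with gene sequences
#' (reverse-complemented for minus-strand implants) and records the truth:
#' exon intervals in genome coordinates (transcription order), the CDS and
#' the pseudogene flag of every implanted gene.
#'
#' @param background Named character vector of background contigs.
#' @param genes List of gene layouts from [generate_toxin_gene()].
#' @param positions data.frame with columns `contig`, `pos` (0-based
#'   implant start), `strand`, and optionally `id`, `family`,
#'   `is_pseudogene`.
#' @return List of class `toxin_fixture_genome`: `genome` (named character)
#'   and `truth` (list of per-gene entries: id, family, contig, strand,
#'   exons matrix in transcription order, cds, is_pseudogene).
#' @export
implant <- function(background, genes, positions) {
  stopifnot(length(genes) == nrow(positions))
  genome <- toupper(background)
  if (is.null(positions$id))
    positions$id <- sprintf("gene_%d", seq_len(nrow(positions)))
  if (is.null(positions$family)) positions$family <- parse_family(positions$id)
  if (is.null(positions$is_pseudogene)) positions$is_pseudogene <- FALSE
  # disjointness check per contig
  iv <- data.frame(contig = positions$contig, start = positions$pos,
                   end = positions$pos +
                     vapply(genes, function(g) nchar(g$seq), numeric(1)))
  for (ct in unique(iv$contig)) {
    sub <- iv[iv$contig == ct, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)]))
      stop("implant intervals overlap on contig ", ct)
    if (any(sub$start < 0L) || any(sub$end > nchar(genome[[ct]])))
      stop("implant interval outside contig ", ct)
  }
  truth <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    ct <- positions$contig[i]; pos <- positions$pos[i]
    strand <- positions$strand[i]
    glen <- nchar(g$seq)
    seq_in <- if (strand == "+") g$seq else revcomp(g$seq)
    genome[[ct]] <- paste0(substr(genome[[ct]], 1L, pos), seq_in,
                           substr(genome[[ct]], pos + glen + 1L,
                                  nchar(genome[[ct]])))
    exons <- g$exons
    gexons <- if (strand == "+") cbind(start = pos + exons[, "start"],
                                       end = pos + exons[, "end"])
    else cbind(start = pos + glen - exons[, "end"],
               end = pos + glen - exons[, "start"])
    truth[[i]] <- list(id = positions$id[i], family = positions$family[i],
                       contig = ct, strand = strand, exons = gexons,
                       cds = g$cds,
                       is_pseudogene = positions$is_pseudogene[i])
  }
  structure(list(genome = genome, truth = truth),
            class = "toxin_fixture_genome")
}

default_families <- function(n) {
  base <- c("SVMP", "SVSP", "PLA2", "CTL", "TFTX", "LAO", "CRISP", "KUN")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("FAM%d", seq_len(n - length(base))))
}

#' Generate the default synthetic benchmark fixture
#'
#' Builds a deterministic synthetic genome with implanted multi-exon toxin
#' genes, diverged within-family paralogs and pseudogenes, together with
#' the exact-CDS toxin database, venom-tissue-like transcripts (CDS plus
#' random UTRs) and machine-readable truth. Defaults emulate a small
#' venomous-lineage assembly: a 1-Mb genome in two contigs carrying 20
#' genes from 5 families (tandem-array style paralogs at ~90% identity,
#' 1-8 exons, introns 60-3000 bp, 2 pseudogenes).
#'
#' @param seed Integer master seed; every random choice derives from it.
#' @param genome_length,n_contigs,gc Background geometry and composition.
#' @param n_genes,n_families Number of implanted genes and families.
#' @param codon_range Range of CDS lengths in codons.
#' @param exon_range Range of exon counts per gene.
#' @param intron_range Range of intron lengths (bp).
#' @param paralog_identity Identity of within-family paralogs to the family
#'   prototype CDS.
#' @param n_pseudogenes Number of implanted pseudogenes. Each is a recently
#'   inactivated copy: its CDS derives from a functional family member at
#'   `pseudogene_identity` plus one premature in-frame stop, matching the
#'   truncated-paralog pattern of toxin tandem arrays.
#' @param pseudogene_identity Identity of a pseudogene to the functional
#'   family member it derives from.
#' @param db_identity Identity of the database records to the implanted
#'   CDSs (1 = the database holds the exact implanted CDSs; lower values
#'   emulate a cross-species database of diverged homologs).
#' @param utr_range Range of UTR lengths flanking each transcript CDS.
#' @return An object of class `toxin_fixture`: list with `genome`, `db`,
#'   `truth`, `transcripts`, `params`, `seed`.
#' @export
make_fixture <- function(seed = 1L,
                         genome_length = 1e6, n_contigs = 2L, gc = 0.42,
                         n_genes = 20L, n_families = 5L,
                         codon_range = c(90L, 320L),
                         exon_range = c(1L, 8L),
                         intron_range = c(60L, 3000L),
                         paralog_identity = 0.90,
                         n_pseudogenes = 2L,
                         pseudogene_identity = 0.98,
                         db_identity = 1.0,
                         utr_range = c(50L, 150L)) {
  seed <- as.integer(seed)
  fams <- default_families(n_families)
  clen <- as.integer(genome_length %/% n_contigs)
  background <- setNames(
    vapply(seq_len(n_contigs), function(i)
      generate_background(clen, gc, seed = seed + 1000L + i), character(1)),
    sprintf("contig_%d", seq_len(n_contigs)))

  protos <- with_seed(seed + 2000L, {
    nc <- sample(seq.int(codon_range[1], codon_range[2]), n_families,
                 replace = TRUE)
    lapply(seq_len(n_families), function(i)
      random_cds(nc[i], seed = seed + 3000L + i))
  })

  fam_of_gene <- rep(seq_len(n_families), length.out = n_genes)
  # pseudogenes are never the sole/first member of a family: they derive
  # from a functional sibling whose exact CDS exists
  eligible <- which(seq_len(n_genes) != match(fam_of_gene, fam_of_gene))
  pseudo <- with_seed(seed + 4000L,
                      sample(eligible, min(n_pseudogenes, length(eligible))))
  layout <- with_seed(seed + 5000L, {
    n_exons <- sample(seq.int(exon_range[1], exon_range[2]), n_genes,
                      replace = TRUE)
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
    list(n_exons = n_exons, strands = strands)
  })

  genes <- vector("list", n_genes)
  cdss <- character(n_genes)
  for (i in seq_len(n_genes)) {
    proto <- protos[[fam_of_gene[i]]]
    first_of_family <- i == match(fam_of_gene[i], fam_of_gene)
    cdss[i] <- if (first_of_family) proto
    else mutate_cds(proto, target_identity = paralog_identity,
                    seed = seed + 6000L + i)
  }
  for (i in pseudo) {
    base <- cdss[match(fam_of_gene[i], fam_of_gene)]
    cdss[i] <- mutate_cds(base, target_identity = pseudogene_identity,
                          seed = seed + 6000L + i, pseudogenize = TRUE)
  }
  for (i in seq_len(n_genes)) {
    cds <- cdss[i]
    # exon count capped by what the CDS length can hold at the minimum
    # exon size (40 bp)
    n_intr <- min(layout$n_exons[i], nchar(cds) %/% 40L) - 1L
    intr <- if (n_intr > 0L)
      with_seed(seed + 7000L + i,
                sample(seq.int(intron_range[1], intron_range[2]), n_intr,
                       replace = TRUE))
    else integer(0)
    genes[[i]] <- generate_toxin_gene(cds, intr, seed = seed + 8000L + i)
  }

  # sequential placement with random spacing, alternating contigs
  positions <- with_seed(seed + 9000L, {
    contig <- character(n_genes); pos <- integer(n_genes)
    cursor <- setNames(rep(5000L, n_contigs), names(background))
    for (i in seq_len(n_genes)) {
      ct <- names(background)[(i - 1L) %% n_contigs + 1L]
      gap <- sample(3000:8000, 1L)
      p <- cursor[[ct]] + gap
      glen <- nchar(genes[[i]]$seq)
      if (p + glen > clen - 5000L)
        stop("fixture genome too small for requested genes")
      contig[i] <- ct; pos[i] <- p
      cursor[[ct]] <- p + glen
    }
    data.frame(contig = contig, pos = pos, stringsAsFactors = FALSE)
  })
  positions$strand <- layout$strands
  fam_counter <- stats::ave(fam_of_gene, fam_of_gene, FUN = seq_along)
  positions$id <- sprintf("%s-%d", fams[fam_of_gene], fam_counter)
  positions$family <- fams[fam_of_gene]
  positions$is_pseudogene <- seq_len(n_genes) %in% pseudo

  fg <- implant(background, genes, positions)

  db_cds <- if (db_identity >= 1.0) cdss
  else vapply(seq_len(n_genes), function(i)
    mutate_cds(cdss[i], db_identity, seed = seed + 10000L + i), character(1))
  db <- suppressWarnings(
    toxin_db(id = paste0("db_", positions$id), family = positions$family,
             cds = db_cds, source = "fixture database",
             min_cds_len = 30L))

  transcripts <- with_seed(seed + 11000L, {
    tr <- vapply(seq_len(n_genes), function(i) {
      u5 <- paste(sample(c("A", "C", "G", "T"),
                         sample(seq.int(utr_range[1], utr_range[2]), 1L),
                         replace = TRUE), collapse = "")
      u3 <- paste(sample(c("A", "C", "G", "T"),
                         sample(seq.int(utr_range[1], utr_range[2]), 1L),
                         replace = TRUE), collapse = "")
      paste0(u5, cdss[i], u3)
    }, character(1))
    setNames(tr, paste0("transcript_", positions$id))
  })

  structure(list(genome = fg$genome, db = db, truth = fg$truth,
                 transcripts = transcripts,
                 params = list(genome_length = genome_length,
                               n_contigs = n_contigs, gc = gc,
                               n_genes = n_genes, n_families = n_families,
                               codon_range = codon_range,
                               exon_range = exon_range,
                               intron_range = intron_range,
                               paralog_identity = paralog_identity,
                               n_pseudogenes = n_pseudogenes,
                               pseudogene_identity = pseudogene_identity,
                               db_identity = db_identity),
                 seed = seed),
            class = "toxin_fixture")
}

#' @export
print.toxin_fixture <- function(x, ...) {
  cat(sprintf("synthetic fixture (seed %d): %d contig(s), %d genes (%d pseudogenes), %d families\n",
              x$seed, length(x$genome), length(x$truth),
              sum(vapply(x$truth, `[[`, TRUE, "is_pseudogene")),
              length(unique(vapply(x$truth, `[[`, character(1), "family")))))
  invisible(x)
}

#' Reference gene table of a fixture (for evaluation)
#'
#' @param fixture A `toxin_fixture` (or the `truth` list of one).
#' @return data.frame usable as the `reference` argument of
#'   [evaluate_annotation()].
#' @export
reference_from_truth <- function(fixture) {
  truth <- if (inherits(fixture, "toxin_fixture") ||
               inherits(fixture, "toxin_fixture_genome")) fixture$truth
  else fixture
  do.call(rbind, lapply(truth, function(g)
    data.frame(gene_id = g$id, contig_id = g$contig, strand = g$strand,
               start = min(g$exons[, "start"]), end = max(g$exons[, "end"]),
               family = g$family, stringsAsFactors = FALSE)))
}

#' Write a fixture to disk (genome FASTA, database FASTA, truth GTF)
#'
#' The truth GTF uses the same dialect as the pipeline's annotation output,
#' so truth and prediction can be compared with the same readers.
#'
#' @param fixture A `toxin_fixture`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome_fa <- file.path(dir, "genome.fasta")
  db_fa <- file.path(dir, "database.fasta")
  truth_gtf <- file.path(dir, "truth.gtf")
  tr_fa <- file.path(dir, "transcripts.fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(fixture$genome),
                              genome_fa, width = 60L)
  write_toxin_db(fixture$db, db_fa)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(fixture$transcripts),
                              tr_fa, width = 60L)
  models <- lapply(fixture$truth, function(g) {
    exon_lens <- g$exons[, "end"] - g$exons[, "start"]
    structure(list(id = g$id, contig_id = g$contig, strand = g$strand,
                   exons = g$exons, phases = exon_phases(exon_lens),
                   cds = g$cds, peptide = NULL,
                   status = if (g$is_pseudogene) "warning" else "reliable",
                   source_query = g$id, family = g$family,
                   score = 0L, identity = 1),
              class = "gene_model")
  })
  write_annotation_gtf(models, truth_gtf)
  invisible(c(genome = genome_fa, db = db_fa, truth = truth_gtf,
              transcripts = tr_fa))
}
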