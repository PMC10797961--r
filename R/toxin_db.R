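#' Validate a coding sequence
#'
#' Checks the canonical full-length CDS grammar used throughout the pipeline:
#' ATG start, terminal stop codon (TAA/TAG/TGA), codon-multiple length, no
#' in-frame internal stop, alphabet restricted to A/C/G/T, and a minimum
#' length. All applicable failure reasons are reported, not just the first.
#'
#' @param seq Nucleotide string.
#' @param min_len Minimum CDS length in nucleotides (default 200, matching
#'   the pipeline's default minimum CDS size).
#' @return A list of class `cds_validation` with elements `valid` (logical)
#'   and `reasons` (character vector drawn from `no_start`,
#'   `no_terminal_stop`, `internal_stop`, `not_codon_multiple`,
#'   `below_min_length`, `bad_alphabet`).
#' @examples
#' validate_cds("ATGGCTTGA", min_len = 9)$valid
#' validate_cds(strrep("A", 196), min_len = 200)$reasons
#' @export
validate_cds <- function(seq, min_len = 200L) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  seq <- toupper(seq)
  reasons <- character(0)
  n <- nchar(seq)
  if (grepl("[^ACGT]", seq)) reasons <- c(reasons, "bad_alphabet")
  if (n < min_len) reasons <- c(reasons, "below_min_length")
  if (n %% 3L != 0L) reasons <- c(reasons, "not_codon_multiple")
  if (n < 3L || substr(seq, 1L, 3L) != "ATG") reasons <- c(reasons, "no_start")
  stops <- c("TAA", "TAG", "TGA")
  if (n %% 3L == 0L && n >= 3L) {
    codons <- substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
    if (!codons[length(codons)] %in% stops)
      reasons <- c(reasons, "no_terminal_stop")
    if (length(codons) > 1L && any(codons[-length(codons)] %in% stops))
      reasons <- c(reasons, "internal_stop")
  } else if (n >= 3L) {
    # frame is anchored at position 1 even when the length is off-frame
    codons <- substring(seq, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
    if (length(codons) > 1L && any(codons[-length(codons)] %in% stops))
      reasons <- c(reasons, "internal_stop")
    if (!codons[length(codons)] %in% stops)
      reasons <- c(reasons, "no_terminal_stop")
  }
  structure(list(valid = length(reasons) == 0L, reasons = reasons),
            class = "cds_validation")
}

#' @export
print.cds_validation <- function(x, ...) {
  if (x$valid) cat("valid full-length CDS\n")
  else cat("invalid CDS:", paste(x$reasons, collapse = ", "), "\n")
  invisible(x)
}

#' Parse a toxin-family tag from a FASTA identifier
#'
#' The family is the token after the last `|` when the id contains one
#' (e.g. `"Bjar012|SVMP"` -> `"SVMP"`), otherwise the id stripped of
#' trailing digits and hyphens/underscores (`"PLA2-3"` -> `"PLA2"`; a
#' trailing letter block such as the `2` in `PLA2` is kept because it is
#' preceded by a letter group match).
#'
#' @param id Character vector of sequence identifiers.
#' @return Character vector of family tags.
#' @export
parse_family <- function(id) {
  out <- character(length(id))
  has_pipe <- grepl("|", id, fixed = TRUE)
  out[has_pipe] <- sub(".*\\|", "", id[has_pipe])
  bare <- sub("[-_][0-9]+$", "", id[!has_pipe])
  bare <- sub("[-_]+$", "", bare)
  out[!has_pipe] <- bare
  out
}

#' Construct a toxin database
#'
#' A toxin database is an ordered collection of full-length toxin CDS
#' records (id, family, sequence). Records failing [validate_cds()] are
#' dropped with a warning rather than aborting, because public sequence
#' sets are noisy.
#'
#' @param id,family,cds Parallel character vectors.
#' @param source Provenance string.
#' @param min_cds_len Minimum CDS length passed to [validate_cds()].
#' @return An object of class `toxin_db`: a list with `records` (data.frame
#'   with columns id, family, cds, length) and `source`.
#' @export
toxin_db <- function(id, family, cds, source = "in-memory", min_cds_len = 200L) {
  stopifnot(length(id) == length(family), length(id) == length(cds))
  cds <- toupper(cds)
  if (anyDuplicated(id)) stop("duplicated record ids in toxin database")
  keep <- logical(length(id))
  for (i in seq_along(id)) {
    v <- validate_cds(cds[i], min_len = min_cds_len)
    keep[i] <- v$valid
    if (!v$valid)
      warning(sprintf("dropping record '%s': %s", id[i],
                      paste(v$reasons, collapse = ", ")), call. = FALSE)
  }
  rec <- data.frame(id = id[keep], family = family[keep], cds = cds[keep],
                    length = nchar(cds[keep]), stringsAsFactors = FALSE)
  structure(list(records = rec, source = source), class = "toxin_db")
}

#' @export
print.toxin_db <- function(x, ...) {
  cat(sprintf("toxin database: %d full-length CDSs, %d families (source: %s)\n",
              nrow(x$records), length(unique(x$records$family)), x$source))
  invisible(x)
}

#' @export
length.toxin_db <- function(x) nrow(x$records)

#' Read a toxin-CDS database from FASTA
#'
#' Family tags are parsed from the FASTA headers with [parse_family()].
#' Records failing the full-length CDS grammar are dropped with a warning.
#'
#' @param path FASTA file of full-length toxin CDSs.
#' @param min_cds_len Minimum CDS length in nucleotides.
#' @return A `toxin_db` object.
#' @export
read_toxin_db <- function(path, min_cds_len = 200L) {
  if (!file.exists(path)) stop_input("toxin database file not found: ", path)
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) stop_input("malformed FASTA: ", path))
  if (length(ss) == 0L) stop_input("empty toxin database: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  toxin_db(id = ids, family = parse_family(ids),
           cds = as.character(ss), source = path,
           min_cds_len = min_cds_len)
}

#' Write a toxin database to FASTA
#'
#' Headers are written as `id|FAMILY` (unless the id already carries the
#' family as its last `|`-token), wrapped at 60 columns, so that
#' [read_toxin_db()] round-trips id and family.
#'
#' @param db A `toxin_db`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_toxin_db <- function(db, path) {
  stopifnot(inherits(db, "toxin_db"))
  rec <- db$records
  hdr <- ifelse(parse_family(rec$id) == rec$family, rec$id,
                paste0(rec$id, "|", rec$family))
  ss <- Biostrings::DNAStringSet(setNames(rec$cds, hdr))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Greedy identity clustering of a toxin database
#'
#' Mirrors redundancy reduction of a CDS set at a similarity threshold
#' (the pipeline's databases are clustered at 99%). Records are sorted by
#' decreasing length (ties by id); each record joins the first existing
#' cluster whose representative shares global percent identity >= the
#' threshold (see [pairwise_identity()]), otherwise it founds a new cluster.
#' Cluster representatives are therefore the longest member of each cluster.
#'
#' @param db A `toxin_db`.
#' @param threshold Identity fraction in (0, 1].
#' @return An object of class `toxin_clusters`: list with `clusters` (each a
#'   list with `representative` and `members` ids), `representatives` (a
#'   `toxin_db` of cluster representatives, in sort order) and `threshold`.
#' @export
cluster_by_identity <- function(db, threshold = 0.99) {
  stopifnot(inherits(db, "toxin_db"), threshold > 0, threshold <= 1)
  rec <- db$records
  if (nrow(rec) == 0L)
    return(structure(list(clusters = list(),
                          representatives = db, threshold = threshold),
                     class = "toxin_clusters"))
  ord <- order(-rec$length, rec$id)
  rec <- rec[ord, , drop = FALSE]
  reps <- integer(0)           # row indices of representatives
  clusters <- list()
  assignment <- integer(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      if (pairwise_identity(rec$cds[i], rec$cds[reps[ci]]) >= threshold) {
        clusters[[ci]]$members <- c(clusters[[ci]]$members, rec$id[i])
        assignment[i] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      clusters[[length(reps)]] <- list(representative = rec$id[i],
                                       members = rec$id[i])
      assignment[i] <- length(reps)
    }
  }
  rep_rec <- rec[reps, , drop = FALSE]
  rownames(rep_rec) <- NULL
  rep_db <- structure(list(records = rep_rec,
                           source = paste0(db$source, " (clustered)")),
                      class = "toxin_db")
  structure(list(clusters = clusters, representatives = rep_db,
                 threshold = threshold),
            class = "toxin_clusters")
}

#' @export
print.toxin_clusters <- function(x, ...) {
  cat(sprintf("%d clusters at %.1f%% identity (%d input records)\n",
              length(x$clusters), 100 * x$threshold,
              sum(vapply(x$clusters, function(cl) length(cl$members), 1L))))
  invisible(x)
}

#' Merge two toxin databases
#'
#' Union of a main and a custom (e.g. transcriptome-derived) database.
#' Exact-duplicate sequences are removed (first occurrence wins); id
#' collisions between different sequences are resolved deterministically by
#' suffixing the later record's id with `.1`, `.2`, ...
#'
#' @param main,custom `toxin_db` objects.
#' @return The merged `toxin_db`.
#' @export
merge_databases <- function(main, custom) {
  stopifnot(inherits(main, "toxin_db"), inherits(custom, "toxin_db"))
  rec <- rbind(main$records, custom$records)
  if (nrow(rec) == 0L)
    return(structure(list(records = rec, source = "merged"), class = "toxin_db"))
  rec <- rec[!duplicated(rec$cds), , drop = FALSE]
  ids <- rec$id
  for (i in seq_along(ids)) {
    if (ids[i] %in% ids[seq_len(i - 1L)]) {
      suffix <- 1L
      while (paste0(ids[i], ".", suffix) %in% ids) suffix <- suffix + 1L
      ids[i] <- paste0(ids[i], ".", suffix)
    }
  }
  rec$id <- ids
  rownames(rec) <- NULL
  structure(list(records = rec,
                 source = paste(main$source, custom$source, sep = " + ")),
            class = "toxin_db")
}

#' Write a database manifest
#'
#' Tab-separated table with one row per record: id, family, length and (if a
#' clustering is supplied) the cluster id of the record.
#'
#' @param db A `toxin_db`.
#' @param path Output TSV path.
#' @param clusters Optional `toxin_clusters` from [cluster_by_identity()].
#' @return `path`, invisibly.
#' @export
write_db_manifest <- function(db, path, clusters = NULL) {
  rec <- db$records
  man <- data.frame(id = rec$id, family = rec$family, length = rec$length,
                    stringsAsFactors = FALSE)
  if (!is.null(clusters)) {
    cl_of <- unlist(lapply(seq_along(clusters$clusters), function(ci)
      setNames(rep(ci, length(clusters$clusters[[ci]]$members)),
               clusters$clusters[[ci]]$members)))
    man$cluster_id <- unname(cl_of[man$id])
  }
  write.table(man, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
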