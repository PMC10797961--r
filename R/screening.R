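#' Find open reading frames in a transcript
#'
#' All ATG..stop ORFs of length >= `min_len` in all three frames of both
#' strands. Nested ORFs sharing a stop codon report only the longest (the
#' first ATG after the previous in-frame stop).
#'
#' @param seq Transcript nucleotide string (may contain N).
#' @param min_len Minimum ORF length in nucleotides (>= 3).
#' @return data.frame with columns `strand`, `start`, `end` (0-based
#'   half-open on the transcript's forward strand), `frame` and `cds`
#'   (the reading-strand sequence, ATG..stop inclusive).
#' @export
find_orfs <- function(seq, min_len = 200L) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  df <- .find_orfs_cpp(toupper(seq), as.integer(min_len))
  df[order(df$start, df$end, df$strand), , drop = FALSE]
}

#' Screening parameters for transcript-derived databases
#'
#' Defaults admit cross-species homologs (80% identity) while requiring the
#' hit to cover at least half of the database entry.
#'
#' @param min_identity Minimum hit identity to a database entry.
#' @param min_coverage Minimum fraction of the database entry covered by
#'   the hits on one transcript.
#' @param search [search_params()] used for the transcript-vs-database
#'   similarity search.
#' @return A list of class `screen_params`.
#' @export
screen_params <- function(min_identity = 0.80, min_coverage = 0.50,
                          search = search_params(min_identity = min_identity)) {
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 search = search), class = "screen_params")
}

#' Screen assembled transcripts for full-length toxin CDSs
#'
#' Identifies toxin transcripts by similarity search of the database CDSs
#' against the transcripts, then extracts from each matching transcript the
#' ORF best overlapping the hit footprint. Each emitted record is a
#' full-length CDS labeled with the family of the best-scoring database
#' hit (ties broken by identity, then id); exact-duplicate CDSs are
#' deduplicated. The result is a custom database ready to merge into the
#' main one with [merge_databases()].
#'
#' @param transcripts Named character vector or `DNAStringSet` of assembled
#'   venom-tissue transcripts.
#' @param db A `toxin_db` to screen against.
#' @param params A [screen_params()].
#' @param min_cds_len Minimum CDS length for emitted records.
#' @return A `toxin_db` of transcript-derived full-length toxin CDSs.
#' @export
screen_transcripts <- function(transcripts, db, params = screen_params(),
                               min_cds_len = 200L) {
  stopifnot(inherits(db, "toxin_db"))
  if (nrow(db$records) == 0L) stop_input("empty toxin database")
  tr <- as_genome(transcripts)
  hits <- search_hits(db, tr, params$search)
  ids <- character(0); fams <- character(0); cdss <- character(0)
  for (tid in names(tr)) {
    h <- hits[hits$contig_id == tid & hits$identity >= params$min_identity, ,
              drop = FALSE]
    if (nrow(h) == 0L) next
    # best database entry: total score, ties by identity then id
    agg <- lapply(split(h, h$query_id), function(x)
      data.frame(query_id = x$query_id[1L], score = sum(x$score),
                 identity = max(x$identity), stringsAsFactors = FALSE))
    agg <- do.call(rbind, agg)
    agg <- agg[order(-agg$score, -agg$identity, agg$query_id), , drop = FALSE]
    best <- agg$query_id[1L]
    hb <- h[h$query_id == best, , drop = FALSE]
    qlen <- db$records$length[db$records$id == best]
    cov <- interval_union_len(hb$qstart, hb$qend) / qlen
    if (cov < params$min_coverage) next
    fam <- db$records$family[db$records$id == best]
    # hit footprint on the transcript, majority strand
    strand <- names(sort(table(hb$strand), decreasing = TRUE))[1L]
    foot_s <- min(hb$tstart); foot_e <- max(hb$tend)
    orfs <- find_orfs(tr[[tid]], min_len = min_cds_len)
    orfs <- orfs[orfs$strand == strand, , drop = FALSE]
    if (nrow(orfs) == 0L) next
    ovl <- pmax(0L, pmin(orfs$end, foot_e) - pmax(orfs$start, foot_s))
    if (max(ovl) == 0L) next
    pick <- which(ovl == max(ovl))
    pick <- pick[order(orfs$end[pick] - orfs$start[pick], decreasing = TRUE)][1L]
    ids <- c(ids, tid); fams <- c(fams, fam); cdss <- c(cdss, orfs$cds[pick])
  }
  keep <- !duplicated(cdss)
  suppressWarnings(
    toxin_db(id = make.unique(ids[keep], sep = "."), family = fams[keep],
             cds = cdss[keep], source = "transcript screening",
             min_cds_len = min_cds_len))
}
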