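#' Full-length selection rule
#'
#' A candidate locus is called full-length when its chained hits cover at
#' least `min_coverage` of the query CDS and reach both CDS termini within
#' `end_tolerance` bases. Exact 100% coverage would be brittle to terminal
#' mismatches under local alignment, hence the tolerance.
#'
#' @param min_coverage Minimum query coverage fraction.
#' @param end_tolerance Maximum distance (bp) of the chained hits from each
#'   query terminus.
#' @return A list of class `full_length_rule`.
#' @export
full_length_rule <- function(min_coverage = 0.95, end_tolerance = 10L) {
  stopifnot(min_coverage > 0, min_coverage <= 1, end_tolerance >= 0)
  structure(list(min_coverage = min_coverage,
                 end_tolerance = as.integer(end_tolerance)),
            class = "full_length_rule")
}

# length of the union of [s, e) intervals
interval_union_len <- function(s, e) {
  if (length(s) == 0L) return(0L)
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  tot <- 0L; cur_s <- s[1L]; cur_e <- e[1L]
  for (i in seq_along(s)[-1L]) {
    if (s[i] <= cur_e) cur_e <- max(cur_e, e[i])
    else { tot <- tot + (cur_e - cur_s); cur_s <- s[i]; cur_e <- e[i] }
  }
  tot + (cur_e - cur_s)
}

# Exact maximal-score collinear chain over one (query, contig, strand) group.
# Hits are taken in transcription order; for each candidate head the span
# constraint is measured from that head, which keeps the DP exact. The join
# cost grows weakly with the genomic gap (1 point per gap_scale bases), so
# ordinary introns are nearly free while chains bridging distinct tandem
# copies tens of kb apart are disfavored relative to single-copy chains.
chain_group <- function(h, max_gene_size, join_penalty, max_overlap,
                        gap_scale) {
  n <- nrow(h)
  # transcription-order genomic coordinates
  if (h$strand[1L] == "+") { gs <- h$tstart; ge <- h$tend }
  else { gs <- -h$tend; ge <- -h$tstart }
  ord <- order(gs, ge, h$qstart)
  h <- h[ord, , drop = FALSE]; gs <- gs[ord]; ge <- ge[ord]
  best_chain <- NULL; best_score <- -Inf
  for (head in seq_len(n)) {
    score <- rep(-Inf, n); prev <- rep(NA_integer_, n)
    score[head] <- h$score[head]
    for (j in seq_len(n)) {
      if (j == head || j < head) next
      if (ge[j] - gs[head] > max_gene_size) next
      for (i in seq_len(j - 1L)) {
        if (i < head || !is.finite(score[i])) next
        # collinear: both query and target strictly increasing, small overlap
        if (h$qstart[j] < h$qend[i] - max_overlap) next
        if (h$qend[j] <= h$qend[i] || h$qstart[j] <= h$qstart[i]) next
        if (gs[j] < ge[i] - max_overlap) next
        if (ge[j] <= ge[i] || gs[j] <= gs[i]) next
        gap <- max(0, gs[j] - ge[i])
        cand <- score[i] + h$score[j] - join_penalty - gap / gap_scale
        if (cand > score[j]) { score[j] <- cand; prev[j] <- i }
      }
    }
    jbest <- which.max(ifelse(is.finite(score), score, -Inf))
    if (length(jbest) && is.finite(score[jbest]) && score[jbest] > best_score) {
      chain <- integer(0); j <- jbest
      while (!is.na(j)) { chain <- c(j, chain); j <- prev[j] }
      best_score <- score[jbest]
      best_chain <- chain
    }
  }
  list(rows = h[best_chain, , drop = FALSE], score = best_score)
}

#' Chain local hits into candidate toxin loci
#'
#' Per (query, contig, strand) group, finds maximal-score collinear chains
#' (chain score = sum of hit scores minus a per-join penalty) subject to a
#' genomic span limit (`max_gene_size`, default 50 kb: only genes shorter
#' than 50 kb are considered), a small permitted overlap between consecutive
#' chained hits on both query and target, and strict collinearity (query and
#' target intervals both increasing in transcription order). Chains are
#' peeled off greedily by score, so each hit belongs to at most one locus
#' per query.
#'
#' @param hits A `local_hits` data.frame (see [search_hits()]).
#' @param query_lengths Named integer vector: CDS length per query id.
#' @param max_gene_size Maximum genomic span of one locus (bp).
#' @param join_penalty Score deducted per chain join; prefers fewer, larger
#'   exon hits when ambiguous.
#' @param max_overlap Maximum permitted overlap (bp) between consecutive
#'   chained hits on the query and on the target.
#' @param gap_scale Genomic-gap cost scale: each join additionally costs
#'   `gap / gap_scale` points, so intron-sized gaps are nearly free while
#'   joins bridging separate tandem gene copies are penalized.
#' @return A list of `candidate_locus` objects with fields `query_id`,
#'   `contig_id`, `strand`, `hits` (chained rows in transcription order),
#'   `span_start`, `span_end`, `query_coverage`, `score`, `qstart_min`,
#'   `qend_max`.
#' @export
chain_hits <- function(hits, query_lengths, max_gene_size = 50000L,
                       join_penalty = 10L, max_overlap = 15L,
                       gap_scale = 1000) {
  stopifnot(is.data.frame(hits))
  loci <- list()
  if (nrow(hits) == 0L) return(loci)
  key <- paste(hits$query_id, hits$contig_id, hits$strand, sep = "\r")
  for (grp in split(seq_len(nrow(hits)), key)) {
    h <- hits[grp, , drop = FALSE]
    qlen <- query_lengths[[h$query_id[1L]]]
    if (is.null(qlen) || is.na(qlen)) stop("missing query length for ", h$query_id[1L])
    while (nrow(h) > 0L) {
      ch <- chain_group(h, max_gene_size, join_penalty, max_overlap,
                        gap_scale)
      rows <- ch$rows
      if (nrow(rows) == 0L) break
      loci[[length(loci) + 1L]] <- structure(list(
        query_id = rows$query_id[1L],
        contig_id = rows$contig_id[1L],
        strand = rows$strand[1L],
        hits = rows,
        span_start = min(rows$tstart),
        span_end = max(rows$tend),
        query_coverage = interval_union_len(rows$qstart, rows$qend) / qlen,
        qstart_min = min(rows$qstart),
        qend_max = max(rows$qend),
        query_length = qlen,
        score = ch$score), class = "candidate_locus")
      used <- paste(rows$tstart, rows$tend, rows$qstart, rows$qend)
      h <- h[!(paste(h$tstart, h$tend, h$qstart, h$qend) %in% used), , drop = FALSE]
    }
  }
  # deterministic order
  if (length(loci)) {
    o <- order(vapply(loci, `[[`, character(1), "contig_id"),
               vapply(loci, `[[`, numeric(1), "span_start"),
               vapply(loci, `[[`, character(1), "query_id"),
               vapply(loci, `[[`, character(1), "strand"))
    loci <- loci[o]
  }
  loci
}

#' @export
print.candidate_locus <- function(x, ...) {
  cat(sprintf("locus %s:%d-%d(%s) query %s, %d hit(s), coverage %.2f\n",
              x$contig_id, x$span_start, x$span_end, x$strand, x$query_id,
              nrow(x$hits), x$query_coverage))
  invisible(x)
}

#' Classify a candidate locus as full-length or partial
#'
#' Full-length iff query coverage meets the rule's minimum AND the chained
#' hits reach both query termini within the rule's end tolerance. Only
#' full-length loci proceed to gene-model building; partial loci are
#' dropped, mirroring the pipeline's restriction to full-length CDS matches.
#'
#' @param locus A `candidate_locus`.
#' @param query_len CDS length of the locus query (defaults to the length
#'   recorded in the locus).
#' @param rule A [full_length_rule()].
#' @return `"full_length"` or `"partial"`.
#' @export
classify_locus <- function(locus, query_len = locus$query_length,
                           rule = full_length_rule()) {
  ok <- locus$query_coverage >= rule$min_coverage &&
    locus$qstart_min <= rule$end_tolerance &&
    locus$qend_max >= query_len - rule$end_tolerance
  if (ok) "full_length" else "partial"
}

#' Merge full-length loci into matched regions
#'
#' Overlapping full-length loci on the same contig and strand are merged
#' into maximal regions; supporting query ids are unioned and the best hit
#' identity is kept. These regions are the `matched_regions` output surface:
#' every final annotation falls inside one, and regions without a final
#' model are the "matched but not annotated" cases a curator inspects.
#'
#' @param loci List of full-length `candidate_locus` objects.
#' @return A data.frame of class `matched_regions` with columns `region_id`,
#'   `contig_id`, `strand`, `start`, `end` (0-based half-open), `queries`
#'   (comma-joined) and `best_identity`.
#' @export
build_matched_regions <- function(loci) {
  empty <- data.frame(region_id = character(0), contig_id = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), queries = character(0),
                      best_identity = numeric(0), stringsAsFactors = FALSE)
  class(empty) <- c("matched_regions", "data.frame")
  if (length(loci) == 0L) return(empty)
  df <- data.frame(
    contig = vapply(loci, `[[`, character(1), "contig_id"),
    strand = vapply(loci, `[[`, character(1), "strand"),
    start = vapply(loci, `[[`, numeric(1), "span_start"),
    end = vapply(loci, `[[`, numeric(1), "span_end"),
    query = vapply(loci, `[[`, character(1), "query_id"),
    identity = vapply(loci, function(l) max(l$hits$identity), 1),
    stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(df$contig,
                               IRanges::IRanges(df$start + 1L, df$end),
                               strand = df$strand)
  red <- GenomicRanges::reduce(gr)
  ov <- GenomicRanges::findOverlaps(gr, red)
  out <- lapply(seq_along(red), function(i) {
    members <- S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == i]
    data.frame(contig_id = as.character(GenomicRanges::seqnames(red))[i],
               strand = as.character(GenomicRanges::strand(red))[i],
               start = GenomicRanges::start(red)[i] - 1L,
               end = GenomicRanges::end(red)[i],
               queries = paste(sort(unique(df$query[members])), collapse = ","),
               best_identity = max(df$identity[members]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$contig_id, out$start, out$end, out$strand), , drop = FALSE]
  out <- cbind(region_id = sprintf("region_%d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("matched_regions", "data.frame")
  out
}

#' Write matched regions as GTF
#'
#' One `match` feature line per region, 1-based inclusive coordinates,
#' score column = best identity x 100.
#'
#' @param regions A `matched_regions` data.frame.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_matched_regions_gtf <- function(regions, path) {
  lines <- sprintf(
    '%s\ttoxannot\tmatch\t%d\t%d\t%.1f\t%s\t.\tregion_id "%s"; queries "%s";',
    regions$contig_id, regions$start + 1L, regions$end,
    regions$best_identity * 100, regions$strand,
    regions$region_id, regions$queries)
  writeLines(lines, path)
  invisible(path)
}
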