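#' Alignment scoring parameters for the search engine
#'
#' @param match,mismatch Per-column scores (mismatch negative).
#' @param gap_open,gap_ext Affine gap scores (negative); a gap of length L
#'   costs `gap_open + L * gap_ext`.
#' @return A list of class `align_scoring`.
#' @export
align_scoring <- function(match = 2L, mismatch = -3L,
                          gap_open = -5L, gap_ext = -2L) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_ext < 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open), gap_ext = as.integer(gap_ext)),
            class = "align_scoring")
}

#' Search parameters for toxin-locus detection
#'
#' @param k Seed length (exact k-mer), 4..31.
#' @param min_score Minimum local alignment score for a reported hit.
#' @param min_identity Minimum hit identity fraction; this is the user-facing
#'   percent-identity knob of the pipeline.
#' @param scoring An [align_scoring()] object.
#' @return A list of class `search_params`.
#' @export
search_params <- function(k = 11L, min_score = 50L, min_identity = 0.80,
                          scoring = align_scoring()) {
  stopifnot(k >= 4, k <= 31, min_score > 0,
            min_identity > 0, min_identity <= 1)
  structure(list(k = as.integer(k), min_score = as.integer(min_score),
                 min_identity = min_identity, scoring = scoring),
            class = "search_params")
}

# normalize a genome to a named character vector over {A,C,G,T,N}
as_genome <- function(x) {
  if (is(x, "DNAStringSet")) {
    g <- setNames(as.character(x), sub("\\s.*$", "", names(x)))
  } else if (is.character(x)) {
    g <- x
    if (is.null(names(g))) names(g) <- paste0("contig", seq_along(g))
  } else {
    stop("genome must be a DNAStringSet or a named character vector")
  }
  if (length(g) == 0L) stop_input("empty genome assembly")
  g <- toupper(g)
  if (anyDuplicated(names(g))) stop_input("duplicated contig ids in genome")
  if (any(grepl("[^ACGTN]", g)))
    stop_input("genome contains characters outside {A,C,G,T,N}")
  g
}

read_genome <- function(path) {
  if (!file.exists(path)) stop_input("genome file not found: ", path)
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) stop_input("malformed FASTA: ", path))
  as_genome(ss)
}

#' Global pairwise percent identity
#'
#' Identity of an optimal global alignment with free terminal gaps (scoring
#' from [align_scoring()]): matching columns divided by total alignment
#' columns, where unaligned terminal overhangs count as gap columns. The
#' measure is symmetric and is the one used for database clustering.
#'
#' @param a,b Nucleotide strings.
#' @param scoring An [align_scoring()] object.
#' @return Identity fraction in `[0, 1]`.
#' @examples
#' pairwise_identity("AAAA", "AAAT")  # 0.75
#' @export
pairwise_identity <- function(a, b, scoring = align_scoring()) {
  stopifnot(nzchar(a), nzchar(b))
  .nw_identity_cpp(toupper(a), toupper(b), scoring$match, scoring$mismatch,
                   scoring$gap_open, scoring$gap_ext)$identity
}

#' Build an exact k-mer seed index over a genome
#'
#' Indexes the forward strand of every contig; minus-strand occurrences of a
#' k-mer are found as forward positions of its reverse complement, so both
#' strands are covered. k-mers containing N are excluded.
#'
#' @param genome A `DNAStringSet` or named character vector of contigs.
#' @param k Seed length (4..31).
#' @return An object of class `seed_index`.
#' @export
build_seed_index <- function(genome, k = 11L) {
  g <- as_genome(genome)
  structure(list(ptr = .seed_index_build_cpp(unname(g), as.integer(k)),
                 contigs = names(g), k = as.integer(k)),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("seed index: k=%d over %d contig(s)\n", x$k, length(x$contigs)))
  invisible(x)
}

#' Query a seed index for one k-mer
#'
#' @param index A [build_seed_index()] object.
#' @param kmer A k-length nucleotide string.
#' @return data.frame with columns `contig`, `pos` (0-based forward-strand
#'   position) and `strand` (`-` rows are forward positions of the reverse
#'   complement seed).
#' @export
query_seeds <- function(index, kmer) {
  stopifnot(inherits(index, "seed_index"))
  df <- .seed_index_query_cpp(index$ptr, toupper(kmer))
  data.frame(contig = index$contigs[df$contig], pos = df$pos,
             strand = df$strand, stringsAsFactors = FALSE)
}

#' Search toxin CDSs against a genome
#'
#' Seed-and-extend gapped local alignment of every database CDS against both
#' strands of every contig. Seed matches are clustered by diagonal and
#' target proximity, each cluster is aligned with windowed Smith-Waterman,
#' and extensions overlapping on both query and target are merged (best
#' score kept). Hits below `min_score` or `min_identity` are discarded.
#'
#' @param db A `toxin_db`.
#' @param genome A `DNAStringSet` or named character vector.
#' @param params A [search_params()] object.
#' @return A data.frame of class `local_hits` with columns `query_id`,
#'   `contig_id`, `strand`, `qstart`, `qend`, `tstart`, `tend` (all 0-based
#'   half-open; query coordinates always in query-forward orientation;
#'   target coordinates on the forward strand), `identity`, `score`, sorted
#'   by (contig, tstart). Zero rows is a valid result.
#' @export
search_hits <- function(db, genome, params = search_params()) {
  stopifnot(inherits(db, "toxin_db"))
  g <- as_genome(genome)
  if (nrow(db$records) == 0L) stop_input("empty toxin database")
  sc <- params$scoring
  df <- .search_hits_cpp(db$records$cds, unname(g), params$k,
                         sc$match, sc$mismatch, sc$gap_open, sc$gap_ext,
                         params$min_score, params$min_identity)
  out <- data.frame(query_id = db$records$id[df$query],
                    contig_id = names(g)[df$contig],
                    strand = df$strand,
                    qstart = df$qstart, qend = df$qend,
                    tstart = df$tstart, tend = df$tend,
                    identity = df$identity, score = df$score,
                    stringsAsFactors = FALSE)
  class(out) <- c("local_hits", "data.frame")
  out
}

#' Import hits from BLAST outfmt-6 style TSV
#'
#' Adapter so an external aligner can substitute the internal engine.
#' Expected columns: qseqid, sseqid, pident, length, mismatch, gapopen,
#' qstart, qend, sstart, send, evalue, bitscore (1-based inclusive; minus
#' strand encoded as sstart > send). Coordinates are converted to the
#' internal 0-based half-open forward-strand convention and the bitscore is
#' used as the hit score.
#'
#' @param path TSV file without header.
#' @return A `local_hits` data.frame (see [search_hits()]).
#' @export
read_blast_hits <- function(path) {
  if (!file.exists(path)) stop_input("hits file not found: ", path)
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- read.delim(path, header = FALSE, col.names = cols,
                   stringsAsFactors = FALSE)
  minus <- df$sstart > df$send
  out <- data.frame(query_id = df$qseqid, contig_id = df$sseqid,
                    strand = ifelse(minus, "-", "+"),
                    qstart = df$qstart - 1L, qend = df$qend,
                    tstart = ifelse(minus, df$send, df$sstart) - 1L,
                    tend = ifelse(minus, df$sstart, df$send),
                    identity = df$pident / 100,
                    score = round(df$bitscore),
                    stringsAsFactors = FALSE)
  out <- out[order(out$contig_id, out$tstart, out$tend, out$query_id), ]
  rownames(out) <- NULL
  class(out) <- c("local_hits", "data.frame")
  out
}

#' Export hits as BLAST outfmt-6 style TSV
#'
#' @param hits A `local_hits` data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_blast_hits <- function(hits, path) {
  alen <- hits$qend - hits$qstart
  minus <- hits$strand == "-"
  df <- data.frame(qseqid = hits$query_id, sseqid = hits$contig_id,
                   pident = round(hits$identity * 100, 2),
                   length = alen,
                   mismatch = round((1 - hits$identity) * alen),
                   gapopen = 0L,
                   qstart = hits$qstart + 1L, qend = hits$qend,
                   sstart = ifelse(minus, hits$tend, hits$tstart + 1L),
                   send = ifelse(minus, hits$tstart + 1L, hits$tend),
                   evalue = 0, bitscore = hits$score)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
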