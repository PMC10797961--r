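#' Spliced-alignment parameters
#'
#' Scoring and structural parameters of the exon/intron dynamic program.
#' Introns are length-independent within `[min_intron, max_intron]` and are
#' only permitted over region segments starting GT and ending AG (canonical
#' splice sites; non-canonical sites are a stated limitation of the method).
#'
#' @param match,mismatch,gap_open,gap_ext Exon-state scores (affine gaps).
#' @param intron_cost Constant score of opening one intron.
#' @param min_intron,max_intron Intron length bounds (bp).
#' @param flank Flanking sequence added around a locus span before spliced
#'   alignment (bp).
#' @param rescue_codons Number of codons scanned in-frame around the aligned
#'   CDS boundaries for a canonical ATG / stop codon during finalization.
#' @param band_slack Slack (bp) added around hit-implied target intervals
#'   when banding the dynamic program; `NULL` disables banding.
#' @return A list of class `splice_params`.
#' @export
splice_params <- function(match = 5L, mismatch = -4L, gap_open = -12L,
                          gap_ext = -2L, intron_cost = -40L,
                          min_intron = 50L, max_intron = 50000L,
                          flank = 500L, rescue_codons = 30L,
                          band_slack = 2000L) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_ext < 0,
            intron_cost < 0, min_intron >= 4, max_intron >= min_intron)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open), gap_ext = as.integer(gap_ext),
                 intron_cost = as.integer(intron_cost),
                 min_intron = as.integer(min_intron),
                 max_intron = as.integer(max_intron),
                 flank = as.integer(flank),
                 rescue_codons = as.integer(rescue_codons),
                 band_slack = if (is.null(band_slack)) NULL else as.integer(band_slack)),
            class = "splice_params")
}

#' Extract the oriented region around a candidate locus
#'
#' Returns the genomic span of the locus plus `flank` on each side, clipped
#' to the contig, reverse-complemented for minus-strand loci so that the
#' region reads in transcription orientation. The returned object maps
#' region coordinates back to forward-strand genome coordinates exactly.
#'
#' @param genome A `DNAStringSet` or named character vector.
#' @param locus A `candidate_locus`.
#' @param flank Flank size in bp.
#' @return An object of class `oriented_region` with fields `seq`,
#'   `contig_id`, `strand`, `g_start`, `g_end` (0-based half-open genomic
#'   interval covered).
#' @export
extract_region <- function(genome, locus, flank = 500L) {
  g <- as_genome(genome)
  contig <- g[[locus$contig_id]]
  if (is.null(contig)) stop("contig not found: ", locus$contig_id)
  clen <- nchar(contig)
  if (locus$span_start < 0 || locus$span_end > clen)
    stop("locus span outside contig bounds")
  gs <- max(0L, locus$span_start - as.integer(flank))
  ge <- min(clen, locus$span_end + as.integer(flank))
  seq <- substr(contig, gs + 1L, ge)
  if (locus$strand == "-") seq <- revcomp(seq)
  structure(list(seq = seq, contig_id = locus$contig_id,
                 strand = locus$strand, g_start = gs, g_end = ge),
            class = "oriented_region")
}

#' Map region coordinates to genome coordinates
#'
#' Converts a 0-based half-open interval in an oriented region back to
#' forward-strand genome coordinates (exact round trip, including under
#' reverse complement for minus-strand regions).
#'
#' @param region An `oriented_region`.
#' @param start,end 0-based half-open interval in region coordinates.
#' @return Integer vector `c(start, end)` in genomic forward-strand
#'   coordinates, 0-based half-open.
#' @export
region_to_genome <- function(region, start, end) {
  if (region$strand == "+") c(region$g_start + start, region$g_start + end)
  else c(region$g_end - end, region$g_end - start)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# target intervals of the locus hits in region coordinates, +/- slack
banding_columns <- function(locus, region, slack) {
  n <- nchar(region$seq)
  if (is.null(slack)) return(integer(0))
  ints <- lapply(seq_len(nrow(locus$hits)), function(i) {
    ts <- locus$hits$tstart[i]; te <- locus$hits$tend[i]
    if (region$strand == "+") c(ts - region$g_start, te - region$g_start)
    else c(region$g_end - te, region$g_end - ts)
  })
  cols <- unique(unlist(lapply(ints, function(iv)
    seq.int(max(0L, iv[1] - slack), min(n - 1L, iv[2] + slack - 1L)))))
  sort(cols)
}

#' Spliced alignment of a CDS against an oriented region
#'
#' Dynamic program with exon match/mismatch, affine exon gaps, and a
#' length-independent intron state allowed only where the skipped region
#' segment starts GT, ends AG and has length within the configured bounds.
#' Global in the CDS, local in the region. By default the exon states are
#' banded to the target intervals implied by the locus hit chain (plus
#' slack); pass `unbanded = TRUE` (or a locus of `NULL`) for the full
#' quadratic program.
#'
#' @param cds CDS nucleotide string.
#' @param region An `oriented_region` (or a plain string).
#' @param params A [splice_params()].
#' @param locus Optional `candidate_locus` used for banding.
#' @param unbanded Force the full dynamic program.
#' @return A list of class `spliced_alignment`: `score`, `segments` (matrix
#'   with columns qstart, qend, rstart, rend; 0-based half-open, region
#'   coordinates in transcription orientation), `matches`, `columns`,
#'   `identity`. A score of 0 with no segments means no alignment.
#' @export
spliced_align <- function(cds, region, params = splice_params(),
                          locus = NULL, unbanded = FALSE) {
  seq <- if (inherits(region, "oriented_region")) region$seq else region
  cols <- integer(0)
  if (!unbanded && !is.null(locus) && !is.null(params$band_slack) &&
      inherits(region, "oriented_region"))
    cols <- banding_columns(locus, region, params$band_slack)
  res <- .spliced_align_cpp(toupper(cds), toupper(seq), cols,
                            params$match, params$mismatch, params$gap_open,
                            params$gap_ext, params$intron_cost,
                            params$min_intron, params$max_intron)
  structure(res, class = "spliced_alignment")
}

#' @export
print.spliced_alignment <- function(x, ...) {
  cat(sprintf("spliced alignment: score %d, %d exon segment(s), identity %.3f\n",
              x$score, nrow(x$segments), x$identity))
  invisible(x)
}

#' Translate a CDS to peptide
#'
#' Standard genetic code; the terminal stop codon is not included in the
#' peptide and internal stops are rendered as `*` (the signature of a
#' warning-class model).
#'
#' @param cds Nucleotide string with length a multiple of 3.
#' @return Peptide string.
#' @examples
#' translate_cds("ATGAAATAG")     # "MK"
#' translate_cds("ATGTGAAAATAG")  # "M*K"
#' @export
translate_cds <- function(cds) {
  if (nchar(cds) %% 3L != 0L) stop("CDS length is not a multiple of 3")
  pep <- as.character(Biostrings::translate(Biostrings::DNAString(toupper(cds)),
                                            if.fuzzy.codon = "X"))
  sub("\\*$", "", pep)
}

# splice exon intervals (genomic, transcription order) out of a genome
splice_cds_from_genome <- function(genome, contig_id, strand, exons) {
  g <- as_genome(genome)
  contig <- g[[contig_id]]
  pieces <- vapply(seq_len(nrow(exons)), function(i)
    substr(contig, exons[i, 1] + 1L, exons[i, 2]), character(1))
  if (strand == "-") pieces <- vapply(pieces, revcomp, character(1))
  paste(pieces, collapse = "")
}

# GTF frame of each exon: bases to skip to reach the first complete codon
exon_phases <- function(exon_lens) {
  cum <- c(0L, cumsum(exon_lens))[seq_along(exon_lens)]
  as.integer((3L - (cum %% 3L)) %% 3L)
}

#' Finalize a gene model from a spliced alignment
#'
#' Maps exon segments to genome coordinates, rescues canonical boundaries
#' (if the aligned CDS does not begin with ATG, scans in-frame within
#' `rescue_codons` codons inside/ahead of the first exon for an ATG;
#' analogously seeks an in-frame terminal stop around the aligned end),
#' computes per-exon phases, splices and translates the CDS, and verifies
#' all introns are canonical GT..AG. Rejection (no ATG, no stop, CDS too
#' short) is a typed result, not an error: rejected loci remain visible
#' only in the matched-regions output.
#'
#' @param aln A `spliced_alignment` with at least one segment.
#' @param query One-row data.frame (a `toxin_db` record) that seeded the
#'   locus: provides `id` and `family`.
#' @param region The `oriented_region` the alignment was computed on.
#' @param params A [splice_params()] (rescue window).
#' @param min_cds_len Minimum CDS length (bp) for an accepted model.
#' @return A `gene_model` object, or a `model_rejection` with a `reason`
#'   (`no_start_codon`, `no_terminal_stop`, `below_min_length`,
#'   `noncanonical_intron`, `empty_alignment`).
#' @export
finalize_model <- function(aln, query, region, params = splice_params(),
                           min_cds_len = 200L) {
  reject <- function(reason)
    structure(list(reason = reason, source_query = query$id,
                   contig_id = region$contig_id, strand = region$strand),
              class = "model_rejection")
  if (nrow(aln$segments) == 0L) return(reject("empty_alignment"))
  seg <- aln$segments
  rseq <- toupper(region$seq)
  n <- nchar(rseq)
  rescue <- 3L * params$rescue_codons

  # start rescue: ATG at the spliced 5' boundary, scanned in region coords
  r1 <- seg[1L, "rstart"]
  first_end <- seg[1L, "rend"]
  cand <- seq.int(max(0L, r1 - rescue), min(first_end - 3L, r1 + rescue))
  cand <- cand[substring(rseq, cand + 1L, cand + 3L) == "ATG"]
  if (length(cand) == 0L) return(reject("no_start_codon"))
  r1_new <- cand[order(abs(cand - r1), cand)][1L]
  seg[1L, "rstart"] <- r1_new

  # end rescue: in-frame terminal stop at the spliced 3' boundary
  exon_lens <- seg[, "rend"] - seg[, "rstart"]
  L0 <- sum(exon_lens)
  r2 <- seg[nrow(seg), "rend"]
  last_start <- seg[nrow(seg), "rstart"]
  cand2 <- seq.int(max(last_start + 3L, r2 - rescue), min(n, r2 + rescue))
  keep <- (L0 + (cand2 - r2)) %% 3L == 0L
  cand2 <- cand2[keep]
  stops <- c("TAA", "TAG", "TGA")
  cand2 <- cand2[substring(rseq, cand2 - 2L, cand2) %in% stops]
  if (length(cand2) == 0L) return(reject("no_terminal_stop"))
  r2_new <- cand2[order(abs(cand2 - r2), cand2)][1L]
  seg[nrow(seg), "rend"] <- r2_new

  exon_lens <- seg[, "rend"] - seg[, "rstart"]
  if (any(exon_lens <= 0L)) return(reject("no_start_codon"))
  L <- sum(exon_lens)
  if (L %% 3L != 0L) return(reject("not_codon_multiple"))
  if (L < min_cds_len) return(reject("below_min_length"))

  # canonical introns (guaranteed by the DP; verified as an invariant)
  if (nrow(seg) > 1L) {
    for (i in seq_len(nrow(seg) - 1L)) {
      istart <- seg[i, "rend"]; iend <- seg[i + 1L, "rstart"]
      if (substring(rseq, istart + 1L, istart + 2L) != "GT" ||
          substring(rseq, iend - 1L, iend) != "AG")
        return(reject("noncanonical_intron"))
    }
  }

  cds <- paste(substring(rseq, seg[, "rstart"] + 1L, seg[, "rend"]),
               collapse = "")
  if (substr(cds, 1L, 3L) != "ATG") return(reject("no_start_codon"))

  exons <- t(vapply(seq_len(nrow(seg)), function(i)
    region_to_genome(region, seg[i, "rstart"], seg[i, "rend"]),
    integer(2)))
  colnames(exons) <- c("start", "end")

  model <- structure(list(
    id = NA_character_,
    contig_id = region$contig_id,
    strand = region$strand,
    exons = exons,  # transcription order, genomic 0-based half-open
    phases = exon_phases(exon_lens),
    cds = cds,
    peptide = translate_cds(cds),
    status = NA_character_,
    source_query = query$id,
    family = query$family,
    score = aln$score,
    identity = aln$identity), class = "gene_model")
  model$status <- classify_annotation(model)
  model
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene model %s [%s] %s:%d-%d(%s): %d exon(s), CDS %d bp, %s\n",
              ifelse(is.na(x$id), "<unnamed>", x$id), x$family, x$contig_id,
              min(x$exons[, "start"]), max(x$exons[, "end"]), x$strand,
              nrow(x$exons), nchar(x$cds), x$status))
  invisible(x)
}

#' @export
print.model_rejection <- function(x, ...) {
  cat(sprintf("rejected model (query %s on %s%s): %s\n",
              x$source_query, x$contig_id, x$strand, x$reason))
  invisible(x)
}

#' Classify a gene model as reliable or warning
#'
#' `warning` iff the CDS contains at least one in-frame internal stop codon
#' (a candidate truncated paralog, pseudogene, or assembly error);
#' `reliable` otherwise. Stops in other frames are ignored.
#'
#' @param model A `gene_model`.
#' @return `"reliable"` or `"warning"`.
#' @export
classify_annotation <- function(model) {
  cds <- model$cds
  n <- nchar(cds)
  codons <- substring(cds, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
  internal <- codons[-length(codons)]
  if (any(internal %in% c("TAA", "TAG", "TGA"))) "warning" else "reliable"
}

# number of internal in-frame stops (for the warning report)
count_internal_stops <- function(cds) {
  n <- nchar(cds)
  codons <- substring(cds, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
  sum(codons[-length(codons)] %in% c("TAA", "TAG", "TGA"))
}

#' Resolve overlapping gene models
#'
#' Among models whose CDS genomic footprints (union of exons) overlap on
#' the same contig and strand by more than `max_overlap` of the shorter
#' footprint, keeps the best by score, then identity, then CDS length, then
#' lexicographic source query id. The result is deterministic and invariant
#' under input permutation.
#'
#' @param models List of `gene_model` objects.
#' @param max_overlap Footprint-overlap fraction above which two models
#'   compete (default 0.3).
#' @return The retained list of models, ordered by (contig, start).
#' @export
resolve_overlaps <- function(models, max_overlap = 0.3) {
  if (length(models) <= 1L) return(models)
  key <- order(
    -vapply(models, `[[`, 1, "score"),
    -vapply(models, `[[`, 1, "identity"),
    -vapply(models, function(m) nchar(m$cds), numeric(1)),
    vapply(models, `[[`, character(1), "source_query"),
    vapply(models, `[[`, character(1), "contig_id"),
    vapply(models, function(m) min(m$exons[, "start"]), numeric(1)))
  models <- models[key]
  grl <- lapply(models, function(m)
    GenomicRanges::reduce(GenomicRanges::GRanges(
      m$contig_id, IRanges::IRanges(m$exons[, "start"] + 1L, m$exons[, "end"]),
      strand = m$strand)))
  flen <- vapply(grl, function(g) sum(GenomicRanges::width(g)), numeric(1))
  kept <- integer(0)
  for (i in seq_along(models)) {
    clash <- FALSE
    for (j in kept) {
      if (models[[i]]$contig_id != models[[j]]$contig_id ||
          models[[i]]$strand != models[[j]]$strand) next
      ovl <- sum(GenomicRanges::width(GenomicRanges::intersect(grl[[i]], grl[[j]])))
      if (ovl > max_overlap * min(flen[i], flen[j])) { clash <- TRUE; break }
    }
    if (!clash) kept <- c(kept, i)
  }
  out <- models[kept]
  o <- order(vapply(out, `[[`, character(1), "contig_id"),
             vapply(out, function(m) min(m$exons[, "start"]), numeric(1)),
             vapply(out, `[[`, character(1), "source_query"))
  out[o]
}

#' Best-match report against a protein set
#'
#' Aligns each model peptide against every subject protein with the
#' module's own local aligner and reports the best subject per model (by
#' score, ties by identity then subject id), with identity and subject
#' coverage. Useful for giving annotated toxins a tentative name from
#' a curated protein database.
#'
#' @param models List of `gene_model` objects.
#' @param proteins Named character vector (or `AAStringSet`) of protein
#'   sequences.
#' @return data.frame with columns `model_id`, `best_subject`, `identity`,
#'   `coverage`, `score`.
#' @export
best_match_report <- function(models, proteins) {
  if (is(proteins, "AAStringSet"))
    proteins <- setNames(as.character(proteins), sub("\\s.*$", "", names(proteins)))
  rows <- lapply(models, function(m) {
    best <- NULL
    for (sid in sort(names(proteins))) {
      r <- .sw_generic_cpp(m$peptide, proteins[[sid]], 2L, -3L, -5L, -2L)
      cand <- list(subject = sid, score = r$score,
                   identity = r$identity,
                   coverage = (r$bend - r$bstart) / nchar(proteins[[sid]]))
      if (is.null(best) || cand$score > best$score ||
          (cand$score == best$score && cand$identity > best$identity))
        best <- cand
    }
    data.frame(model_id = m$id, best_subject = best$subject,
               identity = round(best$identity, 4),
               coverage = round(best$coverage, 4), score = best$score,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
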