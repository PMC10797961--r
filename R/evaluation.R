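#' Per-family toxin recovery rate (TRR)
#'
#' TRR is the number of annotations produced for a family divided by the
#' number of toxin loci reported for that family in the reference
#' annotation. A TRR of 1 is an exact match; above 1 means more loci than
#' reported (e.g. undetected duplications), below 1 fewer. Families with a
#' reported count of 0 get `NA` (undefined; excluded from summaries).
#'
#' @param annotated Named numeric vector: annotation counts per family.
#' @param reported Named numeric vector: reference locus counts per family.
#' @return Named numeric vector of TRR values over the union of families.
#' @examples
#' toxin_recovery_rate(c(SVMP = 3), c(SVMP = 3))  # 1
#' toxin_recovery_rate(c(CTL = 4), c(CTL = 2))    # 2
#' @export
toxin_recovery_rate <- function(annotated, reported) {
  if (any(annotated < 0) || any(reported < 0)) stop("negative counts")
  fams <- sort(union(names(annotated), names(reported)))
  a <- setNames(rep(0, length(fams)), fams)
  r <- setNames(rep(0, length(fams)), fams)
  a[names(annotated)] <- annotated
  r[names(reported)] <- reported
  ifelse(r > 0, a / r, NA_real_)
}

#' Annotation precision
#'
#' Fraction of reference toxin genes recovered in the final annotation
#' (automatic precision).
#'
#' @param n_correct Reference genes correctly annotated.
#' @param n_total Total reference genes (> 0).
#' @return Fraction in `[0, 1]`.
#' @examples
#' render_percent(precision(42, 51))  # 82.4
#' @export
precision <- function(n_correct, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_correct < 0 || n_correct > n_total) stop("invalid counts")
  n_correct / n_total
}

#' Supervised-annotation precision
#'
#' Fraction of reference genes either annotated or localized in a matched
#' region (i.e. recoverable by a curator inspecting the matched-regions
#' output): `(n_correct + n_matched_only) / n_total`.
#'
#' @param n_correct Reference genes correctly annotated.
#' @param n_matched_only Reference genes matched but not annotated.
#' @param n_total Total reference genes (> 0).
#' @return Fraction in `[0, 1]`.
#' @examples
#' render_percent(supervised_precision(44, 4, 51))  # 94.1
#' @export
supervised_precision <- function(n_correct, n_matched_only, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_correct < 0 || n_matched_only < 0 ||
      n_correct + n_matched_only > n_total) stop("invalid counts")
  (n_correct + n_matched_only) / n_total
}

#' Render a fraction as a percent
#'
#' Rounds half away from zero to `digits` decimals (one decimal by
#' default, the conventional display for precision percentages).
#'
#' @param x Fraction (e.g. 0.9216).
#' @param digits Decimal places.
#' @return Numeric percent value (e.g. 92.2).
#' @export
render_percent <- function(x, digits = 1L) {
  p <- x * 100
  f <- 10^digits
  sign(p) * floor(abs(p) * f + 0.5) / f
}

# reference gene table: one row per gene with CDS footprint
# (contig, strand, start, end 0-based half-open, family)
as_reference_table <- function(reference) {
  stopifnot(is.data.frame(reference))
  need <- c("gene_id", "contig_id", "strand", "start", "end")
  if (!all(need %in% names(reference)))
    stop("reference must have columns ", paste(need, collapse = ", "))
  if (is.null(reference$family))
    reference$family <- parse_family(reference$gene_id)
  reference
}

#' Read a reference annotation (GTF/GFF) into a gene table
#'
#' CDS features are grouped by transcript (or gene) id; each gene's
#' footprint is the span of its CDS features. Family tags are taken from a
#' `family` attribute when present, otherwise parsed from the gene id.
#'
#' @param path GTF or GFF3 file.
#' @return data.frame with columns `gene_id`, `contig_id`, `strand`,
#'   `start`, `end` (0-based half-open), `family`.
#' @export
read_reference_annotation <- function(path) {
  if (!file.exists(path)) stop_input("reference annotation not found: ", path)
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  gr <- gr[!is.na(md$type) & toupper(md$type) == "CDS"]
  md <- S4Vectors::mcols(gr)
  ids <- if (!is.null(md$transcript_id)) md$transcript_id else md$gene_id
  if (is.null(ids)) stop_input("reference annotation lacks transcript_id/gene_id")
  fam <- if (!is.null(md$family)) md$family else parse_family(ids)
  rows <- lapply(split(seq_along(gr), ids), function(ix) {
    data.frame(gene_id = ids[ix[1L]],
               contig_id = as.character(GenomicRanges::seqnames(gr))[ix[1L]],
               strand = as.character(GenomicRanges::strand(gr))[ix[1L]],
               start = min(GenomicRanges::start(gr)[ix]) - 1L,
               end = max(GenomicRanges::end(gr)[ix]),
               family = fam[ix[1L]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$contig_id, out$start, out$gene_id), , drop = FALSE]
}

model_footprints <- function(models) {
  if (length(models) == 0L)
    return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    vapply(models, `[[`, character(1), "contig_id"),
    IRanges::IRanges(vapply(models, function(m) min(m$exons[, "start"]) + 1, numeric(1)),
                     vapply(models, function(m) max(m$exons[, "end"]), numeric(1))),
    strand = vapply(models, `[[`, character(1), "strand"))
}

#' Label reference genes against an annotation run
#'
#' Each reference gene is labeled `matched_and_annotated` when a final
#' annotation overlaps its CDS footprint by at least `min_overlap` of the
#' footprint on the same strand; else `matched_but_not_annotated` when a
#' matched region overlaps likewise; else `not_matched`. The three labels
#' partition the reference set.
#'
#' @param models List of final `gene_model`s (or a `GRanges` of their
#'   footprints).
#' @param regions A `matched_regions` data.frame.
#' @param reference Reference gene table (see
#'   [read_reference_annotation()]).
#' @param min_overlap Minimum overlap fraction of the reference footprint.
#' @return Named character vector of labels, one per reference gene id.
#' @export
label_against_reference <- function(models, regions, reference,
                                    min_overlap = 0.5) {
  reference <- as_reference_table(reference)
  ref_gr <- GenomicRanges::GRanges(reference$contig_id,
                                   IRanges::IRanges(reference$start + 1L,
                                                    reference$end),
                                   strand = reference$strand)
  ann_gr <- if (is(models, "GRanges")) models else model_footprints(models)
  reg_gr <- if (nrow(regions) > 0L)
    GenomicRanges::GRanges(regions$contig_id,
                           IRanges::IRanges(regions$start + 1L, regions$end),
                           strand = regions$strand)
  else GenomicRanges::GRanges()
  frac_covered <- function(subject_gr) {
    if (length(subject_gr) == 0L) return(numeric(length(ref_gr)))
    ov <- GenomicRanges::findOverlaps(ref_gr, subject_gr)
    out <- numeric(length(ref_gr))
    for (k in seq_along(ov)) {
      qi <- S4Vectors::queryHits(ov)[k]; si <- S4Vectors::subjectHits(ov)[k]
      w <- GenomicRanges::width(GenomicRanges::pintersect(ref_gr[qi], subject_gr[si]))
      out[qi] <- max(out[qi], w / GenomicRanges::width(ref_gr[qi]))
    }
    out
  }
  ann_cov <- frac_covered(ann_gr)
  reg_cov <- frac_covered(reg_gr)
  labels <- ifelse(ann_cov >= min_overlap, "matched_and_annotated",
                   ifelse(reg_cov >= min_overlap, "matched_but_not_annotated",
                          "not_matched"))
  setNames(labels, reference$gene_id)
}

#' Evaluate an annotation run against a reference
#'
#' Combines the per-family toxin recovery rate, the per-gene labels and
#' the automatic/supervised precision into one report.
#'
#' @param models List of final `gene_model`s.
#' @param regions A `matched_regions` data.frame.
#' @param reference Reference gene table (see
#'   [read_reference_annotation()]).
#' @param min_overlap Overlap fraction used by [label_against_reference()].
#' @return An object of class `evaluation_report`: list with `trr`,
#'   `labels`, `counts` (n_correct, n_matched_only, n_total),
#'   `automatic_precision`, `supervised_precision` (fractions) and their
#'   one-decimal percent renderings.
#' @export
evaluate_annotation <- function(models, regions, reference,
                                min_overlap = 0.5) {
  reference <- as_reference_table(reference)
  labels <- label_against_reference(models, regions, reference, min_overlap)
  annotated <- table(vapply(models, `[[`, character(1), "family"))
  reported <- table(reference$family)
  trr <- toxin_recovery_rate(setNames(as.numeric(annotated), names(annotated)),
                             setNames(as.numeric(reported), names(reported)))
  n_total <- length(labels)
  n_correct <- sum(labels == "matched_and_annotated")
  n_matched_only <- sum(labels == "matched_but_not_annotated")
  auto <- precision(n_correct, n_total)
  sup <- supervised_precision(n_correct, n_matched_only, n_total)
  structure(list(trr = trr, labels = labels,
                 counts = c(n_correct = n_correct,
                            n_matched_only = n_matched_only,
                            n_total = n_total),
                 automatic_precision = auto,
                 supervised_precision = sup,
                 automatic_percent = render_percent(auto),
                 supervised_percent = render_percent(sup)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation: %d/%d annotated (automatic %.1f%%), +%d matched only (supervised %.1f%%)\n",
              x$counts["n_correct"], x$counts["n_total"], x$automatic_percent,
              x$counts["n_matched_only"], x$supervised_percent))
  trr <- x$trr[!is.na(x$trr)]
  if (length(trr))
    cat("TRR:", paste(sprintf("%s=%.2f", names(trr), trr), collapse = ", "), "\n")
  invisible(x)
}

#' Write an evaluation report as TSV and JSON
#'
#' @param report An `evaluation_report`.
#' @param prefix Output path prefix; writes `<prefix>.tsv` (per-gene labels)
#'   and `<prefix>.json` (full report).
#' @return The two paths, invisibly.
#' @export
write_evaluation_report <- function(report, prefix) {
  tsv <- paste0(prefix, ".tsv")
  json <- paste0(prefix, ".json")
  write.table(data.frame(gene_id = names(report$labels),
                         label = unname(report$labels)),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    trr = as.list(report$trr),
    counts = as.list(report$counts),
    automatic_precision_percent = report$automatic_percent,
    supervised_precision_percent = report$supervised_percent),
    json, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(c(tsv, json))
}
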