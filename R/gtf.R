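# All internal coordinates are 0-based half-open on the forward strand;
# conversion to 1-based inclusive happens only here, at GTF emission.

#' Write gene models as a toxin annotation GTF
#'
#' GTF2.2 dialect: per model one `transcript` line and one `CDS` line per
#' exon (frame column = phase), 1-based inclusive coordinates, attributes
#' `gene_id`, `transcript_id`, `family`, `status` (reliable|warning) and
#' `source_query`. Output order is (contig, start, id), so identical inputs
#' produce identical bytes.
#'
#' @param models List of `gene_model` objects.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_annotation_gtf <- function(models, path) {
  if (length(models) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  o <- order(vapply(models, `[[`, character(1), "contig_id"),
             vapply(models, function(m) min(m$exons[, "start"]), numeric(1)),
             vapply(models, `[[`, character(1), "id"))
  lines <- unlist(lapply(models[o], function(m) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; family "%s"; status "%s"; source_query "%s";',
                     m$id, m$id, m$family, m$status, m$source_query)
    tx <- sprintf("%s\ttoxannot\ttranscript\t%d\t%d\t%d\t%s\t.\t%s",
                  m$contig_id, min(m$exons[, "start"]) + 1L,
                  max(m$exons[, "end"]), as.integer(round(m$score)),
                  m$strand, attrs)
    cds <- vapply(seq_len(nrow(m$exons)), function(i)
      sprintf("%s\ttoxannot\tCDS\t%d\t%d\t%d\t%s\t%d\t%s",
              m$contig_id, m$exons[i, "start"] + 1L, m$exons[i, "end"],
              as.integer(round(m$score)), m$strand, m$phases[i], attrs),
      character(1))
    c(tx, cds)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a toxin annotation GTF back into gene models
#'
#' Reconstructs `gene_model` objects (exons in transcription order, phases,
#' status, family, source query) from a GTF written by
#' [write_annotation_gtf()]; CDS and peptide sequences are re-extracted
#' from the genome when one is supplied.
#'
#' @param path GTF file.
#' @param genome Optional genome (`DNAStringSet` or named character) used
#'   to re-splice each model's CDS.
#' @return List of `gene_model` objects.
#' @export
read_annotation_gtf <- function(path, genome = NULL) {
  if (!file.exists(path)) stop_input("annotation file not found: ", path)
  raw <- readLines(path)
  raw <- raw[nzchar(raw) & !startsWith(raw, "#")]
  if (length(raw) == 0L) return(list())
  f <- strsplit(raw, "\t", fixed = TRUE)
  df <- data.frame(contig = vapply(f, `[[`, "", 1L),
                   type = vapply(f, `[[`, "", 3L),
                   start = as.integer(vapply(f, `[[`, "", 4L)) - 1L,
                   end = as.integer(vapply(f, `[[`, "", 5L)),
                   score = vapply(f, `[[`, "", 6L),
                   strand = vapply(f, `[[`, "", 7L),
                   frame = vapply(f, `[[`, "", 8L),
                   attrs = vapply(f, `[[`, "", 9L),
                   stringsAsFactors = FALSE)
  get_attr <- function(a, key) {
    m <- regmatches(a, regexpr(sprintf('%s "[^"]*"', key), a))
    ifelse(lengths(regmatches(a, gregexpr(sprintf('%s "[^"]*"', key), a))) > 0,
           sub(sprintf('%s "([^"]*)"', key), "\\1", m), NA_character_)
  }
  df$gene_id <- vapply(df$attrs, get_attr, "", key = "gene_id")
  df$family <- vapply(df$attrs, get_attr, "", key = "family")
  df$status <- vapply(df$attrs, get_attr, "", key = "status")
  df$source_query <- vapply(df$attrs, get_attr, "", key = "source_query")
  cds <- df[df$type == "CDS", , drop = FALSE]
  models <- lapply(split(seq_len(nrow(cds)), cds$gene_id), function(ix) {
    sub <- cds[ix, , drop = FALSE]
    minus <- sub$strand[1L] == "-"
    sub <- sub[order(sub$start, decreasing = minus), , drop = FALSE]
    exons <- cbind(start = sub$start, end = sub$end)
    m <- list(id = sub$gene_id[1L], contig_id = sub$contig[1L],
              strand = sub$strand[1L], exons = exons,
              phases = as.integer(sub$frame),
              cds = NA_character_, peptide = NA_character_,
              status = sub$status[1L], source_query = sub$source_query[1L],
              family = sub$family[1L],
              score = as.numeric(sub$score[1L]), identity = NA_real_)
    if (!is.null(genome)) {
      m$cds <- splice_cds_from_genome(genome, m$contig_id, m$strand, exons)
      if (nchar(m$cds) %% 3L == 0L) m$peptide <- translate_cds(m$cds)
    }
    structure(m, class = "gene_model")
  })
  ids <- vapply(models, `[[`, character(1), "id")
  starts <- vapply(models, function(m) min(m$exons[, "start"]), numeric(1))
  contigs <- vapply(models, `[[`, character(1), "contig_id")
  unname(models[order(contigs, starts, ids)])
}

#' Write CDS and peptide FASTA for an annotation set
#'
#' @param models List of `gene_model` objects.
#' @param cds_path,pep_path Output FASTA paths.
#' @return The two paths, invisibly.
#' @export
write_model_fastas <- function(models, cds_path, pep_path) {
  o <- order(vapply(models, `[[`, character(1), "contig_id"),
             vapply(models, function(m) min(m$exons[, "start"]), numeric(1)),
             vapply(models, `[[`, character(1), "id"))
  models <- models[o]
  ids <- vapply(models, `[[`, character(1), "id")
  cds <- setNames(vapply(models, `[[`, character(1), "cds"), ids)
  pep <- setNames(vapply(models, `[[`, character(1), "peptide"), ids)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(cds), cds_path, width = 60L)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(pep), pep_path, width = 60L)
  invisible(c(cds_path, pep_path))
}

#' Write the warning-annotation report
#'
#' One tab-separated line per warning model: id, contig, 1-based inclusive
#' interval, and the reason (number of premature in-frame stops).
#'
#' @param models List of `gene_model` objects (all statuses; only warning
#'   models are written).
#' @param path Output TXT path.
#' @return `path`, invisibly.
#' @export
write_warnings <- function(models, path) {
  warn <- Filter(function(m) identical(m$status, "warning"), models)
  o <- order(vapply(warn, `[[`, character(1), "contig_id"),
             vapply(warn, function(m) min(m$exons[, "start"]), numeric(1)),
             vapply(warn, `[[`, character(1), "id"))
  lines <- vapply(warn[o], function(m)
    sprintf("%s\t%s\t%d-%d\tpremature_stop(%d)", m$id, m$contig_id,
            min(m$exons[, "start"]) + 1L, max(m$exons[, "end"]),
            count_internal_stops(m$cds)),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
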