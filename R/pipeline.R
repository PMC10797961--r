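# typed error helpers: input errors exit 2 at the CLI, internal errors 3
stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("toxannot_input_error",
                                             "toxannot_error")))
}

#' Pipeline configuration
#'
#' All tunable parameters of the annotation pipeline with their defaults:
#' maximum gene size 50 kb (only genes shorter than this are annotated),
#' minimum CDS length 200 bp, minimum hit identity 0.80, database
#' clustering threshold 0.99, full-length selection rule (coverage 0.95,
#' end tolerance 10 bp), and the search/splice scoring parameters. Every
#' value is echoed in the run log and the configuration serializes to and
#' from YAML.
#'
#' @param max_gene_size Maximum genomic span of an annotated gene (bp).
#' @param min_cds_len Minimum CDS length (bp).
#' @param min_identity Minimum hit identity fraction.
#' @param cluster_threshold Identity threshold for database clustering.
#' @param min_coverage,end_tolerance Full-length selection rule.
#' @param k,min_score Seed length and minimum hit score of the search.
#' @param splice A [splice_params()] object.
#' @param threads Worker count accepted for interface compatibility; the
#'   pipeline is deterministic and its result never depends on it.
#' @param seed Seed recorded for provenance (the annotation stages are
#'   deterministic; the seed matters for fixture generation only).
#' @return A list of class `toxannot_config`.
#' @export
toxannot_config <- function(max_gene_size = 50000L, min_cds_len = 200L,
                            min_identity = 0.80, cluster_threshold = 0.99,
                            min_coverage = 0.95, end_tolerance = 10L,
                            k = 11L, min_score = 50L,
                            splice = splice_params(), threads = 1L,
                            seed = 1L) {
  stopifnot(max_gene_size > 0, min_cds_len >= 3,
            min_identity > 0, min_identity <= 1,
            cluster_threshold > 0, cluster_threshold <= 1,
            min_coverage > 0, min_coverage <= 1, end_tolerance >= 0,
            threads >= 1)
  # an intron may span almost the whole permitted gene size
  splice$max_intron <- as.integer(max_gene_size)
  structure(list(max_gene_size = as.integer(max_gene_size),
                 min_cds_len = as.integer(min_cds_len),
                 min_identity = min_identity,
                 cluster_threshold = cluster_threshold,
                 min_coverage = min_coverage,
                 end_tolerance = as.integer(end_tolerance),
                 k = as.integer(k), min_score = as.integer(min_score),
                 splice = splice, threads = as.integer(threads),
                 seed = as.integer(seed)),
            class = "toxannot_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @param config A `toxannot_config`.
#' @return `read_config` returns a `toxannot_config`; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  sp <- do.call(splice_params, y$splice %||% list())
  y$splice <- sp
  do.call(toxannot_config, y)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  y <- unclass(config)
  y$splice <- unclass(y$splice)
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Annotate a genome in memory
#'
#' Runs the annotation stages on in-memory objects: similarity search,
#' collinear hit chaining, full-length locus selection, matched-region
#' construction, spliced gene-model building, boundary finalization,
#' reliable/warning classification and overlap resolution. Model ids are
#' assigned per family in (contig, start) order.
#'
#' @param genome A `DNAStringSet` or named character vector.
#' @param db A `toxin_db`.
#' @param config A [toxannot_config()].
#' @param log Optional function called with one structured message per
#'   stage (e.g. `message`).
#' @return A list of class `toxannot_result` with `models` (final
#'   annotation set), `all_models`, `rejections`, `regions`
#'   (`matched_regions`), `loci`, `hits` and `config`.
#' @export
annotate_genome <- function(genome, db, config = toxannot_config(),
                            log = NULL) {
  g <- as_genome(genome)
  if (nrow(db$records) == 0L) stop_input("empty toxin database")
  say <- function(fmt, ...) if (!is.null(log)) log(sprintf(fmt, ...))

  sp <- search_params(k = config$k, min_score = config$min_score,
                      min_identity = config$min_identity)
  hits <- search_hits(db, g, sp)
  say("search: %d queries vs %d contigs -> %d hits", nrow(db$records),
      length(g), nrow(hits))

  qlen <- setNames(db$records$length, db$records$id)
  loci <- chain_hits(hits, qlen, max_gene_size = config$max_gene_size)
  rule <- full_length_rule(config$min_coverage, config$end_tolerance)
  status <- vapply(loci, classify_locus, character(1), rule = rule)
  full <- loci[status == "full_length"]
  say("chaining: %d loci (%d full-length, %d partial)",
      length(loci), length(full), sum(status == "partial"))

  regions <- build_matched_regions(full)
  say("matched regions: %d", nrow(regions))

  models <- list(); rejections <- list()
  for (locus in full) {
    region <- extract_region(g, locus, flank = config$splice$flank)
    qrec <- db$records[db$records$id == locus$query_id, , drop = FALSE]
    aln <- spliced_align(qrec$cds, region, params = config$splice,
                         locus = locus)
    res <- finalize_model(aln, qrec, region, params = config$splice,
                          min_cds_len = config$min_cds_len)
    if (inherits(res, "gene_model")) models[[length(models) + 1L]] <- res
    else rejections[[length(rejections) + 1L]] <- res
  }
  say("gene models: %d built, %d rejected", length(models),
      length(rejections))

  final <- resolve_overlaps(models)
  # family-wise ids in (contig, start) order
  fams <- vapply(final, `[[`, character(1), "family")
  idx <- stats::ave(seq_along(final), fams, FUN = seq_along)
  for (i in seq_along(final)) final[[i]]$id <- sprintf("%s-%d", fams[i], idx[i])
  n_warn <- sum(vapply(final, `[[`, character(1), "status") == "warning")
  say("final annotation: %d models (%d reliable, %d warning)",
      length(final), length(final) - n_warn, n_warn)

  structure(list(models = final, all_models = models,
                 rejections = rejections, regions = regions, loci = loci,
                 hits = hits, config = config),
            class = "toxannot_result")
}

#' @export
print.toxannot_result <- function(x, ...) {
  st <- vapply(x$models, `[[`, character(1), "status")
  cat(sprintf("toxin annotation: %d models (%d reliable, %d warning), %d matched regions\n",
              length(x$models), sum(st == "reliable"), sum(st == "warning"),
              nrow(x$regions)))
  invisible(x)
}

#' Run the full annotation pipeline on files
#'
#' Reads the genome and database(s), optionally screens venom-tissue
#' transcripts into a custom database and merges it, annotates, and writes
#' all outputs to `outdir`: `toxin_annotation.gtf`, `matched_regions.gtf`,
#' `toxins_cds.fasta`, `toxins_pep.fasta`, `annotation_warning.txt`,
#' `run_log.txt` and (when transcripts are given) `custom_database.fasta`.
#' Outputs are bit-stable given identical inputs and configuration.
#'
#' @param genome_path Genome assembly FASTA.
#' @param db_path Toxin database FASTA (full-length CDSs).
#' @param custom_db_path Optional additional database FASTA merged into the
#'   main one.
#' @param transcripts_path Optional assembled venom-tissue transcripts
#'   FASTA; screened with [screen_transcripts()] and merged.
#' @param outdir Output directory (created if needed).
#' @param config A [toxannot_config()].
#' @return A `toxannot_result` (invisibly), with an added `paths` element.
#' @export
run_pipeline <- function(genome_path, db_path, custom_db_path = NULL,
                         transcripts_path = NULL, outdir = "toxannot_out",
                         config = toxannot_config()) {
  genome <- read_genome(genome_path)
  db <- read_toxin_db(db_path, min_cds_len = config$min_cds_len)
  if (nrow(db$records) == 0L) stop_input("empty toxin database: ", db_path)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  log <- function(msg) log_lines <<- c(log_lines, msg)

  cfg_flat <- unlist(utils::modifyList(unclass(config),
                                       list(splice = unclass(config$splice))))
  log(paste0("config: ", paste(names(cfg_flat), cfg_flat, sep = "=",
                               collapse = " ")))
  log(sprintf("inputs: genome=%s database=%s", genome_path, db_path))

  if (!is.null(custom_db_path)) {
    custom <- read_toxin_db(custom_db_path, min_cds_len = config$min_cds_len)
    db <- merge_databases(db, custom)
    log(sprintf("custom database: %d records merged -> %d total",
                nrow(custom$records), nrow(db$records)))
  }
  paths <- c(annotation = file.path(outdir, "toxin_annotation.gtf"),
             regions = file.path(outdir, "matched_regions.gtf"),
             cds = file.path(outdir, "toxins_cds.fasta"),
             pep = file.path(outdir, "toxins_pep.fasta"),
             warnings = file.path(outdir, "annotation_warning.txt"),
             log = file.path(outdir, "run_log.txt"))
  if (!is.null(transcripts_path)) {
    transcripts <- read_genome(transcripts_path)
    custom <- screen_transcripts(transcripts, db,
                                 params = screen_params(
                                   min_identity = config$min_identity),
                                 min_cds_len = config$min_cds_len)
    log(sprintf("transcript screening: %d transcripts -> %d custom CDSs",
                length(transcripts), nrow(custom$records)))
    if (nrow(custom$records) > 0L) {
      paths <- c(paths, custom_db = file.path(outdir, "custom_database.fasta"))
      write_toxin_db(custom, paths[["custom_db"]])
      db <- merge_databases(db, custom)
      log(sprintf("merged database: %d records", nrow(db$records)))
    }
  }

  res <- annotate_genome(genome, db, config, log = log)

  write_annotation_gtf(res$models, paths[["annotation"]])
  write_matched_regions_gtf(res$regions, paths[["regions"]])
  write_model_fastas(res$models, paths[["cds"]], paths[["pep"]])
  write_warnings(res$models, paths[["warnings"]])
  writeLines(log_lines, paths[["log"]])
  res$paths <- paths
  invisible(res)
}
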