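# Independent oracles used across the suite. These deliberately avoid the
# package's own alignment/chaining code paths.

# identity of two equal-length strings under substitution-only divergence
count_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  mean(va == vb)
}

# best local alignment score via Biostrings (affine scoring matched to the
# search engine: +2/-3, gap open 5, gap extension 2)
biostrings_local_score <- function(a, b, match = 2, mismatch = -3,
                                   gap_open = 5, gap_ext = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(a, b, type = "local",
                                substitutionMatrix = mat,
                                gapOpening = gap_open,
                                gapExtension = gap_ext,
                                scoreOnly = TRUE)
}

# exhaustive best collinear-chain score over all hit subsets (<= ~10 hits):
# score = sum of hit scores - (join_penalty + gap/gap_scale) per join,
# subject to the same constraints the chainer states (span, order, bounded
# overlap)
brute_force_chain_score <- function(h, max_gene_size = 50000,
                                    join_penalty = 10, max_overlap = 15,
                                    gap_scale = 1000) {
  n <- nrow(h)
  if (h$strand[1] == "+") { gs <- h$tstart; ge <- h$tend }
  else { gs <- -h$tend; ge <- -h$tstart }
  best <- -Inf
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(idx) == 0) next
    o <- order(gs[idx], ge[idx])
    idx <- idx[o]
    ok <- TRUE
    if (length(idx) > 1) {
      for (k in seq_len(length(idx) - 1L)) {
        i <- idx[k]; j <- idx[k + 1L]
        if (h$qstart[j] < h$qend[i] - max_overlap || h$qend[j] <= h$qend[i] ||
            h$qstart[j] <= h$qstart[i] || gs[j] < ge[i] - max_overlap ||
            ge[j] <= ge[i] || gs[j] <= gs[i]) { ok <- FALSE; break }
      }
    }
    if (!ok) next
    if (max(ge[idx]) - min(gs[idx]) > max_gene_size) next
    gaps <- if (length(idx) > 1)
      pmax(0, gs[idx][-1] - ge[idx][-length(idx)]) else numeric(0)
    sc <- sum(h$score[idx]) - join_penalty * (length(idx) - 1L) -
      sum(gaps) / gap_scale
    if (sc > best) best <- sc
  }
  best
}

# random hit table generator for chaining property tests
random_hits <- function(n, seed) {
  set.seed(seed)
  qs <- sort(sample(0:400, n))
  qe <- qs + sample(30:120, n, replace = TRUE)
  ts <- sort(sample(0:20000, n)) + sample(-50:50, n, replace = TRUE)
  te <- ts + (qe - qs) + sample(-5:5, n, replace = TRUE)
  te <- pmax(te, ts + 1L)
  data.frame(query_id = "q", contig_id = "c", strand = "+",
             qstart = qs, qend = qe, tstart = ts, tend = te,
             identity = runif(n, 0.85, 1),
             score = sample(40:200, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# deterministic random DNA
rand_dna <- function(n, seed, gc = 0.5) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# substitute exactly k positions of a CDS interior, avoiding new in-frame
# stops (positions 4..L-3)
sub_mutate <- function(cds, k, seed) {
  set.seed(seed)
  x <- strsplit(cds, "")[[1]]
  L <- length(x)
  repeat {
    pos <- sample(seq.int(4L, L - 3L), k)
    y <- x
    for (p in pos) y[p] <- sample(setdiff(c("A", "C", "G", "T"), y[p]), 1)
    out <- paste(y, collapse = "")
    cods <- substring(out, seq(1, L - 2, 3), seq(3, L, 3))
    if (!any(cods[-length(cods)] %in% c("TAA", "TAG", "TGA"))) return(out)
  }
}
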