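#' Score a candidate site under a profile
#'
#' Additive position-weight score: the sum over positions of the weight of
#' the base observed there, `score = sum_i w(seq_i, i)`.
#'
#' @param profile a `motif_profile`.
#' @param seq character L-mer over A/C/G/T (ambiguity codes are an error).
#' @return numeric score.
#' @export
score_site <- function(profile, seq) {
  idx <- seq_to_int(seq)
  if (length(idx) != profile$L) {
    stop("sequence length ", length(idx), " != profile width ", profile$L)
  }
  sum(profile$weights[cbind(idx, seq_len(profile$L))])
}

#' Set the score threshold from the training set
#'
#' The threshold is the lowest score observed among the training sites, so
#' every training site passes by construction and the threshold can only
#' stay or decrease as sites are added to the training set.
#'
#' @param profile a `motif_profile`.
#' @param training_sites character vector of L-mers; defaults to the
#'   profile's own training sites.
#' @return the profile with `threshold` (and `training_sites`) set.
#' @export
set_threshold <- function(profile, training_sites = profile$training_sites) {
  if (length(training_sites) == 0L) {
    stop("cannot set a threshold from an empty training set")
  }
  scores <- vapply(training_sites, function(s) score_site(profile, s),
                   numeric(1))
  profile$threshold <- min(scores)
  profile$training_sites <- unname(training_sites)
  profile
}

#' Scan one region for sites scoring at or above the threshold
#'
#' Every window of width L on both strands is scored; windows with
#' `score >= threshold` are returned sorted by (offset, strand). For
#' palindromic profiles the + and - hits at one offset have equal score and
#' are collapsed to a single "+" record. Overlapping hits are all reported;
#' per-operon deduplication is a regulon-level concern.
#'
#' @param profile a `motif_profile`.
#' @param region character region sequence (oriented 5'->3' toward the
#'   gene), or a one-row `upstream_regions` data.frame.
#' @param threshold score cutoff; defaults to the profile's stored
#'   threshold.
#' @param slack optional fractional relaxation of the threshold for
#'   exploratory scans (effective cutoff `threshold - slack * |threshold|`;
#'   default 0 reproduces the minimum-training-score rule exactly).
#' @return data.frame of class `scan_hits`: `offset` (1-based within the
#'   region), `strand` (relative to the region), `sequence` (site as
#'   matched, reverse-complemented for "-" hits), `score`, `passed`.
#' @export
scan_region <- function(profile, region, threshold = profile$threshold,
                        slack = 0) {
  if (is.data.frame(region)) region <- region$seq[1L]
  if (is.na(threshold)) {
    stop("no threshold: call set_threshold() or pass one explicitly")
  }
  cutoff <- threshold - slack * abs(threshold)
  empty <- data.frame(offset = integer(), strand = character(),
                      sequence = character(), score = numeric(),
                      passed = logical(), stringsAsFactors = FALSE)
  class(empty) <- c("scan_hits", "data.frame")
  if (nchar(region) < profile$L) {
    message("region shorter than profile width; no windows to scan")
    return(empty)
  }
  ints <- seq_to_int(region)
  sc <- score_windows(ints, profile$weights)
  L <- profile$L
  hit_f <- which(sc$fwd >= cutoff - 1e-12)
  hit_r <- which(sc$rev >= cutoff - 1e-12)
  take <- function(off, strand, score) {
    s <- substr(rep(region, length(off)), off, off + L - 1L)
    if (strand == "-") s <- revcomp(s)
    data.frame(offset = off, strand = strand, sequence = s, score = score,
               passed = TRUE, stringsAsFactors = FALSE)
  }
  out <- rbind(
    if (length(hit_f)) take(hit_f, "+", sc$fwd[hit_f]) else empty,
    if (length(hit_r)) take(hit_r, "-", sc$rev[hit_r]) else empty
  )
  if (profile$palindromic && nrow(out)) {
    # +/- hits at one offset score identically; keep the "+" record
    dup <- out$strand == "-" & out$offset %in% out$offset[out$strand == "+"]
    out <- out[!dup, , drop = FALSE]
  }
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("scan_hits", "data.frame")
  out
}

#' Scan all operon upstream regions of a genome
#'
#' @param profile a `motif_profile` with its threshold set (or `threshold`
#'   given).
#' @param genome a [genome_annotation()].
#' @param operons an `operon_table` for the genome; computed with defaults
#'   when NULL.
#' @param window,truncate_at_neighbor,min_len region extraction parameters,
#'   see [extract_upstream()].
#' @param threshold,slack see [scan_region()].
#' @return data.frame: one row per hit with `genome_id`, `operon_id`,
#'   `offset`, `strand`, `sequence`, `score`, `passed`, plus the genomic
#'   `position` (1-based plus-strand start of the site).
#' @export
scan_genome <- function(profile, genome, operons = NULL,
                        window = c(300L, 20L), truncate_at_neighbor = TRUE,
                        min_len = 30L, threshold = profile$threshold,
                        slack = 0) {
  if (is.null(operons)) operons <- predict_operons(genome)
  if (nrow(operons) == 0L) {
    return(data.frame(genome_id = character(), operon_id = character(),
                      offset = integer(), position = integer(),
                      strand = character(), sequence = character(),
                      score = numeric(), passed = logical(),
                      stringsAsFactors = FALSE))
  }
  regions <- extract_upstream(genome, operons, window = window,
                              truncate_at_neighbor = truncate_at_neighbor,
                              min_len = min_len)
  scan_upstream_regions(profile, regions, threshold = threshold,
                        slack = slack)
}

# scan a prepared upstream_regions table
scan_upstream_regions <- function(profile, regions,
                                  threshold = profile$threshold, slack = 0) {
  out <- lapply(seq_len(nrow(regions)), function(i) {
    h <- scan_region(profile, regions$seq[i], threshold = threshold,
                     slack = slack)
    if (nrow(h) == 0L) return(NULL)
    rg <- regions[i, ]
    # genomic plus-strand start of each site
    pos <- if (rg$strand == "+") rg$start + h$offset - 1L
    else rg$end - h$offset - profile$L + 2L
    data.frame(genome_id = rg$genome_id, operon_id = rg$operon_id,
               offset = h$offset, position = pos, strand = h$strand,
               sequence = h$sequence, score = h$score, passed = h$passed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(genome_id = character(), operon_id = character(),
                      offset = integer(), position = integer(),
                      strand = character(), sequence = character(),
                      score = numeric(), passed = logical(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Write a hit table as TSV
#'
#' Scores are reported to 4 decimal places in the file; internal
#' comparisons always use exact floats.
#'
#' @param hits hit table from [scan_genome()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_hit_table <- function(hits, path) {
  hits$score <- sprintf("%.4f", hits$score)
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
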