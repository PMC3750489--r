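# Independent oracles and small builders shared across the test files.
# These deliberately re-derive results with naive loops / closed forms so
# they never share code paths with the package implementation.

BASES <- c("A", "C", "G", "T")

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

naive_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# naive additive scoring of one L-mer under a 4xL weight matrix
naive_score <- function(weights, s) {
  chars <- strsplit(s, "")[[1]]
  tot <- 0
  for (i in seq_along(chars)) tot <- tot + weights[chars[i], i]
  tot
}

# brute-force scan: enumerate every window on both strands with loops
brute_force_scan <- function(weights, region, threshold) {
  L <- ncol(weights)
  hits <- list()
  for (o in seq_len(nchar(region) - L + 1)) {
    win <- substr(region, o, o + L - 1)
    sf <- naive_score(weights, win)
    sr <- naive_score(weights, naive_revcomp(win))
    if (sf >= threshold - 1e-9) {
      hits[[length(hits) + 1]] <- data.frame(offset = o, strand = "+",
                                             score = sf)
    }
    if (sr >= threshold - 1e-9) {
      hits[[length(hits) + 1]] <- data.frame(offset = o, strand = "-",
                                             score = sr)
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(offset = integer(), strand = character(),
                      score = numeric())
  }
  out[order(out$offset, out$strand), , drop = FALSE]
}

# exhaustive hypergeometric upper tail from binomial coefficients
hyper_tail_oracle <- function(overlap, n_regulon, n_induced, n_universe) {
  ks <- overlap:min(n_regulon, n_induced)
  sum(choose(n_regulon, ks) *
        choose(n_universe - n_regulon, n_induced - ks)) /
    choose(n_universe, n_induced)
}

# one-contig genome builder: genes placed at given (start, end, strand)
toy_genome <- function(genome_id, contig_seq, genes,
                       contig_id = "c1") {
  genes$contig <- rep(contig_id, nrow(genes))
  genome_annotation(genome_id, stats::setNames(contig_seq, contig_id),
                    genes)
}

# profile with a fixed threshold, built from explicit sites
trained_profile <- function(sites, ...) {
  set_threshold(build_pwm(sites, ...), sites)
}

# plant a given site string inside a random region at a known offset
plant_in_region <- function(site, region_len, offset, gc = 0.5) {
  stopifnot(offset + nchar(site) - 1 <= region_len)
  r <- random_dna(region_len, gc)
  paste0(substr(r, 1, offset - 1), site,
         substr(r, offset + nchar(site), region_len))
}
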