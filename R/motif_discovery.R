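#' Build a positional-weight profile from aligned sites
#'
#' Counts `n(b,i)` are raw occurrences over the `N` aligned L-mers; weights
#' are the log-odds
#' \deqn{w(b,i) = \log_2\frac{n(b,i)+p}{(N+4p)\,q(b)}}
#' with pseudocount `p` per base against background `q`. A candidate site's
#' score is the sum of the weights of its bases, so any training site scores
#' the profile additively. With `palindromic = TRUE` the counts are
#' symmetrized by averaging with their reverse-complement mirror
#' (`n'(b,i) = (n(b,i) + n(comp(b), L+1-i))/2`), giving
#' `w(b,i) = w(comp(b), L+1-i)`.
#'
#' @param sites character vector of aligned sites, all the same length, over
#'   A/C/G/T only (no IUPAC ambiguity codes).
#' @param background numeric length-4 base probabilities (A,C,G,T), summing
#'   to 1; default uniform.
#' @param pseudocount positive pseudocount per base, default 0.25.
#' @param palindromic symmetrize the profile (default FALSE).
#' @return object of class `motif_profile`: list with `L`, `counts` (4 x L),
#'   `weights` (4 x L), `background`, `pseudocount`, `palindromic`,
#'   `n_sites`, `training_sites`, `threshold` (NA until [set_threshold()]),
#'   `consensus`.
#' @export
build_pwm <- function(sites, background = rep(0.25, 4), pseudocount = 0.25,
                      palindromic = FALSE) {
  if (length(sites) == 0L) stop("no sites supplied")
  L <- nchar(sites[1L])
  if (any(nchar(sites) != L)) stop("sites have unequal lengths")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  background <- background / sum(background)
  mat <- vapply(sites, seq_to_int, integer(L))
  if (L == 1L) mat <- matrix(mat, nrow = 1L)
  counts <- matrix(0, 4L, L, dimnames = list(DNA_BASES, NULL))
  for (b in 1:4) counts[b, ] <- rowSums(mat == b)
  profile_from_counts(counts, length(sites), background, pseudocount,
                      palindromic, training_sites = unname(sites))
}

# core constructor shared by build_pwm and the Gibbs sampler
profile_from_counts <- function(counts, n_sites, background, pseudocount,
                                palindromic, training_sites = character()) {
  if (palindromic) counts <- symmetrize_counts(counts)
  f <- (counts + pseudocount) / (n_sites + 4 * pseudocount)
  weights <- log2(f / background)
  cons <- paste(DNA_BASES[apply(counts, 2L, which.max)], collapse = "")
  structure(list(L = ncol(counts), counts = counts, weights = weights,
                 background = stats::setNames(background, DNA_BASES),
                 pseudocount = pseudocount, palindromic = palindromic,
                 n_sites = n_sites, training_sites = training_sites,
                 threshold = NA_real_, consensus = cons),
            class = "motif_profile")
}

symmetrize_counts <- function(counts) {
  (counts + counts[4:1, ncol(counts):1, drop = FALSE]) / 2
}

#' @export
print.motif_profile <- function(x, ...) {
  cat("<motif_profile> L=", x$L, ", ", x$n_sites, " training sites",
      if (x$palindromic) ", palindromic", ", consensus ", x$consensus,
      if (!is.na(x$threshold)) sprintf(", threshold %.4f", x$threshold),
      "\n", sep = "")
  invisible(x)
}

# pseudocounted per-position frequencies
pwm_frequencies <- function(profile) {
  (profile$counts + profile$pseudocount) /
    (profile$n_sites + 4 * profile$pseudocount)
}

#' Per-position and total information content of a profile
#'
#' `IC_i = 2 + sum_b f(b,i) log2 f(b,i)` with `f` the pseudocounted column
#' frequencies; each position lies in `[0, 2]` bits.
#'
#' @param profile a `motif_profile`.
#' @return list with `per_position` (numeric, bits) and `total`.
#' @export
information_content <- function(profile) {
  f <- pwm_frequencies(profile)
  per <- apply(f, 2L, function(col) 2 + sum(col * log2(col)))
  list(per_position = per, total = sum(per))
}

# objective used by discovery: total information content of the profile
# built from the currently aligned sites
alignment_objective <- function(site_mat, pseudocount, palindromic) {
  counts <- matrix(0, 4L, ncol(site_mat), dimnames = list(DNA_BASES, NULL))
  for (b in 1:4) counts[b, ] <- colSums(site_mat == b)
  if (palindromic) counts <- symmetrize_counts(counts)
  f <- (counts + pseudocount) / (nrow(site_mat) + 4 * pseudocount)
  sum(apply(f, 2L, function(col) 2 + sum(col * log2(col))))
}

# score every window of an integer sequence on both strands.
# W is the 4 x L weight matrix; returns list(fwd, rev) of length n-L+1.
score_windows <- function(int_seq, W) {
  L <- ncol(W)
  n <- length(int_seq)
  nw <- n - L + 1L
  if (nw < 1L) return(list(fwd = numeric(0), rev = numeric(0)))
  Wrc <- W[4:1, L:1, drop = FALSE]
  idx <- rep(seq_len(nw), L) + rep(0:(L - 1L), each = nw)
  base <- int_seq[idx]
  col <- rep(seq_len(L), each = nw)
  fwd <- rowSums(matrix(W[cbind(base, col)], nw, L))
  rev <- rowSums(matrix(Wrc[cbind(base, col)], nw, L))
  list(fwd = fwd, rev = rev)
}

#' Discover a shared motif in upstream regions (Gibbs site sampler)
#'
#' One-occurrence-per-region Gibbs sampling with a simulated-annealing
#' finish, greedy polishing, and phase-shift moves (the whole alignment is
#' tried at small column offsets to escape shifted local optima), restarted
#' `n_restarts` times. Both strands of every region are considered; in
#' `symmetry = "palindrome"` mode the profile is symmetrized at every step.
#' With `zoops = TRUE` each region may instead opt out of the alignment: a
#' window competes against a null option whose log-odds score is
#' `log2(2 m_i (1-gamma)/gamma)` for a region with `m_i` windows per
#' strand, i.e. a site is kept only when it beats what the best of that
#' many background windows would warrant under the site prior `gamma`.
#' Results are deterministic given `seed`, and restart `r` consumes its own
#' seed stream, so enlarging `n_restarts` can only improve (never change
#' earlier restarts' result or decrease) the best objective.
#'
#' The reported objective is the total information content of the aligned
#' sites (one-per-region mode) or, in zero-or-one mode, the total site
#' score in excess of the null scores, which the sampler maximizes.
#'
#' @param regions an `upstream_regions` data.frame or plain character vector
#'   of region sequences.
#' @param L motif width in nt.
#' @param symmetry `"none"` or `"palindrome"`.
#' @param n_restarts random restarts (default 20).
#' @param seed integer seed governing all sampling.
#' @param zoops allow zero-or-one occurrence per region (default FALSE,
#'   exactly one site per region).
#' @param gamma prior probability that a region contains a site in zoops
#'   mode (default 0.5).
#' @param n_iter annealing passes per restart (default 40).
#' @param background,pseudocount passed to the profile; background defaults
#'   to uniform.
#' @return list with `profile` (a `motif_profile` built from the final
#'   sites), `sites` (data.frame: `region`, `operon_id`, `offset` 1-based
#'   within the oriented region, `strand_relative`, `sequence`, `score`),
#'   `objective`, and `restart_objectives`.
#' @export
discover_profile <- function(regions, L, symmetry = c("none", "palindrome"),
                             n_restarts = 20L, seed = 1L, zoops = FALSE,
                             gamma = 0.5, n_iter = 40L,
                             background = rep(0.25, 4),
                             pseudocount = 0.25) {
  symmetry <- match.arg(symmetry)
  palin <- symmetry == "palindrome"
  if (is.data.frame(regions)) {
    seqs <- regions$seq
    ids <- regions$operon_id
  } else {
    seqs <- as.character(regions)
    ids <- names(seqs) %||% paste0("region", seq_along(seqs))
  }
  ok <- nchar(seqs) >= L
  if (any(!ok)) {
    warning(sum(!ok), " region(s) shorter than L=", L, " skipped")
  }
  seqs <- seqs[ok]; ids <- ids[ok]
  if (length(seqs) < 2L) stop("need at least 2 regions of length >= L")
  ints <- lapply(seqs, seq_to_int)
  nw <- vapply(ints, length, integer(1)) - L + 1L
  N <- length(ints)
  background <- background / sum(background)
  null_score <- if (zoops) log2(2 * nw * (1 - gamma) / gamma) else
    rep(-Inf, N)

  restart_seeds <- with_stream(seed, "discover-restarts",
                               sample.int(2147483646L, n_restarts,
                                          replace = TRUE))
  # restart seeding: occurrences of over-represented words. Words shared by
  # many regions are almost always motif cores, so starting the sampler at
  # one of them lands it near the global basin far more often than a
  # uniform random start.
  k <- min(8L, L)
  word_occ <- local({
    occ <- do.call(rbind, lapply(seq_len(N), function(i) {
      m <- nchar(seqs[i]) - k + 1L
      w <- substring(seqs[i], seq_len(m), seq_len(m) + k - 1L)
      data.frame(region = i, pos = seq_len(m), word = w,
                 stringsAsFactors = FALSE)
    }))
    rc <- revcomp(occ$word)
    occ$canon <- ifelse(occ$word <= rc, occ$word, rc)
    counts <- sort(table(occ$canon), decreasing = TRUE)
    top <- names(counts)[seq_len(min(20L, length(counts)))]
    occ[occ$canon %in% top, c("region", "pos"), drop = FALSE]
  })
  extract_site <- function(r, off, strand) {
    v <- ints[[r]][off:(off + L - 1L)]
    if (strand == 2L) comp_idx(rev(v)) else v
  }
  weights_of <- function(counts, n_in) {
    cc <- if (palin) symmetrize_counts(counts) else counts
    f <- (cc + pseudocount) / (n_in + 4 * pseudocount)
    log2(f / background)
  }
  state_objective <- function(site_mat, use, off) {
    sm <- site_mat[use, , drop = FALSE]
    if (nrow(sm) == 0L) return(-Inf)
    if (!zoops) return(alignment_objective(sm, pseudocount, palin))
    counts <- matrix(0, 4L, L)
    for (b in 1:4) counts[b, ] <- colSums(sm == b)
    W <- weights_of(counts, nrow(sm))
    sc <- rowSums(matrix(W[cbind(as.vector(t(sm)),
                                 rep(seq_len(L), nrow(sm)))],
                         nrow(sm), L, byrow = TRUE))
    sum(sc - null_score[use])
  }
  best <- NULL
  objs <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    set.seed(restart_seeds[r])
    # site-projection start: seed the alignment from one window containing
    # an over-represented word (uniform random window when none exists),
    # align every region to it greedily, then anneal from there
    if (nrow(word_occ)) {
      oi <- word_occ[sample.int(nrow(word_occ), 1L), ]
      seed_region <- oi$region
      lo <- max(1L, oi$pos + k - L)
      hi <- min(oi$pos, nw[seed_region])
      seed_off <- if (lo <= hi) lo + sample.int(hi - lo + 1L, 1L) - 1L
      else sample.int(nw[seed_region], 1L)
    } else {
      seed_region <- sample.int(N, 1L)
      seed_off <- sample.int(nw[seed_region], 1L)
    }
    seed_strand <- sample.int(2L, 1L)
    seed_counts <- matrix(0, 4L, L, dimnames = list(DNA_BASES, NULL))
    seed_site <- extract_site(seed_region, seed_off, seed_strand)
    seed_counts[cbind(seed_site, seq_len(L))] <- 1
    W0 <- weights_of(seed_counts, 1L)
    off <- integer(N); strand <- integer(N)
    for (i in seq_len(N)) {
      sc <- score_windows(ints[[i]], W0)
      pick <- which.max(c(sc$fwd, sc$rev))
      if (pick <= nw[i]) { off[i] <- pick; strand[i] <- 1L }
      else { off[i] <- pick - nw[i]; strand[i] <- 2L }
    }
    use <- rep(TRUE, N)
    site_mat <- t(vapply(seq_len(N),
                         function(i) extract_site(i, off[i], strand[i]),
                         integer(L)))
    counts <- matrix(0, 4L, L, dimnames = list(DNA_BASES, NULL))
    for (b in 1:4) counts[b, ] <- colSums(site_mat == b)

    one_pass <- function(temp, greedy) {
      changed <- FALSE
      for (i in seq_len(N)) {
        if (use[i]) {
          ci <- counts
          hot <- cbind(site_mat[i, ], seq_len(L))
          ci[hot] <- ci[hot] - 1
        } else ci <- counts
        n_in <- sum(use) - as.integer(use[i])
        W <- weights_of(ci, n_in)
        sc <- score_windows(ints[[i]], W)
        cand <- c(sc$fwd, sc$rev)
        if (zoops) cand <- c(cand, null_score[i])
        if (greedy) {
          pick <- which.max(cand)
        } else {
          p <- exp((cand - max(cand)) * log(2) / temp)
          pick <- sample.int(length(cand), 1L, prob = p)
        }
        new_use <- TRUE; new_off <- off[i]; new_strand <- strand[i]
        if (zoops && pick == 2L * nw[i] + 1L) {
          new_use <- FALSE
        } else if (pick <= nw[i]) {
          new_off <- pick; new_strand <- 1L
        } else {
          new_off <- pick - nw[i]; new_strand <- 2L
        }
        if (new_use != use[i] || new_off != off[i] ||
            new_strand != strand[i]) changed <- TRUE
        # write back
        if (use[i]) {
          hot <- cbind(site_mat[i, ], seq_len(L))
          counts[hot] <<- counts[hot] - 1
        }
        use[i] <<- new_use; off[i] <<- new_off; strand[i] <<- new_strand
        if (new_use) {
          site_mat[i, ] <<- extract_site(i, new_off, new_strand)
          hot <- cbind(site_mat[i, ], seq_len(L))
          counts[hot] <<- counts[hot] + 1
        }
      }
      changed
    }
    # try moving the whole alignment a few columns left/right
    shift_pass <- function() {
      cur <- state_objective(site_mat, use, off)
      improved <- FALSE
      for (s in c(-3:-1, 1:3)) {
        ui <- which(use)
        new_off <- off
        new_off[ui] <- off[ui] + ifelse(strand[ui] == 1L, s, -s)
        if (any(new_off[ui] < 1L | new_off[ui] > nw[ui])) next
        sm <- site_mat
        for (i in ui) sm[i, ] <- extract_site(i, new_off[i], strand[i])
        obj_s <- state_objective(sm, use, new_off)
        if (obj_s > cur + 1e-9) {
          off <<- new_off; site_mat <<- sm
          counts_new <- matrix(0, 4L, L, dimnames = list(DNA_BASES, NULL))
          smu <- sm[use, , drop = FALSE]
          for (b in 1:4) counts_new[b, ] <- colSums(smu == b)
          counts <<- counts_new
          cur <- obj_s
          improved <- TRUE
        }
      }
      improved
    }
    for (t in seq_len(n_iter)) {
      temp <- max(0.1, 1.2 * (1 - t / n_iter))
      one_pass(temp, greedy = FALSE)
      if (t %% 10L == 0L) shift_pass()
    }
    for (t in 1:15) {
      moved <- one_pass(0, greedy = TRUE)
      shifted <- shift_pass()
      if (!moved && !shifted) break
    }
    obj <- state_objective(site_mat, use, off)
    objs[r] <- obj
    if (is.null(best) || obj > best$objective + 1e-12) {
      best <- list(objective = obj, off = off, strand = strand, use = use,
                   site_mat = site_mat)
    }
  }

  keep <- which(best$use)
  if (length(keep) == 0L) {
    stop("no sites retained by discovery; lower gamma or disable zoops")
  }
  site_seqs <- vapply(keep, function(i) int_to_seq(best$site_mat[i, ]),
                      character(1))
  profile <- build_pwm(site_seqs, background = background,
                       pseudocount = pseudocount, palindromic = palin)
  sites <- data.frame(
    region = keep,
    operon_id = ids[keep],
    offset = best$off[keep],
    strand_relative = c("+", "-")[best$strand[keep]],
    sequence = site_seqs,
    stringsAsFactors = FALSE
  )
  sites$score <- vapply(sites$sequence, function(s) score_site(profile, s),
                        numeric(1))
  list(profile = profile, sites = sites, objective = best$objective,
       restart_objectives = objs)
}

#' Write a profile in MEME minimal motif format
#'
#' @param profile a `motif_profile`.
#' @param path output file.
#' @param name motif name recorded in the file.
#' @return invisibly, `path`.
#' @export
write_meme <- function(profile, path, name = "motif") {
  f <- pwm_frequencies(profile)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", DNA_BASES, profile$background),
                     collapse = " "), "",
               paste("MOTIF", name),
               sprintf(
                 "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                 profile$L, profile$n_sites)), con)
  writeLines(apply(f, 2L, function(col)
    paste(sprintf("%.6f", col), collapse = "  ")), con)
  invisible(path)
}

#' Read a MEME minimal motif file written by [write_meme()]
#'
#' Frequencies are converted back to counts using the recorded `nsites`.
#'
#' @param path MEME minimal format file.
#' @param background,pseudocount profile parameters (background defaults to
#'   the file's background line).
#' @return a `motif_profile`.
#' @export
read_meme <- function(path, background = NULL, pseudocount = 0.25) {
  lines <- readLines(path)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i) && is.null(background)) {
    toks <- strsplit(trimws(lines[bg_i + 1L]), "\\s+")[[1L]]
    background <- as.numeric(toks[seq(2, 8, by = 2)])
  }
  if (is.null(background)) background <- rep(0.25, 4)
  hdr <- grep("^letter-probability matrix", lines)[1L]
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
  nsites <- as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", lines[hdr]))
  rows <- lines[(hdr + 1L):(hdr + w)]
  f <- t(vapply(rows, function(x)
    as.numeric(strsplit(trimws(x), "\\s+")[[1L]]), numeric(4)))
  # invert the pseudocounted frequencies to recover integer counts
  counts <- t(round(f * (nsites + 4 * pseudocount) - pseudocount))
  counts[counts < 0] <- 0
  dimnames(counts) <- list(DNA_BASES, NULL)
  profile_from_counts(counts, nsites, background, pseudocount,
                      palindromic = FALSE)
}

#' Write a profile's count matrix as TSV (4 rows x L columns)
#' @param profile a `motif_profile`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_count_matrix <- function(profile, path) {
  m <- profile$counts
  colnames(m) <- seq_len(ncol(m))
  utils::write.table(data.frame(base = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count-matrix TSV written by [write_count_matrix()]
#' @param path TSV file.
#' @param background,pseudocount,palindromic profile parameters.
#' @return a `motif_profile`.
#' @export
read_count_matrix <- function(path, background = rep(0.25, 4),
                              pseudocount = 0.25, palindromic = FALSE) {
  d <- utils::read.delim(path, check.names = FALSE)
  counts <- as.matrix(d[, -1L, drop = FALSE])
  rownames(counts) <- d$base
  counts <- counts[DNA_BASES, , drop = FALSE]
  profile_from_counts(counts, max(colSums(counts)), background, pseudocount,
                      palindromic)
}
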