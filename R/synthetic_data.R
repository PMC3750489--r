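#' Sample a ground-truth PWM with a target information content
#'
#' Columns are drawn from a flat Dirichlet and then blended toward the
#' consensus base (or toward uniform) so each column's information content
#' matches `target_ic` (middle column of an odd-width palindrome is
#' self-complementary and capped just below 1 bit by construction).
#'
#' @param L motif width.
#' @param target_ic target per-column information content in bits,
#'   `0 < target_ic <= 2`.
#' @param seed integer seed.
#' @param palindrome enforce the reverse-complement mirror constraint.
#' @return object of class `truth_pwm`: list with `L`, `freqs` (4 x L),
#'   `consensus`, `palindromic`, `per_column_ic`, `target_ic`.
#' @export
sample_pwm <- function(L, target_ic = 1.2, seed = 1L, palindrome = FALSE) {
  if (target_ic <= 0 || target_ic > 2) {
    stop("target_ic must be in (0, 2]")
  }
  col_ic <- function(f) 2 + sum(ifelse(f > 0, f * log2(f), 0))
  solve_col <- function(f0, target) {
    b <- which.max(f0)
    if (col_ic(f0) < target) {
      towards <- function(w) (1 - w) * f0 + w * as.numeric(1:4 == b)
    } else {
      towards <- function(w) (1 - w) * f0 + w * rep(0.25, 4)
    }
    if (target >= 2 - 1e-9) return(as.numeric(1:4 == b) * 0.9999 + 2.5e-5)
    w <- stats::uniroot(function(w) col_ic(towards(w)) - target,
                        c(0, 1 - 1e-9), tol = 1e-10)$root
    towards(w)
  }
  freqs <- with_stream(seed, "sample-pwm", {
    n_free <- if (palindrome) L %/% 2L else L
    cols <- vapply(seq_len(n_free), function(i) {
      g <- stats::rgamma(4, 1)
      solve_col(g / sum(g), target_ic)
    }, numeric(4))
    if (palindrome) {
      f <- matrix(0, 4, L)
      f[, seq_len(n_free)] <- cols
      f[, L + 1L - seq_len(n_free)] <- cols[4:1, , drop = FALSE]
      if (L %% 2L == 1L) {
        # middle column must equal its own complement: f(A)=f(T), f(C)=f(G)
        mid_ic <- function(a) 2 + 2 * a * log2(a) +
          2 * (0.5 - a) * log2(0.5 - a)
        tgt <- min(target_ic, 0.98)
        a <- stats::uniroot(function(a) mid_ic(a) - tgt,
                            c(1e-6, 0.25 - 1e-6), tol = 1e-10)$root
        f[, (L + 1L) %/% 2L] <- c(a, 0.5 - a, 0.5 - a, a)
      }
      f
    } else cols
  })
  rownames(freqs) <- DNA_BASES
  structure(list(
    L = L, freqs = freqs,
    consensus = paste(DNA_BASES[apply(freqs, 2L, which.max)], collapse = ""),
    palindromic = palindrome,
    per_column_ic = apply(freqs, 2L, col_ic),
    target_ic = target_ic), class = "truth_pwm")
}

#' @export
print.truth_pwm <- function(x, ...) {
  cat("<truth_pwm> L=", x$L, ", mean IC ",
      round(mean(x$per_column_ic), 3), " bits/column, consensus ",
      x$consensus, "\n", sep = "")
  invisible(x)
}

# draw one site column-wise from a truth profile
sample_site <- function(truth) {
  paste(DNA_BASES[vapply(seq_len(truth$L), function(i)
    sample.int(4L, 1L, prob = truth$freqs[, i]), integer(1))],
    collapse = "")
}

sample_background <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

random_gene_body <- function(len, gc) {
  # start codon + random body + stop codon; content is irrelevant to the
  # pipeline but keeps the FASTA realistic
  paste0("ATG", sample_background(len - 6L, gc), "TAA")
}

#' Generate a synthetic multi-genome community with planted regulons
#'
#' Builds `n_genomes` single-contig genomes sharing `n_groups` ortholog
#' groups. Each regulon is a TF ortholog group plus target groups; in each
#' genome of its subset the regulon's genes are laid out as a contiguous
#' cluster (the TF adjacent to its regulated operons, emulating TFs encoded
#' within their regulated loci) and one site sampled from the regulon's
#' ground-truth PWM is planted in each regulated gene's upstream intergenic
#' segment at a uniform-random offset. Genomes outside the subset keep the
#' target genes (scattered, unregulated) but lack the TF ortholog. Genes
#' are spaced by `intergenic_len`, which exceeds the default operon-chaining
#' gap, so every gene forms its own operon and truth tables can name
#' operons directly.
#'
#' @param n_genomes,n_groups community dimensions (defaults 5 and 40).
#' @param n_regulons,operons_per_regulon,genomes_per_regulon regulon design:
#'   each regulon spans `operons_per_regulon` groups (the TF's own group
#'   first) and is planted in `genomes_per_regulon` genomes, always
#'   including the first genome (defaults 3, 6, 4).
#' @param motif_L,target_ic ground-truth motif width and per-column
#'   information content (defaults 17 nt, 1.2 bits).
#' @param palindrome sample palindromic truth motifs.
#' @param background_gc background GC content (default 0.46, approximately
#'   the T. maritima genomic GC).
#' @param intergenic_len intergenic segment length in nt (default 250; must
#'   be at least `motif_L + 10`).
#' @param gene_len coding length in nt (default 900).
#' @param seed master seed; every artifact draws from a named stream
#'   derived from it, so outputs are byte-identical given the seed.
#' @param out_dir when non-NULL, write per-genome FASTA + gene-table TSV,
#'   the ortholog table, and truth tables there.
#' @return object of class `synthetic_community`: list with `genomes`
#'   (named list of [genome_annotation()]), `orthologs`, and `truth` (list:
#'   `profiles`, `sites`, `membership`, `design`, `params`).
#' @export
generate_community <- function(n_genomes = 5L, n_groups = 40L,
                               n_regulons = 3L, operons_per_regulon = 6L,
                               genomes_per_regulon = 4L,
                               motif_L = 17L, target_ic = 1.2,
                               palindrome = FALSE,
                               background_gc = 0.46,
                               intergenic_len = 250L, gene_len = 900L,
                               seed = 1L, out_dir = NULL) {
  if (intergenic_len < motif_L + 10L) {
    stop("intergenic_len must be at least motif width + 10")
  }
  if (n_regulons * operons_per_regulon > n_groups) {
    stop("not enough ortholog groups for the regulon design")
  }
  genome_ids <- sprintf("g%02d", seq_len(n_genomes))
  group_ids <- sprintf("og%03d", seq_len(n_groups))

  design <- with_stream(seed, "design", {
    lapply(seq_len(n_regulons), function(r) {
      grp <- group_ids[((r - 1L) * operons_per_regulon + 1L):
                         (r * operons_per_regulon)]
      others <- sample(genome_ids[-1L],
                       min(genomes_per_regulon - 1L, n_genomes - 1L))
      list(regulon = paste0("R", r), tf_group = grp[1L],
           operon_groups = grp,
           genomes = c(genome_ids[1L], sort(others)))
    })
  })
  profiles <- stats::setNames(lapply(seq_len(n_regulons), function(r) {
    sample_pwm(motif_L, target_ic, seed = stream_seed(seed, paste0("pwm", r)),
               palindrome = palindrome)
  }), vapply(design, `[[`, character(1), "regulon"))

  tf_groups <- vapply(design, `[[`, character(1), "tf_group")
  regulated <- unlist(lapply(design, `[[`, "operon_groups"))
  group_regulon <- stats::setNames(rep(vapply(design, `[[`, character(1),
                                              "regulon"),
                                       lengths(lapply(design,
                                                      `[[`,
                                                      "operon_groups"))),
                                   regulated)

  genomes <- list()
  ortho_rows <- list()
  site_rows <- list()
  member_rows <- list()
  for (gid in genome_ids) {
    active <- Filter(function(d) gid %in% d$genomes, design)
    active_groups <- unlist(lapply(active, `[[`, "operon_groups"))
    absent_tfs <- setdiff(tf_groups,
                          vapply(active, `[[`, character(1), "tf_group"))
    scattered <- setdiff(group_ids, c(active_groups, absent_tfs))
    layout <- with_stream(seed, paste0("genome-", gid), {
      ord <- sample(scattered)
      for (d in active) {
        blk <- sample(d$operon_groups)
        at <- sample.int(length(ord) + 1L, 1L)
        ord <- append(ord, blk, after = at - 1L)
      }
      strands <- sample(c("+", "-"), length(ord), replace = TRUE)
      bodies <- vapply(seq_along(ord), function(i)
        random_gene_body(gene_len, background_gc), character(1))
      gaps <- vapply(seq_len(length(ord) + 1L), function(i)
        sample_background(intergenic_len, background_gc), character(1))
      list(ord = ord, strands = strands, bodies = bodies, gaps = gaps)
    })
    ord <- layout$ord
    n <- length(ord)
    starts <- intergenic_len + 1L +
      (seq_len(n) - 1L) * (gene_len + intergenic_len)
    ends <- starts + gene_len - 1L
    gaps <- layout$gaps

    # plant sites in the upstream intergenic segment of regulated genes
    planted <- with_stream(seed, paste0("sites-", gid), {
      out <- list()
      d_max <- intergenic_len %/% 2L - motif_L - 2L
      d_min <- 5L
      if (d_max < d_min) stop("intergenic_len too short to place sites")
      for (d in active) {
        truth <- profiles[[d$regulon]]
        for (grp in d$operon_groups) {
          i <- match(grp, ord)
          site <- sample_site(truth)
          dd <- sample(d_min:d_max, 1L)
          out[[length(out) + 1L]] <- list(regulon = d$regulon, group = grp,
                                          i = i, d = dd, seq = site)
        }
      }
      out
    })
    for (p in planted) {
      i <- p$i
      gap_len <- intergenic_len
      if (layout$strands[i] == "+") {
        # site sits in gap i (before gene i), d nt before the gene start
        pos <- gap_len - p$d - motif_L + 1L
        substr(gaps[i], pos, pos + motif_L - 1L) <- p$seq
      } else {
        # upstream of a minus-strand gene is gap i+1; region is read
        # right-to-left so the planted sequence is reverse-complemented
        pos <- p$d + 1L
        substr(gaps[i + 1L], pos, pos + motif_L - 1L) <- revcomp(p$seq)
      }
    }

    contig <- paste0(paste0(gaps[seq_len(n)], layout$bodies,
                            collapse = ""), gaps[n + 1L])
    contig_id <- paste0(gid, "_c1")
    gene_ids <- paste0(gid, "_", ord)
    genes <- data.frame(
      gene_id = gene_ids, contig = contig_id,
      start = starts, end = ends, strand = layout$strands,
      name = ord,
      role = ifelse(ord %in% tf_groups, "TF", "enzyme"),
      pathway = ifelse(ord %in% names(group_regulon),
                       group_regulon[ord], ""),
      stringsAsFactors = FALSE
    )
    genomes[[gid]] <- genome_annotation(gid,
                                        stats::setNames(contig, contig_id),
                                        genes)
    ortho_rows[[gid]] <- data.frame(group_id = ord, genome_id = gid,
                                    gene_id = gene_ids,
                                    stringsAsFactors = FALSE)
    for (p in planted) {
      i <- p$i
      s <- starts[i]; e <- ends[i]
      if (layout$strands[i] == "+") {
        site_start <- s - p$d - motif_L
        site_end <- s - p$d - 1L
      } else {
        site_start <- e + p$d + 1L
        site_end <- e + p$d + motif_L
      }
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        regulon = p$regulon, genome_id = gid,
        group_id = p$group, gene_id = paste0(gid, "_", p$group),
        operon_id = paste0("opn:", gid, ":", gid, "_", p$group),
        contig = contig_id, site_start = site_start, site_end = site_end,
        strand = layout$strands[i],
        offset = intergenic_len - p$d - motif_L + 1L,
        sequence = p$seq, stringsAsFactors = FALSE)
    }
    for (d in active) {
      member_rows[[length(member_rows) + 1L]] <- data.frame(
        regulon = d$regulon, tf_group = d$tf_group, genome_id = gid,
        group_id = d$operon_groups,
        gene_id = paste0(gid, "_", d$operon_groups),
        stringsAsFactors = FALSE)
    }
  }

  orthologs <- do.call(rbind, ortho_rows)
  rownames(orthologs) <- NULL
  truth <- list(profiles = profiles,
                sites = do.call(rbind, site_rows),
                membership = do.call(rbind, member_rows),
                design = design,
                params = list(n_genomes = n_genomes, n_groups = n_groups,
                              motif_L = motif_L, target_ic = target_ic,
                              background_gc = background_gc,
                              intergenic_len = intergenic_len,
                              gene_len = gene_len, seed = seed))
  community <- structure(list(genomes = genomes, orthologs = orthologs,
                              truth = truth),
                         class = "synthetic_community")
  if (!is.null(out_dir)) write_community(community, out_dir)
  community
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat("<synthetic_community> ", length(x$genomes), " genomes, ",
      length(unique(x$orthologs$group_id)), " ortholog groups, ",
      length(x$truth$design), " planted regulons, ",
      nrow(x$truth$sites), " planted sites (seed ",
      x$truth$params$seed, ")\n", sep = "")
  invisible(x)
}

#' Write a synthetic community to disk
#'
#' Per-genome FASTA + TSV gene tables (readable by [load_genome()]), the
#' ortholog table, and the truth tables.
#'
#' @param community a `synthetic_community`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, `out_dir`.
#' @export
write_community <- function(community, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (gid in names(community$genomes)) {
    write_genome(community$genomes[[gid]],
                 file.path(out_dir, paste0(gid, "_genes.tsv")),
                 file.path(out_dir, paste0(gid, ".fna")))
  }
  utils::write.table(community$orthologs,
                     file.path(out_dir, "orthologs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(community$truth$sites,
                     file.path(out_dir, "truth_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(community$truth$membership,
                     file.path(out_dir, "truth_membership.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Simulate a condition-specific expression matrix for a community
#'
#' Emulates a sugar-panel design: every gene of one genome gets a baseline
#' log2 level; each regulon's genes are shifted on that regulon's cognate
#' condition by a gene-specific true effect drawn from
#' `Normal(mu_log2fc, sigma)`; independent replicate noise is added to
#' every measurement. The reference condition carries no shifts.
#'
#' @param community a `synthetic_community`.
#' @param genome genome whose genes are profiled (default: the first).
#' @param reference reference condition label (default `"ribose"`).
#' @param mu_log2fc,sigma mean and sd of the true per-gene log2 fold change
#'   (defaults 4 and 0.3).
#' @param baseline_mu,baseline_sigma baseline log2 level distribution
#'   (defaults 8 and 1).
#' @param replicate_sd replicate measurement noise sd (default 0.15).
#' @param n_replicates replicates per condition (default 2).
#' @param missing_genes genes removed from the platform (emulating absent
#'   probes); surfaced downstream as missing, never imputed.
#' @param seed integer seed.
#' @return list with `matrix` (an [expression_matrix()]), `conditions`
#'   (named map regulon -> condition label), and `truth_induced`
#'   (data.frame `gene`, `condition`, `true_log2fc`).
#' @export
generate_expression <- function(community, genome = NULL,
                                reference = "ribose", mu_log2fc = 4,
                                sigma = 0.3, baseline_mu = 8,
                                baseline_sigma = 1, replicate_sd = 0.15,
                                n_replicates = 2L,
                                missing_genes = character(), seed = 1L) {
  genome <- genome %||% names(community$genomes)[1L]
  genes <- community$genomes[[genome]]$genes$gene_id
  regulons <- vapply(community$truth$design, `[[`, character(1), "regulon")
  conditions <- stats::setNames(paste0("sugar_", seq_along(regulons)),
                                regulons)
  cond_labels <- c(unname(conditions), reference)
  mem <- community$truth$membership
  mem <- mem[mem$genome_id == genome, , drop = FALSE]

  out <- with_stream(seed, "expression", {
    baseline <- stats::rnorm(length(genes), baseline_mu, baseline_sigma)
    names(baseline) <- genes
    shift <- matrix(0, length(genes), length(cond_labels),
                    dimnames = list(genes, cond_labels))
    truth_rows <- list()
    for (r in regulons) {
      rg <- mem$gene_id[mem$regulon == r]
      rg <- intersect(rg, genes)
      if (!length(rg)) next
      eff <- stats::rnorm(length(rg), mu_log2fc, sigma)
      shift[rg, conditions[[r]]] <- eff
      truth_rows[[r]] <- data.frame(gene = rg,
                                    condition = conditions[[r]],
                                    true_log2fc = eff,
                                    stringsAsFactors = FALSE)
    }
    cols <- list()
    for (cond in cond_labels) {
      for (rep_i in seq_len(n_replicates)) {
        cols[[paste0(cond, "_rep", rep_i)]] <-
          baseline + shift[, cond] +
          stats::rnorm(length(genes), 0, replicate_sd)
      }
    }
    values <- do.call(cbind, cols)
    rownames(values) <- genes
    list(values = values, truth = do.call(rbind, truth_rows))
  })
  values <- out$values[!rownames(out$values) %in% missing_genes, ,
                       drop = FALSE]
  list(matrix = expression_matrix(values),
       conditions = conditions,
       truth_induced = out$truth)
}

#' Run the full reconstruction on a synthetic community and score it
#'
#' For every planted regulon: reconstruct from the community's genomes and
#' ortholog table with [reconstruct_regulon()], pool the predicted members
#' and sites across regulons, and compare against the planted truth with
#' [recovery_metrics()].
#'
#' @param community a `synthetic_community`.
#' @param n_restarts,seed,L,max_iter,k_min pipeline parameters (motif width
#'   defaults to the community's planted width).
#' @return list with `metrics` (site- and gene-level precision/recall),
#'   `models` (per-regulon `regulon_model`s), `predicted_members`,
#'   `predicted_sites`.
#' @export
evaluate_community_recovery <- function(community, n_restarts = 10L,
                                        seed = 1L, L = NULL,
                                        max_iter = 3L, k_min = 2L) {
  L <- L %||% community$truth$params$motif_L
  operons <- lapply(community$genomes, predict_operons)
  members <- list()
  sites <- list()
  models <- list()
  for (d in community$truth$design) {
    model <- reconstruct_regulon(community$genomes, community$orthologs,
                                 d$tf_group, L = L,
                                 n_restarts = n_restarts,
                                 seed = stream_seed(seed, d$regulon),
                                 k_min = k_min, max_iter = max_iter,
                                 operons = operons)
    m <- model$members
    m$regulon <- rep(d$regulon, nrow(m))
    members[[d$regulon]] <- m
    sites[[d$regulon]] <- unique(m[, c("regulon", "genome_id", "operon_id",
                                       "offset", "position", "strand")])
    models[[d$regulon]] <- model
  }
  predicted_members <- do.call(rbind, members)
  predicted_sites <- do.call(rbind, sites)
  metrics <- recovery_metrics(predicted_sites = predicted_sites,
                              predicted_members = predicted_members,
                              truth = community$truth)
  list(metrics = metrics, models = models,
       predicted_members = predicted_members,
       predicted_sites = predicted_sites)
}

#' Precision and recall of predictions against planted truth
#'
#' Site-level: a predicted site matches a planted one within +/-1 nt,
#' either strand. When both tables carry genomic coordinates (`position`
#' in the predictions, `site_start` in the truth) matching is by genomic
#' position within the genome, which treats a site in a shared divergent
#' intergenic region as recovered regardless of which operon's region
#' reported it; otherwise matching falls back to (genome, operon) identity
#' plus region offset. Gene-level: set overlap of (regulon, genome, gene)
#' membership (the `regulon` key is used only when present in both
#' tables). Empty predictions give recall 0 and precision NA.
#'
#' @param predicted_sites data.frame with `genome_id`, `operon_id`,
#'   `offset` (and optionally `regulon`), or NULL to skip the site level.
#' @param predicted_members data.frame with `genome_id`, `gene_id` (and
#'   optionally `regulon`), or NULL to skip the gene level.
#' @param truth the `truth` element of a `synthetic_community`.
#' @param offset_tolerance site offset tolerance in nt (default 1).
#' @return data.frame: `level`, `n_predicted`, `n_truth`, `tp`,
#'   `precision`, `recall`.
#' @export
recovery_metrics <- function(predicted_sites = NULL,
                             predicted_members = NULL, truth,
                             offset_tolerance = 1L) {
  rows <- list()
  if (!is.null(predicted_sites)) {
    ts <- truth$sites
    use_reg <- "regulon" %in% names(predicted_sites)
    by_position <- "position" %in% names(predicted_sites) &&
      "site_start" %in% names(ts)
    if (by_position) {
      pkey <- paste(if (use_reg) predicted_sites$regulon else "",
                    predicted_sites$genome_id)
      tkey <- paste(if (use_reg) ts$regulon else "", ts$genome_id)
      tpos <- ts$site_start
      ppos <- predicted_sites$position
    } else {
      pkey <- paste(if (use_reg) predicted_sites$regulon else "",
                    predicted_sites$genome_id, predicted_sites$operon_id)
      tkey <- paste(if (use_reg) ts$regulon else "", ts$genome_id,
                    ts$operon_id)
      tpos <- ts$offset
      ppos <- predicted_sites$offset
    }
    match_one <- function(i) {
      j <- which(tkey == pkey[i] &
                   abs(tpos - ppos[i]) <= offset_tolerance)
      if (length(j)) j[1L] else NA_integer_
    }
    hit <- vapply(seq_len(nrow(predicted_sites)), match_one, integer(1))
    tp <- sum(!is.na(hit))
    rows$site <- data.frame(
      level = "site", n_predicted = nrow(predicted_sites),
      n_truth = nrow(ts), tp = tp,
      precision = if (nrow(predicted_sites)) tp / nrow(predicted_sites)
      else NA_real_,
      recall = length(unique(hit[!is.na(hit)])) / nrow(ts),
      stringsAsFactors = FALSE)
  }
  if (!is.null(predicted_members)) {
    tm <- truth$membership
    use_reg <- "regulon" %in% names(predicted_members)
    pk <- unique(paste(if (use_reg) predicted_members$regulon else "",
                       predicted_members$genome_id,
                       predicted_members$gene_id))
    tk <- unique(paste(if (use_reg) tm$regulon else "", tm$genome_id,
                       tm$gene_id))
    tp <- length(intersect(pk, tk))
    rows$gene <- data.frame(
      level = "gene", n_predicted = length(pk), n_truth = length(tk),
      tp = tp,
      precision = if (length(pk)) tp / length(pk) else NA_real_,
      recall = tp / length(tk), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
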