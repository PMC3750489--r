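#' Propagate a motif across genomes and group hits by target ortholog group
#'
#' Scans every operon upstream region in every genome with the profile, keeps
#' the best (max-score) passing site per operon, and maps operons to the
#' ortholog groups of their member genes. Support of a candidate interaction
#' is the number of genomes that both carry the TF ortholog and show a
#' passing hit for the target group; genomes lacking the TF contribute hits
#' but never support.
#'
#' @param profile a `motif_profile` with threshold set.
#' @param genomes named list of [genome_annotation()] objects.
#' @param orthologs data.frame `group_id`, `genome_id`, `gene_id`.
#' @param tf_group ortholog-group id of the scanned TF.
#' @param operons optional named list of `operon_table`s per genome.
#' @param window,truncate_at_neighbor,min_len region extraction parameters.
#' @param threshold,slack see [scan_region()].
#' @return object of class `candidate_set`: list with `tf_group`,
#'   `tf_genomes` (genomes carrying the TF), `hits` (best passing hit per
#'   operon with member genes/groups), `support` (data.frame `group_id`,
#'   `support`, `n_hit_genomes`).
#' @export
propagate <- function(profile, genomes, orthologs, tf_group,
                      operons = NULL, window = c(300L, 20L),
                      truncate_at_neighbor = TRUE, min_len = 30L,
                      threshold = profile$threshold, slack = 0) {
  tf_genomes <- unique(orthologs$genome_id[orthologs$group_id == tf_group])
  tf_genomes <- intersect(tf_genomes, names(genomes))
  gene_group <- stats::setNames(orthologs$group_id, orthologs$gene_id)
  rows <- list()
  for (gid in names(genomes)) {
    genome <- genomes[[gid]]
    ops <- operons[[gid]] %||% predict_operons(genome)
    if (nrow(ops) == 0L) next
    hits <- scan_genome(profile, genome, ops, window = window,
                        truncate_at_neighbor = truncate_at_neighbor,
                        min_len = min_len, threshold = threshold,
                        slack = slack)
    if (nrow(hits) == 0L) next
    # one best site per operon
    hits <- hits[order(hits$operon_id, -hits$score, hits$offset), ]
    hits <- hits[!duplicated(hits$operon_id), , drop = FALSE]
    for (k in seq_len(nrow(hits))) {
      op_genes <- ops$gene_ids[[match(hits$operon_id[k], ops$operon_id)]]
      grp <- unname(gene_group[op_genes])
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = gid, operon_id = hits$operon_id[k],
        gene_id = op_genes, group_id = ifelse(is.na(grp), "", grp),
        offset = hits$offset[k], position = hits$position[k],
        strand = hits$strand[k], sequence = hits$sequence[k],
        score = hits$score[k],
        tf_present = gid %in% tf_genomes,
        stringsAsFactors = FALSE
      )
    }
  }
  hits <- do.call(rbind, rows)
  if (is.null(hits)) {
    hits <- data.frame(genome_id = character(), operon_id = character(),
                       gene_id = character(), group_id = character(),
                       offset = integer(), position = integer(),
                       strand = character(), sequence = character(),
                       score = numeric(), tf_present = logical(),
                       stringsAsFactors = FALSE)
  }
  grp_rows <- hits[hits$group_id != "", , drop = FALSE]
  support <- if (nrow(grp_rows)) {
    # support counts distinct genomes with the TF present and a passing hit
    sup <- tapply(grp_rows$genome_id[grp_rows$tf_present],
                  grp_rows$group_id[grp_rows$tf_present],
                  function(g) length(unique(g)))
    nh <- tapply(grp_rows$genome_id, grp_rows$group_id,
                 function(g) length(unique(g)))
    data.frame(group_id = names(nh),
               support = as.integer(ifelse(is.na(sup[names(nh)]), 0L,
                                           sup[names(nh)])),
               n_hit_genomes = as.integer(nh),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(group_id = character(), support = integer(),
               n_hit_genomes = integer(), stringsAsFactors = FALSE)
  }
  structure(list(tf_group = tf_group, tf_genomes = tf_genomes,
                 hits = hits, support = support),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("<candidate_set> TF", x$tf_group, "-", nrow(x$support),
      "target groups across", length(unique(x$hits$genome_id)),
      "genomes\n")
  invisible(x)
}

#' Default conservation cutoff
#'
#' 2 when at most 4 genomes carry the TF, else 3.
#' @param n_tf_genomes number of genomes carrying the TF ortholog.
#' @return integer k_min.
#' @export
default_k_min <- function(n_tf_genomes) if (n_tf_genomes <= 4L) 2L else 3L

#' Cross-genome consistency filter
#'
#' Keeps candidate interactions supported by passing sites in at least
#' `k_min` genomes that carry the TF ortholog. Genomes where the TF is
#' absent never block acceptance elsewhere. Acceptance is monotone: raising
#' `k_min` can only shrink the accepted set.
#'
#' @param candidates a `candidate_set` from [propagate()].
#' @param k_min minimum supporting genomes (default by [default_k_min()]).
#' @return the filtered `candidate_set` (accepted groups and their hits).
#' @export
consistency_filter <- function(candidates, k_min = NULL) {
  if (is.null(k_min)) k_min <- default_k_min(length(candidates$tf_genomes))
  if (k_min < 1L) stop("k_min must be >= 1")
  acc <- candidates$support$group_id[candidates$support$support >= k_min]
  hits <- candidates$hits[candidates$hits$group_id %in% acc, , drop = FALSE]
  structure(list(tf_group = candidates$tf_group,
                 tf_genomes = candidates$tf_genomes,
                 hits = hits,
                 support = candidates$support[
                   candidates$support$group_id %in% acc, , drop = FALSE],
                 k_min = k_min),
            class = "candidate_set")
}

# regulon membership from an accepted candidate set: genes of accepted
# groups in genomes where their operon carries a passing site
regulon_membership <- function(accepted) {
  m <- accepted$hits[accepted$hits$tf_present, , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Iteratively refine a profile by re-scanning and rebuilding
#'
#' The reconstruction loop: scan all genomes, apply the consistency filter,
#' add the accepted sites to the training set, rebuild the profile and reset
#' its threshold to the new training minimum, and repeat until the accepted
#' site set is unchanged or `max_iter` is reached. The original training
#' sites are never dropped, so the threshold is non-increasing and the
#' accepted set can only grow or stabilise in typical use; oscillation past
#' `max_iter` returns the last model with `converged = FALSE` and a warning.
#'
#' @param profile initial `motif_profile` with threshold set.
#' @param genomes,orthologs,tf_group,operons,window,truncate_at_neighbor,min_len
#'   as in [propagate()].
#' @param k_min conservation cutoff (default by [default_k_min()]).
#' @param max_iter maximum refinement iterations (default 10).
#' @return object of class `regulon_model`: list with `tf_group`, `profile`,
#'   `members` (per-genome operon/gene/site table), `support`,
#'   `iteration_count`, `converged`, `objective_trace` (total training-set
#'   score after each iteration), `effector` (metadata slot, NA unless set).
#' @export
iterate_refinement <- function(profile, genomes, orthologs, tf_group,
                               k_min = NULL, max_iter = 10L, operons = NULL,
                               window = c(300L, 20L),
                               truncate_at_neighbor = TRUE, min_len = 30L) {
  if (is.na(profile$threshold)) {
    stop("initial profile must have its threshold set")
  }
  original_sites <- profile$training_sites
  prev_key <- NULL
  accepted <- NULL
  trace <- numeric(0)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    cand <- propagate(profile, genomes, orthologs, tf_group,
                      operons = operons, window = window,
                      truncate_at_neighbor = truncate_at_neighbor,
                      min_len = min_len)
    accepted <- consistency_filter(cand, k_min)
    members <- regulon_membership(accepted)
    site_tab <- unique(members[, c("genome_id", "operon_id", "offset",
                                   "strand", "sequence")])
    key <- paste(site_tab$genome_id, site_tab$operon_id, site_tab$offset,
                 site_tab$strand, sep = "/")
    key <- sort(key)
    training <- union(original_sites, site_tab$sequence)
    training_unchanged <- setequal(training, profile$training_sites)
    profile <- build_pwm(training, background = profile$background,
                         pseudocount = profile$pseudocount,
                         palindromic = profile$palindromic)
    profile <- set_threshold(profile, training)
    trace <- c(trace, sum(vapply(training,
                                 function(s) score_site(profile, s),
                                 numeric(1))))
    # fixed point: the accepted site set repeats, or the training set (and
    # hence profile and threshold) is unchanged so the next scan must repeat
    if ((!is.null(prev_key) && identical(key, prev_key)) ||
        training_unchanged) {
      converged <- TRUE
      break
    }
    prev_key <- key
  }
  if (!converged && iter >= max_iter) {
    warning("refinement did not reach a fixed point within ", max_iter,
            " iterations; returning last model")
  }
  structure(list(tf_group = tf_group, profile = profile,
                 members = regulon_membership(accepted),
                 support = accepted$support,
                 iteration_count = iter, converged = converged,
                 objective_trace = trace, effector = NA_character_),
            class = "regulon_model")
}

#' @export
print.regulon_model <- function(x, ...) {
  cat("<regulon_model> TF", x$tf_group, "-",
      length(unique(x$members$gene_id)), "genes in",
      length(unique(x$members$operon_id)), "operons;",
      x$iteration_count, "iteration(s),",
      if (x$converged) "converged" else "not converged", "\n")
  invisible(x)
}

#' Attach effector metadata to a regulon model
#'
#' Effector assignments (e.g. TreR - trehalose) are carried as annotation
#' from configuration, never inferred.
#' @param model a `regulon_model`.
#' @param effector single string.
#' @return the model with `effector` set.
#' @export
set_effector <- function(model, effector) {
  model$effector <- effector
  model
}

#' Write regulon models as a flat TSV
#'
#' One row per (TF, genome, operon, gene) with the supporting site and its
#' score (4 decimals) and cross-genome support.
#'
#' @param models a `regulon_model` or list of them.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_regulon_tsv <- function(models, path) {
  if (inherits(models, "regulon_model")) models <- list(models)
  rows <- lapply(models, function(m) {
    if (nrow(m$members) == 0L) return(NULL)
    sup <- stats::setNames(m$support$support, m$support$group_id)
    data.frame(tf_group = m$tf_group,
               genome = m$members$genome_id,
               operon = m$members$operon_id,
               gene = m$members$gene_id,
               site_sequence = m$members$sequence,
               score = sprintf("%.4f", m$members$score),
               support = as.integer(sup[m$members$group_id]),
               effector = m$effector,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a per-TF summary table as TSV
#'
#' @param summary result of [summarize_regulons()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_summary_tsv <- function(summary, path) {
  utils::write.table(summary$per_tf, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Reconstruct one regulon from genomes and an ortholog table
#'
#' The full single-TF pipeline: assemble the training set from the TF's
#' gene neighbourhood, discover the shared motif (zero-or-one occurrence
#' per region by default, since not every neighbourhood operon is
#' regulated), set the threshold to the minimum training-site score, then
#' iteratively rescan/filter/rebuild to a fixed point.
#'
#' @param genomes named list of [genome_annotation()] objects.
#' @param orthologs ortholog table (`group_id`, `genome_id`, `gene_id`).
#' @param tf_group TF ortholog group id.
#' @param L motif width (default 17 nt).
#' @param symmetry,n_restarts,zoops,gamma,background,pseudocount passed to
#'   [discover_profile()].
#' @param seed seed for the discovery sampler.
#' @param radius_genes training-set neighbourhood radius.
#' @param k_min,max_iter refinement parameters, see [iterate_refinement()].
#' @param window,operons region extraction / operon inputs.
#' @return a `regulon_model` (with the discovery result attached as
#'   `$discovery`).
#' @export
reconstruct_regulon <- function(genomes, orthologs, tf_group, L = 17L,
                                symmetry = "none", n_restarts = 20L,
                                seed = 1L, zoops = TRUE, gamma = 0.5,
                                radius_genes = 5L, k_min = NULL,
                                max_iter = 10L, window = c(300L, 20L),
                                operons = NULL,
                                background = rep(0.25, 4),
                                pseudocount = 0.25) {
  training <- neighborhood_training_set(tf_group, genomes, orthologs,
                                        radius_genes = radius_genes,
                                        operons = operons, window = window)
  disc <- discover_profile(training, L = L, symmetry = symmetry,
                           n_restarts = n_restarts, seed = seed,
                           zoops = zoops, gamma = gamma,
                           background = background,
                           pseudocount = pseudocount)
  profile <- set_threshold(disc$profile, disc$sites$sequence)
  model <- iterate_refinement(profile, genomes, orthologs, tf_group,
                              k_min = k_min, max_iter = max_iter,
                              operons = operons, window = window)
  model$discovery <- disc
  model
}

#' Summarize regulon membership tables
#'
#' Works on any membership table with columns `tf`, `genome_id`,
#' `operon_id`, `gene_id`, optional `role` and site identity columns. Genes
#' are deduplicated by gene_id within a regulon and in the global total.
#'
#' @param membership data.frame as above (bind several regulons' members,
#'   adding a `tf` column, or use a fixture catalog's membership table).
#' @param sites optional data.frame of site records with a `tf` column; one
#'   row per (TF, site). When NULL, sites are counted as distinct
#'   (operon, offset) pairs in `membership` if present.
#' @return list with `per_tf` (data.frame `tf`, `n_operons`, `n_genes`,
#'   `n_sites`, role breakdown columns) and `totals` (named numeric:
#'   `n_tfs`, `n_operons`, `n_sites`, `n_genes`, `n_target_genes`).
#' @export
summarize_regulons <- function(membership, sites = NULL) {
  if (nrow(membership) == 0L) {
    per_tf <- data.frame(tf = character(), n_operons = integer(),
                         n_genes = integer(), n_sites = integer(),
                         n_enzymes = integer(), n_transporters = integer(),
                         n_tfs = integer(), stringsAsFactors = FALSE)
    totals <- c(n_tfs = 0, n_operons = 0, n_sites = 0, n_genes = 0,
                n_target_genes = 0)
    return(list(per_tf = per_tf, totals = totals))
  }
  if (is.null(membership$role)) membership$role <- ""
  site_count <- function(tf) {
    if (!is.null(sites)) return(sum(sites$tf == tf))
    m <- membership[membership$tf == tf, , drop = FALSE]
    if (!is.null(m$offset)) {
      nrow(unique(m[, c("genome_id", "operon_id", "offset")]))
    } else {
      length(unique(m$operon_id))
    }
  }
  tfs <- unique(membership$tf)
  per_tf <- do.call(rbind, lapply(tfs, function(tf) {
    m <- membership[membership$tf == tf, , drop = FALSE]
    m <- m[!duplicated(m$gene_id), , drop = FALSE]
    data.frame(tf = tf,
               n_operons = length(unique(
                 membership$operon_id[membership$tf == tf])),
               n_genes = nrow(m),
               n_sites = site_count(tf),
               n_enzymes = sum(m$role == "enzyme"),
               n_transporters = sum(m$role == "transporter"),
               n_tfs = sum(m$role == "TF"),
               stringsAsFactors = FALSE)
  }))
  uniq <- membership[!duplicated(membership$gene_id), , drop = FALSE]
  totals <- c(n_tfs = length(tfs),
              n_operons = length(unique(membership$operon_id)),
              n_sites = sum(per_tf$n_sites),
              n_genes = nrow(uniq),
              n_target_genes = nrow(uniq) - sum(uniq$role == "TF"))
  list(per_tf = per_tf, totals = totals)
}
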