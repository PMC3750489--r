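#' Expression matrix container
#'
#' A genes x samples matrix of normalized log2 expression values with a
#' condition label per sample column and explicit replicate structure.
#' Genes absent from the platform (e.g. probes missing for part of a
#' regulon) are represented by rows of NA or simply absent, and are
#' surfaced as `missing` downstream rather than silently dropped.
#'
#' @param values numeric matrix, rownames = gene ids.
#' @param conditions character vector, one condition label per column
#'   (replicate columns share a label). Defaults to the part of each column
#'   name before the last underscore, so `"glucose_rep1"` maps to
#'   `"glucose"`.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, conditions = NULL) {
  values <- as.matrix(values)
  if (is.null(conditions)) {
    if (is.null(colnames(values))) stop("conditions or column names needed")
    conditions <- sub("_[^_]*$", "", colnames(values))
  }
  if (length(conditions) != ncol(values)) {
    stop("one condition label per column required")
  }
  if (any(!is.finite(values) & !is.na(values))) {
    stop("expression values must be finite (or NA for missing probes)")
  }
  structure(list(values = values, conditions = conditions),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (", length(unique(x$conditions)), " conditions)\n", sep = "")
  invisible(x)
}

#' Read an expression matrix TSV (gene rows, condition_replicate columns)
#' @param path TSV with a `gene` column and one column per sample.
#' @return an [expression_matrix()].
#' @export
read_expression_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  expression_matrix(m)
}

#' Fold change of a condition against a reference
#'
#' Replicates are combined on the log2 scale (mean by default, median
#' optionally); `log2FC = combine(condition) - combine(reference)` and
#' `FC = 2^log2FC`. Genes with no measurement in either condition get a
#' missing-value record, never silently dropped.
#'
#' @param mat an [expression_matrix()].
#' @param condition,reference condition labels present in `mat`.
#' @param genes optional gene set to report (default: all matrix rows);
#'   genes not in the matrix at all are reported with `missing = TRUE`.
#' @param combine `"mean"` (default) or `"median"`.
#' @return data.frame of class `fold_change_table`: `gene`, `log2fc`, `fc`,
#'   `missing`.
#' @export
fold_change <- function(mat, condition, reference, genes = NULL,
                        combine = c("mean", "median")) {
  combine <- match.arg(combine)
  fun <- if (combine == "mean") rowMeans else
    function(m, na.rm) apply(m, 1L, stats::median, na.rm = na.rm)
  for (cond in c(condition, reference)) {
    if (!cond %in% mat$conditions) stop("unknown condition: ", cond)
  }
  if (is.null(genes)) genes <- rownames(mat$values)
  present <- intersect(genes, rownames(mat$values))
  v <- mat$values[present, , drop = FALSE]
  a <- fun(v[, mat$conditions == condition, drop = FALSE], na.rm = TRUE)
  b <- fun(v[, mat$conditions == reference, drop = FALSE], na.rm = TRUE)
  lfc <- a - b
  out <- data.frame(gene = genes,
                    log2fc = lfc[match(genes, present)],
                    stringsAsFactors = FALSE)
  out$fc <- 2^out$log2fc
  out$missing <- is.na(out$log2fc)
  class(out) <- c("fold_change_table", "data.frame")
  out
}

#' Classify genes as induced by the >k-fold rule
#'
#' A gene is induced iff its linear fold change strictly exceeds
#' `threshold_fold` (so FC = 2 exactly is *not* induced under the default
#' >2-fold rule). Missing genes are classified `"missing"`.
#'
#' @param fc_table a `fold_change_table` from [fold_change()].
#' @param threshold_fold linear-scale cutoff, default 2.
#' @return the table with a `status` column, factor with levels
#'   `induced`, `not_induced`, `missing`.
#' @export
classify_induction <- function(fc_table, threshold_fold = 2) {
  status <- ifelse(fc_table$missing, "missing",
                   ifelse(fc_table$fc > threshold_fold,
                          "induced", "not_induced"))
  fc_table$status <- factor(status,
                            levels = c("induced", "not_induced", "missing"))
  fc_table
}

#' Hypergeometric enrichment of a regulon in the induced gene set
#'
#' Upper-tail hypergeometric probability of drawing at least the observed
#' overlap when `length(induced)` genes are drawn from the universe.
#'
#' @param regulon_genes,induced,universe character vectors of gene ids;
#'   `regulon_genes` and `induced` must be subsets of `universe`.
#' @return list with `overlap`, `n_regulon`, `n_induced`, `n_universe`,
#'   `p_value`.
#' @export
regulon_enrichment <- function(regulon_genes, induced, universe) {
  if (length(universe) == 0L) stop("empty universe")
  regulon_genes <- unique(regulon_genes)
  induced <- unique(induced)
  if (!all(regulon_genes %in% universe)) {
    stop("regulon genes outside the universe")
  }
  if (!all(induced %in% universe)) stop("induced genes outside the universe")
  k <- length(intersect(regulon_genes, induced))
  p <- stats::phyper(k - 1L, length(regulon_genes),
                     length(universe) - length(regulon_genes),
                     length(induced), lower.tail = FALSE)
  list(overlap = k, n_regulon = length(regulon_genes),
       n_induced = length(induced), n_universe = length(universe),
       p_value = p)
}

#' Enrichment report across regulons with BH correction
#'
#' Tests each regulon against one induced set and adjusts p-values by
#' Benjamini-Hochberg across the regulons tested in the run. Regulon genes
#' without a measurement are counted as missing, reported per regulon.
#'
#' @param regulons named list of gene-id vectors.
#' @param fc_table classified fold-change table ([classify_induction()])
#'   over the measured universe.
#' @param universe gene universe; defaults to all genes in `fc_table`.
#' @return data.frame: `tf`, `n_genes`, `n_measured`, `n_induced`,
#'   `median_fc`, `p_value`, `q_value`.
#' @export
enrich_regulons <- function(regulons, fc_table, universe = fc_table$gene) {
  measured <- fc_table$gene[!fc_table$missing]
  induced <- fc_table$gene[!fc_table$missing &
                             fc_table$status == "induced"]
  rows <- lapply(names(regulons), function(tf) {
    genes <- unique(regulons[[tf]])
    meas <- intersect(genes, measured)
    enr <- regulon_enrichment(intersect(meas, universe),
                              intersect(induced, universe),
                              universe)
    fcs <- fc_table$fc[match(meas, fc_table$gene)]
    data.frame(tf = tf, n_genes = length(genes), n_measured = length(meas),
               n_induced = enr$overlap,
               median_fc = if (length(fcs)) stats::median(fcs) else NA_real_,
               p_value = enr$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}
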