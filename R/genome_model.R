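#' Genome annotation container
#'
#' Bundles contig sequences with a gene table for one genome. Coordinates are
#' 1-based inclusive throughout (GFF3 convention), `strand` is `"+"` or `"-"`.
#'
#' @param genome_id single string identifying the genome.
#' @param contigs named character vector or `DNAStringSet` of contig sequences.
#' @param genes data.frame with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand`, and optionally `name`, `role`, `pathway`.
#' @return object of class `genome_annotation`: a list with elements
#'   `genome_id`, `contigs` (named character) and `genes` (data.frame with a
#'   `genome_id` column added).
#' @export
genome_annotation <- function(genome_id, contigs, genes) {
  if (methods::is(contigs, "DNAStringSet")) contigs <- as.character(contigs)
  contigs <- toupper(contigs)
  if (is.null(names(contigs)) || anyNA(names(contigs))) {
    stop("contigs must be named")
  }
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  required <- c("gene_id", "contig", "start", "end", "strand")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols)) {
    stop("gene table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  for (opt in c("name", "role", "pathway")) {
    if (is.null(genes[[opt]])) genes[[opt]] <- rep("", nrow(genes))
  }
  genes$genome_id <- rep(genome_id, nrow(genes))
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes <- genes[, c("gene_id", "genome_id", "contig", "start", "end",
                     "strand", "name", "role", "pathway")]
  obj <- structure(list(genome_id = genome_id, contigs = contigs,
                        genes = genes),
                   class = "genome_annotation")
  validate_genome(obj)
  obj
}

validate_genome <- function(x) {
  g <- x$genes
  if (nrow(g) == 0L) return(invisible(x))
  bad <- !g$strand %in% c("+", "-")
  if (any(bad)) {
    stop("unknown strand symbol for gene ", g$gene_id[which(bad)[1L]],
         ": '", g$strand[which(bad)[1L]], "'")
  }
  if (anyDuplicated(g$gene_id)) {
    stop("duplicate gene_id within genome: ",
         g$gene_id[anyDuplicated(g$gene_id)])
  }
  if (any(g$start > g$end)) {
    stop("start > end for gene ", g$gene_id[which(g$start > g$end)[1L]])
  }
  unknown <- !g$contig %in% names(x$contigs)
  if (any(unknown)) {
    stop("gene ", g$gene_id[which(unknown)[1L]], " references unknown contig ",
         g$contig[which(unknown)[1L]])
  }
  clen <- nchar(x$contigs)[g$contig]
  if (any(g$end > clen)) {
    stop("coordinate outside contig for gene ",
         g$gene_id[which(g$end > clen)[1L]])
  }
  invisible(x)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation> ", x$genome_id, ": ",
      length(x$contigs), " contig(s), ", nrow(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Load a genome from a gene table and contig FASTA
#'
#' The gene table is either the package's TSV dialect (header `gene_id`,
#' `genome_id`, `contig`, `start`, `end`, `strand`, `name`, `role`,
#' `pathway`) or GFF3 (detected by extension/`##gff` header; `role` and
#' `pathway` are read from the attribute column when present).
#'
#' @param gene_table path to the TSV or GFF3 gene table.
#' @param contigs path to a FASTA file of contig sequences.
#' @param genome_id genome identifier; defaults to the value found in the
#'   table or the file name.
#' @return a [genome_annotation()].
#' @export
load_genome <- function(gene_table, contigs, genome_id = NULL) {
  seqs <- Biostrings::readDNAStringSet(contigs)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  first <- readLines(gene_table, n = 1L)
  is_gff <- grepl("\\.gff3?$", gene_table, ignore.case = TRUE) ||
    startsWith(first, "##gff")
  genes <- if (is_gff) read_gff_genes(gene_table) else {
    utils::read.delim(gene_table, stringsAsFactors = FALSE,
                      colClasses = "character")
  }
  if (is.null(genome_id)) {
    genome_id <- if ("genome_id" %in% names(genes) && nrow(genes) > 0L)
      genes$genome_id[1L]
    else sub("\\.[^.]*$", "", basename(gene_table))
  }
  genome_annotation(genome_id, seqs, genes)
}

read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  keep <- if ("type" %in% names(md)) md$type %in% c("gene", "CDS") else
    rep(TRUE, length(gr))
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  get_attr <- function(field, fallback = "") {
    if (field %in% names(md)) {
      v <- as.character(md[[field]])
      ifelse(is.na(v), fallback, v)
    } else rep(fallback, length(gr))
  }
  data.frame(
    gene_id = get_attr("ID"),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    name = get_attr("Name"),
    role = get_attr("role"),
    pathway = get_attr("pathway"),
    stringsAsFactors = FALSE
  )
}

#' Write a genome's gene table and contigs back to disk
#'
#' Round-trip companion to [load_genome()]: writing then re-reading yields
#' identical records.
#'
#' @param genome a [genome_annotation()].
#' @param gene_table,contigs output paths (TSV and FASTA).
#' @return invisibly, the genome.
#' @export
write_genome <- function(genome, gene_table, contigs) {
  utils::write.table(genome$genes, gene_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  seqs <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(seqs, contigs, width = 70L)
  invisible(genome)
}

#' Chain neighbouring genes into operons
#'
#' Adjacent genes on the same contig and strand whose intergenic gap is at
#' most `max_gap` nucleotides are chained transitively into one operon; every
#' gene ends up in exactly one operon (singletons where no neighbour
#' qualifies). The partition does not depend on the input row order.
#'
#' @param genome a [genome_annotation()].
#' @param max_gap maximum intergenic gap in nt (default 100, a common
#'   bacterial heuristic).
#' @param require_same_strand chain only same-strand neighbours (default
#'   TRUE; divergent or convergent pairs never merge).
#' @return data.frame of class `operon_table` with one row per operon:
#'   `operon_id`, `genome_id`, `contig`, `strand`, `first_start`, `last_end`,
#'   `tss` (the transcription-start-proximal coordinate of the first gene),
#'   `n_genes`, and list-column `gene_ids` in transcription order.
#' @export
predict_operons <- function(genome, max_gap = 100L,
                            require_same_strand = TRUE) {
  g <- genome$genes
  if (nrow(g) == 0L) {
    return(empty_operon_table())
  }
  g <- g[order(g$contig, g$start, g$end), , drop = FALSE]
  new_block <- rep(TRUE, nrow(g))
  if (nrow(g) > 1L) {
    prev <- seq_len(nrow(g) - 1L)
    gap <- g$start[prev + 1L] - g$end[prev] - 1L
    same_contig <- g$contig[prev + 1L] == g$contig[prev]
    same_strand <- if (require_same_strand)
      g$strand[prev + 1L] == g$strand[prev] else TRUE
    new_block[prev + 1L] <- !(same_contig & same_strand & gap <= max_gap)
  }
  block <- cumsum(new_block)
  rows <- lapply(split(seq_len(nrow(g)), block), function(i) {
    gi <- g[i, , drop = FALSE]
    minus <- gi$strand[1L] == "-"
    ids <- if (minus) rev(gi$gene_id) else gi$gene_id
    data.frame(
      operon_id = paste0("opn:", genome$genome_id, ":", ids[1L]),
      genome_id = genome$genome_id,
      contig = gi$contig[1L],
      strand = gi$strand[1L],
      first_start = min(gi$start),
      last_end = max(gi$end),
      tss = if (minus) max(gi$end) else min(gi$start),
      n_genes = nrow(gi),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$gene_ids <- lapply(split(seq_len(nrow(g)), block), function(i) {
    gi <- g[i, , drop = FALSE]
    if (gi$strand[1L] == "-") rev(gi$gene_id) else gi$gene_id
  })
  rownames(out) <- NULL
  class(out) <- c("operon_table", "data.frame")
  out
}

empty_operon_table <- function() {
  out <- data.frame(operon_id = character(), genome_id = character(),
                    contig = character(), strand = character(),
                    first_start = integer(), last_end = integer(),
                    tss = integer(), n_genes = integer(),
                    stringsAsFactors = FALSE)
  out$gene_ids <- list()
  class(out) <- c("operon_table", "data.frame")
  out
}

#' Map gene ids to the operon containing them
#' @param operons an `operon_table`.
#' @return named character vector, gene_id -> operon_id.
#' @export
gene_to_operon <- function(operons) {
  n <- lengths(operons$gene_ids)
  stats::setNames(rep(operons$operon_id, n), unlist(operons$gene_ids))
}

#' Extract promoter-proximal upstream regions of operons
#'
#' The region spans `window[1]` nt upstream of the operon's first gene start
#' plus `window[2]` nt downstream of (and including) that start, oriented
#' 5'->3' toward the gene (minus-strand regions are reverse-complemented).
#' With `truncate_at_neighbor = TRUE` the region never overlaps the coding
#' span of the nearest upstream gene outside the operon. Regions clipped at a
#' contig edge are flagged `truncated`, not errors. Divergently transcribed
#' operon pairs whose regions overlap the shared intergenic segment carry
#' each other's id in `shared_divergent_with`.
#'
#' @param genome a [genome_annotation()].
#' @param operons an `operon_table` (or subset of one) for this genome.
#' @param window integer pair `(upstream_nt, downstream_nt)`, both > 0;
#'   default `c(300, 20)`, a typical bacterial regulatory-region scan span.
#' @param truncate_at_neighbor clip at the upstream neighbour's coding span
#'   (default TRUE).
#' @param min_len regions shorter than this are dropped with a warning
#'   (default 30 nt).
#' @return data.frame of class `upstream_regions`: `operon_id`, `genome_id`,
#'   `contig`, `strand`, `start`, `end` (plus-strand interval), `length`,
#'   `truncated`, `shared_divergent_with`, `seq`.
#' @export
extract_upstream <- function(genome, operons, window = c(300L, 20L),
                             truncate_at_neighbor = TRUE, min_len = 30L) {
  if (length(window) != 2L || any(window <= 0L)) {
    stop("window must be two positive integers (upstream_nt, downstream_nt)")
  }
  up <- as.integer(window[1L]); down <- as.integer(window[2L])
  genes <- genome$genes
  res <- vector("list", nrow(operons))
  for (i in seq_len(nrow(operons))) {
    op <- operons[i, ]
    clen <- nchar(genome$contigs[[op$contig]])
    own <- operons$gene_ids[[i]]
    if (op$strand == "+") {
      lo <- op$tss - up; hi <- op$tss + down - 1L
    } else {
      lo <- op$tss - down + 1L; hi <- op$tss + up
    }
    truncated <- FALSE
    if (lo < 1L) { lo <- 1L; truncated <- TRUE }
    if (hi > clen) { hi <- clen; truncated <- TRUE }
    if (truncate_at_neighbor) {
      other <- genes[genes$contig == op$contig &
                       !genes$gene_id %in% own, , drop = FALSE]
      if (op$strand == "+") {
        ends <- other$end[other$end < op$tss]
        if (length(ends) && max(ends) >= lo) {
          lo <- max(ends) + 1L; truncated <- TRUE
        }
      } else {
        starts <- other$start[other$start > op$tss]
        if (length(starts) && min(starts) <= hi) {
          hi <- min(starts) - 1L; truncated <- TRUE
        }
      }
    }
    len <- hi - lo + 1L
    if (len < min_len) {
      warning("upstream region of ", op$operon_id, " is ", len,
              " nt (< ", min_len, "); skipped")
      next
    }
    s <- substr(genome$contigs[[op$contig]], lo, hi)
    if (op$strand == "-") s <- revcomp(s)
    res[[i]] <- data.frame(
      operon_id = op$operon_id, genome_id = op$genome_id,
      contig = op$contig, strand = op$strand,
      start = lo, end = hi, length = len, truncated = truncated,
      shared_divergent_with = NA_character_, seq = s,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(operon_id = character(), genome_id = character(),
                      contig = character(), strand = character(),
                      start = integer(), end = integer(), length = integer(),
                      truncated = logical(),
                      shared_divergent_with = character(), seq = character(),
                      stringsAsFactors = FALSE)
  }
  # divergent pairs: a minus-strand operon followed by a plus-strand operon
  # whose extracted regions overlap the shared intergenic segment
  if (nrow(out) > 1L) {
    ord <- order(operons$contig, operons$first_start)
    ops <- operons[ord, , drop = FALSE]
    for (j in seq_len(nrow(ops) - 1L)) {
      a <- ops[j, ]; b <- ops[j + 1L, ]
      if (a$contig == b$contig && a$strand == "-" && b$strand == "+" &&
          a$last_end < b$first_start) {
        ia <- match(a$operon_id, out$operon_id)
        ib <- match(b$operon_id, out$operon_id)
        if (!is.na(ia) && !is.na(ib) &&
            out$start[ib] <= out$end[ia] && out$start[ia] <= out$end[ib]) {
          out$shared_divergent_with[ia] <- b$operon_id
          out$shared_divergent_with[ib] <- a$operon_id
        }
      }
    }
  }
  rownames(out) <- NULL
  class(out) <- c("upstream_regions", "data.frame")
  out
}

#' Assemble the motif-discovery training set by gene-neighbourhood analysis
#'
#' Collects the upstream regions of every operon lying within `radius_genes`
#' genes of a TF ortholog in each genome that carries one -- including the
#' TF's own operon, since the studied sugar TFs are encoded inside their
#' regulated loci and autoregulated. Genomes lacking the TF contribute no
#' regions (not an error); the TF being absent from all genomes is an error.
#'
#' @param tf_group ortholog-group id of the transcription factor.
#' @param genomes named list of [genome_annotation()] objects.
#' @param orthologs data.frame with columns `group_id`, `genome_id`,
#'   `gene_id`.
#' @param radius_genes neighbourhood radius in genes (default 5); 0 keeps
#'   only the TF's own operon.
#' @param operons optional named list of precomputed `operon_table`s
#'   (otherwise [predict_operons()] defaults are used).
#' @param window,truncate_at_neighbor,min_len passed to [extract_upstream()].
#' @param dedup_divergent keep only one region of each divergently
#'   transcribed pair sharing an intergenic segment (default TRUE): the
#'   shared segment appears in both regions (reverse-complemented in one),
#'   and exact duplicates would otherwise masquerade as conserved motifs
#'   during discovery.
#' @return an `upstream_regions` data.frame across genomes.
#' @export
neighborhood_training_set <- function(tf_group, genomes, orthologs,
                                      radius_genes = 5L, operons = NULL,
                                      window = c(300L, 20L),
                                      truncate_at_neighbor = TRUE,
                                      min_len = 30L,
                                      dedup_divergent = TRUE) {
  tf_rows <- orthologs[orthologs$group_id == tf_group, , drop = FALSE]
  tf_rows <- tf_rows[tf_rows$genome_id %in% names(genomes), , drop = FALSE]
  if (nrow(tf_rows) == 0L) {
    stop("TF ortholog group '", tf_group, "' absent from all genomes")
  }
  pieces <- list()
  for (gid in unique(tf_rows$genome_id)) {
    genome <- genomes[[gid]]
    ops <- operons[[gid]] %||% predict_operons(genome)
    g2o <- gene_to_operon(ops)
    # gene order index per contig
    genes <- genome$genes[order(genome$genes$contig, genome$genes$start), ]
    genes$idx <- stats::ave(seq_len(nrow(genes)), genes$contig,
                            FUN = seq_along)
    tf_genes <- tf_rows$gene_id[tf_rows$genome_id == gid]
    keep <- character()
    for (tfg in tf_genes) {
      trow <- genes[genes$gene_id == tfg, , drop = FALSE]
      if (nrow(trow) == 0L) next
      near <- genes$gene_id[genes$contig == trow$contig[1L] &
                              abs(genes$idx - trow$idx[1L]) <= radius_genes]
      keep <- union(keep, unname(g2o[near]))
    }
    keep <- keep[!is.na(keep)]
    if (!length(keep)) next
    sel <- ops[ops$operon_id %in% keep, , drop = FALSE]
    pieces[[gid]] <- extract_upstream(genome, sel, window = window,
                                      truncate_at_neighbor =
                                        truncate_at_neighbor,
                                      min_len = min_len)
  }
  out <- do.call(rbind, pieces)
  if (is.null(out)) stop("no upstream regions recovered for ", tf_group)
  if (dedup_divergent && nrow(out) > 1L) {
    drop <- logical(nrow(out))
    for (i in seq_len(nrow(out))) {
      partner <- out$shared_divergent_with[i]
      if (is.na(partner)) next
      j <- which(out$operon_id == partner & out$genome_id == out$genome_id[i])
      # keep the lexicographically smaller operon id of each pair
      if (length(j) && out$operon_id[i] > partner) drop[i] <- TRUE
    }
    out <- out[!drop, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("upstream_regions", "data.frame")
  out
}
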