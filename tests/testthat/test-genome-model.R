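test_that("gene tables and contigs round-trip through write and load", {
  set.seed(11)
  contig <- random_dna(2000)
  genes <- data.frame(
    gene_id = c("TM0439", "TM0440", "TM0441"),
    start = c(101L, 501L, 1201L), end = c(400L, 1100L, 1900L),
    strand = c("+", "-", "+"),
    name = c("uxaR", "uxaE", "uxaD"),
    role = c("TF", "enzyme", "enzyme"),
    pathway = c("Uxa", "Uxa", "Uxa"))
  g <- toy_genome("Tmar", contig, genes)
  tsv <- tempfile(fileext = ".tsv"); fa <- tempfile(fileext = ".fna")
  write_genome(g, tsv, fa)
  g2 <- load_genome(tsv, fa)
  expect_identical(g2$genes, g$genes)
  expect_identical(g2$contigs, g$contigs)
  expect_equal(g2$genes$name[g2$genes$gene_id == "TM0439"], "uxaR")

  # empty gene table with one contig is a valid genome
  empty <- toy_genome("e", contig, genes[0, ])
  expect_identical(nrow(empty$genes), 0L)
})

test_that("invalid annotations fail loudly with the offending gene named", {
  contig <- random_dna(500)
  base <- data.frame(gene_id = "gX", start = 10L, end = 100L, strand = "+",
                     name = "", role = "", pathway = "")
  out_of_range <- base; out_of_range$end <- 900L
  expect_error(toy_genome("g", contig, out_of_range), "gX")
  bad_strand <- base; bad_strand$strand <- "?"
  expect_error(toy_genome("g", contig, bad_strand), "strand")
  dup <- rbind(base, base)
  expect_error(toy_genome("g", contig, dup), "duplicate")
})

test_that("GFF3 gene tables are accepted with role/pathway attributes", {
  contig <- random_dna(1000)
  gff <- tempfile(fileext = ".gff3")
  fa <- tempfile(fileext = ".fna")
  writeLines(c("##gff-version 3",
               paste("c1", "test", "gene", "101", "400", ".", "+", ".",
                     "ID=TM0439;Name=uxaR;role=TF;pathway=Uxa",
                     sep = "\t")), gff)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(c(c1 = contig)), fa)
  g <- load_genome(gff, fa, genome_id = "Tmar")
  expect_equal(g$genes$gene_id, "TM0439")
  expect_equal(g$genes$name, "uxaR")
  expect_equal(g$genes$role, "TF")
  expect_equal(g$genes$start, 101L)
})

test_that("operon chaining follows the same-strand max-gap rule", {
  contig <- random_dna(1000)
  genes <- data.frame(
    gene_id = c("A", "B", "C"),
    start = c(1L, 350L, 700L), end = c(300L, 600L, 900L),
    strand = c("+", "+", "-"),
    name = "", role = "", pathway = "")
  g <- toy_genome("g", contig, genes)
  ops <- predict_operons(g, max_gap = 100L)
  sets <- vapply(ops$gene_ids, function(x) paste(sort(x), collapse = ","),
                 character(1))
  expect_setequal(sets, c("A,B", "C"))

  # single gene forms a singleton operon
  single <- toy_genome("g", contig, genes[1, ])
  expect_equal(predict_operons(single)$gene_ids[[1]], "A")

  # a divergent pair never merges regardless of gap
  div <- genes[1:2, ]; div$strand <- c("-", "+")
  expect_equal(nrow(predict_operons(toy_genome("g", contig, div),
                                    max_gap = 1e6)), 2L)
})

test_that("operon partition covers every gene once, independent of order", {
  set.seed(5)
  for (rep in 1:5) {
    n <- 12L
    starts <- sort(sample.int(5000, n)) * 2L
    genes <- data.frame(
      gene_id = sprintf("g%02d", seq_len(n)),
      start = starts, end = starts + sample(50:400, n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      name = "", role = "", pathway = "")
    genes$end <- pmin(genes$end,
                      c(genes$start[-1] - 1L, 20000L))  # keep non-overlapping
    g <- toy_genome("g", random_dna(20000), genes)
    ops <- predict_operons(g, max_gap = 150L)
    got <- sort(unname(unlist(ops$gene_ids)))
    expect_identical(got, sort(genes$gene_id))       # partition
    shuf <- genes[sample.int(n), ]
    ops2 <- predict_operons(toy_genome("g", random_dna(20000), shuf),
                            max_gap = 150L)
    expect_setequal(
      unname(vapply(ops2$gene_ids, paste, collapse = ",", "")),
      unname(vapply(ops$gene_ids, paste, collapse = ",", "")))
  }
})

test_that("upstream extraction obeys window, orientation and truncation", {
  set.seed(21)
  contig <- random_dna(1000)
  # minus-strand gene ending at 500 with window (300, 20):
  # plus-strand interval [481, 800], reverse-complemented
  genes <- data.frame(gene_id = "M", start = 200L, end = 500L,
                      strand = "-", name = "", role = "", pathway = "")
  g <- toy_genome("g", contig, genes)
  ops <- predict_operons(g)
  reg <- extract_upstream(g, ops, window = c(300L, 20L))
  expect_equal(reg$start, 481L)
  expect_equal(reg$end, 800L)
  expect_equal(reg$seq, naive_revcomp(substr(contig, 481, 800)))
  expect_false(reg$truncated)

  # first gene starting at 1 on + strand: only the downstream part remains
  genes2 <- data.frame(gene_id = "F", start = 1L, end = 300L, strand = "+",
                       name = "", role = "", pathway = "")
  g2 <- toy_genome("g", contig, genes2)
  reg2 <- extract_upstream(g2, predict_operons(g2), window = c(300L, 20L),
                           min_len = 10L)
  expect_equal(reg2$length, 20L)
  expect_true(reg2$truncated)
  expect_equal(reg2$seq, substr(contig, 1, 20))

  expect_error(extract_upstream(g, ops, window = c(0L, 20L)), "window")
})

test_that("divergent operons share the intergenic region and cross-reference", {
  set.seed(31)
  contig <- random_dna(1500)
  genes <- data.frame(gene_id = c("gloR", "gloE"),
                      start = c(100L, 700L), end = c(450L, 1100L),
                      strand = c("-", "+"), name = "", role = "",
                      pathway = "")
  g <- toy_genome("g", contig, genes)
  ops <- predict_operons(g)
  reg <- extract_upstream(g, ops, window = c(300L, 20L))
  i_glor <- match("-", reg$strand)
  i_gloe <- match("+", reg$strand)
  expect_equal(reg$shared_divergent_with[i_glor], reg$operon_id[i_gloe])
  expect_equal(reg$shared_divergent_with[i_gloe], reg$operon_id[i_glor])
  # both regions cover the shared intergenic segment [451, 699]
  expect_lte(reg$start[i_gloe], 460L)
  expect_gte(reg$end[i_glor], 690L)
  # truncation keeps regions off the neighbour's coding span
  expect_gte(reg$start[i_gloe], 451L)
  expect_lte(reg$end[i_glor], 699L)
})

test_that("extracted sequences always equal the genome substring", {
  set.seed(41)
  for (rep in 1:3) {
    com <- generate_community(n_genomes = 2, n_groups = 8, n_regulons = 1,
                              operons_per_regulon = 3,
                              genomes_per_regulon = 2, seed = rep)
    g <- com$genomes[[1]]
    reg <- extract_upstream(g, predict_operons(g))
    for (i in seq_len(nrow(reg))) {
      raw <- substr(g$contigs[[reg$contig[i]]], reg$start[i], reg$end[i])
      expected <- if (reg$strand[i] == "-") naive_revcomp(raw) else raw
      expect_identical(reg$seq[i], expected)
    }
  }
})

test_that("neighbourhood training sets follow the TF across genomes", {
  com <- generate_community(n_genomes = 3, n_groups = 10, n_regulons = 1,
                            operons_per_regulon = 3,
                            genomes_per_regulon = 2, seed = 3)
  tf <- com$truth$design[[1]]$tf_group
  in_genomes <- com$truth$design[[1]]$genomes

  # radius 0: only the TF's own operon, one region per carrying genome
  r0 <- neighborhood_training_set(tf, com$genomes, com$orthologs,
                                  radius_genes = 0L)
  expect_setequal(unique(r0$genome_id), in_genomes)
  expect_equal(nrow(r0), length(in_genomes))
  expect_true(all(grepl(tf, r0$operon_id)))

  # genomes lacking the TF contribute nothing, without error
  r5 <- neighborhood_training_set(tf, com$genomes, com$orthologs,
                                  radius_genes = 5L)
  expect_setequal(unique(r5$genome_id), in_genomes)
  expect_gt(nrow(r5), nrow(r0))

  expect_error(
    neighborhood_training_set("no_such_group", com$genomes, com$orthologs),
    "absent")
})
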