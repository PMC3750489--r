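test_that("site scores are the additive sum of positional weights", {
  # hand profile: column 1 counts A:3, C:1; column 2 counts G:4
  p <- build_pwm(c("AG", "AG", "AG", "CG"))
  expect_equal(score_site(p, "AG"),
               log2(3.25 / 5 * 4) + log2(4.25 / 5 * 4), tolerance = 1e-9)
  expect_equal(score_site(p, "CG"),
               log2(1.25 / 5 * 4) + log2(4.25 / 5 * 4), tolerance = 1e-9)

  # additivity: score equals the sum of single-column scores
  set.seed(1)
  q <- build_pwm(c("ACGTA", "ACCTA", "TCGTG", "ACGTT"))
  s <- "TCGAA"
  per_col <- vapply(1:5, function(i)
    q$weights[substr(s, i, i), i], numeric(1))
  expect_equal(score_site(q, s), sum(per_col), tolerance = 1e-12)

  expect_error(score_site(q, "ACG"), "length")
  expect_error(score_site(q, "ACGTN"), "outside")
})

test_that("the threshold is the lowest training-site score", {
  p <- build_pwm(c("ACGTACGT", "ACGAACGT", "TCGTACGA"))
  one <- set_threshold(p, "ACGTACGT")
  expect_equal(one$threshold, score_site(p, "ACGTACGT"))

  full <- set_threshold(p)
  scores <- vapply(full$training_sites, function(s) score_site(full, s),
                   numeric(1))
  expect_equal(full$threshold, min(scores))
  expect_true(all(scores >= full$threshold))

  # adding sites to the training set never increases the threshold
  set.seed(17)
  sites <- full$training_sites
  t_prev <- full$threshold
  for (i in 1:10) {
    sites <- c(sites, random_dna(8))
    t_new <- set_threshold(p, sites)$threshold
    expect_lte(t_new, t_prev + 1e-12)
    t_prev <- t_new
  }
  expect_error(set_threshold(p, character(0)), "empty")
})

test_that("scan_region agrees with brute-force window enumeration", {
  set.seed(23)
  for (rep in 1:100) {
    L <- sample(4:10, 1)
    n_sites <- sample(3:6, 1)
    sites <- vapply(seq_len(n_sites), function(i) random_dna(L),
                    character(1))
    p <- build_pwm(sites)
    region <- random_dna(sample(60:200, 1), gc = runif(1, 0.3, 0.7))
    thr <- stats::quantile(c(-5, 0, 5, 10), probs = runif(1))
    got <- scan_region(p, region, threshold = thr)
    want <- brute_force_scan(p$weights, region, thr)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$offset, want$offset)
      expect_equal(got$strand, want$strand)
      expect_equal(got$score, want$score, tolerance = 1e-9)
    }
  }
})

test_that("scan hits behave at the edges", {
  p <- trained_profile(c("ACGTAC", "ACGAAC", "ACGTTC"))
  region <- random_dna(100)
  expect_equal(nrow(scan_region(p, region, threshold = Inf)), 0L)
  expect_message(scan_region(p, "ACG"), "shorter")
  expect_error(scan_region(build_pwm("ACGT"), region), "threshold")

  # minus-strand hit scores equal score_site on the reverse complement
  set.seed(3)
  hits <- scan_region(p, region, threshold = -50)
  minus <- hits[hits$strand == "-", ]
  for (i in seq_len(min(nrow(minus), 20))) {
    win <- substr(region, minus$offset[i], minus$offset[i] + p$L - 1)
    expect_equal(minus$score[i], score_site(p, naive_revcomp(win)),
                 tolerance = 1e-9)
    expect_equal(minus$sequence[i], naive_revcomp(win))
  }
})

test_that("palindromic profiles hit both strands equally and collapse", {
  set.seed(9)
  p <- build_pwm(c("TTGACAAAATTGTCAA", "TTGACATTAATGTCAA",
                   "TTGACAGCTCTGTCAA"), palindromic = TRUE)
  region <- random_dna(150)
  thr <- -20
  raw <- brute_force_scan(p$weights, region, thr)
  # symmetry: every + hit has a - hit of equal score at the same offset
  plus <- raw[raw$strand == "+", ]
  minus <- raw[raw$strand == "-", ]
  expect_equal(plus$offset, minus$offset)
  expect_equal(plus$score, minus$score, tolerance = 1e-9)
  # the scanner collapses them to a single "+" record
  got <- scan_region(p, region, threshold = thr)
  expect_true(all(got$strand == "+"))
  expect_equal(got$offset, plus$offset)
})

test_that("hit sets are nested as the threshold decreases", {
  set.seed(29)
  p <- build_pwm(vapply(1:4, function(i) random_dna(8), character(1)))
  region <- random_dna(300)
  thresholds <- c(8, 4, 0, -4, -8)
  prev <- NULL
  for (t in thresholds) {
    hits <- scan_region(p, region, threshold = t)
    key <- paste(hits$offset, hits$strand)
    if (!is.null(prev)) expect_true(all(prev %in% key))
    prev <- key
  }
})

test_that("genome scans report planted sites per operon", {
  com <- generate_community(n_genomes = 2, n_groups = 10, n_regulons = 1,
                            operons_per_regulon = 5,
                            genomes_per_regulon = 2, seed = 8)
  truth <- com$truth
  ts <- truth$sites[truth$sites$genome_id == "g01", ]
  profile <- trained_profile(ts$sequence)
  g <- com$genomes[["g01"]]

  hits <- scan_genome(profile, g)
  hit_ops <- unique(hits$operon_id[hits$passed])
  expect_true(all(ts$operon_id %in% hit_ops))
  # planted offsets are recovered exactly
  for (i in seq_len(nrow(ts))) {
    h <- hits[hits$operon_id == ts$operon_id[i], ]
    expect_true(any(h$offset == ts$offset[i]))
    expect_true(any(h$position == ts$site_start[i]))
  }

  # an empty genome gives an empty map
  empty <- genome_annotation("e", c(c1 = random_dna(500)),
                             data.frame(gene_id = character(),
                                        contig = character(),
                                        start = integer(), end = integer(),
                                        strand = character()))
  expect_equal(nrow(scan_genome(profile, empty)), 0L)

  # lowering the threshold weakly enlarges every per-operon hit list
  lo <- scan_genome(profile, g, threshold = profile$threshold - 5)
  expect_gte(nrow(lo), nrow(hits))
  expect_true(all(paste(hits$operon_id, hits$offset, hits$strand) %in%
                    paste(lo$operon_id, lo$offset, lo$strand)))
})

test_that("hit tables print scores to 4 decimals", {
  p <- trained_profile(c("ACGTAC", "ACGAAC"))
  hits <- scan_genome(p, generate_community(n_genomes = 1, n_groups = 3,
                                            n_regulons = 1,
                                            operons_per_regulon = 2,
                                            genomes_per_regulon = 1,
                                            seed = 2)$genomes[[1]],
                      threshold = -30)
  f <- tempfile(fileext = ".tsv")
  write_hit_table(hits, f)
  re <- utils::read.delim(f, colClasses = "character")
  expect_true(all(grepl("^-?\\d+\\.\\d{4}$", re$score)))
})
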