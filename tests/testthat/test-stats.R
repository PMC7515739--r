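stats_ref <- function() {
  set.seed(51)
  feats <- data.frame(gene_id = c("gp", "gm"), start = c(100L, 300L),
                      end = c(200L, 400L), strand = c("+", "-"),
                      temporal_class = c("early", "late"),
                      stringsAsFactors = FALSE)
  reference_genome("ref", rand_dna(1000), features = feats,
                   regions = list(hot = c(0L, 250L), cold = c(250L, 1000L)))
}

clus <- function(start, strand, len = 38L, count = 1L) {
  data.frame(reference_id = "ref", start = as.integer(start), length = len,
             strand = strand, read_count = count, unique_sequences = 1L,
             stringsAsFactors = FALSE)
}

test_that("targeting follows crRNA:mRNA complementarity", {
  ref <- stats_ref()
  out <- classify_targeting(rbind(clus(120, "-"),   # gene on +, hit on -
                                  clus(120, "+"),   # same gene, hit on +
                                  clus(320, "+"),   # gene on -, hit on +
                                  clus(220, "+")),  # between genes
                            ref)
  expect_equal(out$targeting,
               c("targeting", "non_targeting", "targeting", "intergenic"))
  expect_equal(out$gene_id[1:3], c("gp", "gp", "gm"))
  # [220, 258) overlaps hot by 30 bp and cold by 8 bp -> majority hot
  expect_equal(out$region, c("hot", "hot", "cold", "hot"))
})

test_that("straddling protospacers resolve by majority overlap", {
  feats <- data.frame(gene_id = c("a", "b"), start = c(0L, 50L),
                      end = c(50L, 120L), strand = c("+", "-"),
                      stringsAsFactors = FALSE)
  ref <- reference_genome("ref", rand_dna(200, seed = 52), features = feats)
  # [30, 68): 20 bp in a, 18 bp in b -> a wins
  expect_equal(classify_targeting(clus(30, "-"), ref)$gene_id, "a")
  # [31, 69): 19 in a, 19 in b -> exact tie -> smaller start (a)
  expect_equal(classify_targeting(clus(31, "-"), ref)$gene_id, "a")
  # [40, 78): 10 in a, 28 in b -> b
  expect_equal(classify_targeting(clus(40, "-"), ref)$gene_id, "b")
})

test_that("strand bias report computes weighted and unweighted fractions", {
  ref <- stats_ref()
  cl <- rbind(clus(120, "-", count = 10L),  # targeting, weight 10
              clus(150, "+", count = 2L),   # non-targeting
              clus(320, "+", count = 1L))   # targeting (gene on -)
  cl <- classify_targeting(cl, ref)
  rep_class <- c(ref = "phage")
  rp <- strand_bias_report(cl, rep_class)
  phage <- rp$per_category[rp$per_category$category_type == "replicon", ]
  expect_equal(phage$fraction_targeting[phage$weighting == "weighted"],
               11 / 13)
  expect_equal(phage$fraction_targeting[phage$weighting == "unweighted"],
               2 / 3)
  expect_equal(unname(rp$phage_fraction["weighted"]), 1)

  # all-intergenic input yields NA fractions
  cli <- classify_targeting(clus(220, "+"), ref)
  rpi <- strand_bias_report(cli, rep_class)
  expect_true(all(is.na(rpi$per_category$fraction_targeting)) ||
                nrow(rpi$per_category) == 0)
})

test_that("jaccard overlap satisfies its unit identities", {
  expect_equal(jaccard_overlap(c("a", "b", "c"), c("a", "b", "c")), 1.0)
  expect_equal(jaccard_overlap(c("a", "b"), c("c", "d")), 0.0)
  expect_equal(jaccard_overlap(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_true(is.na(jaccard_overlap(character(), character())))
  set.seed(53)
  for (i in 1:10) {
    A <- sample(letters, sample(0:10, 1))
    B <- sample(letters, sample(1:10, 1))
    j <- jaccard_overlap(A, B)
    expect_equal(j, jaccard_overlap(B, A))
    expect_true(j >= 0 && j <= 1)
  }
})

dbl_table <- function(doubles_regions, singles_regions) {
  n_d <- length(doubles_regions) / 2
  rbind(
    data.frame(read_id = rep(sprintf("d%03d", seq_len(n_d)), each = 2),
               ordinal = rep(1:2, n_d), region = doubles_regions,
               stringsAsFactors = FALSE),
    data.frame(read_id = sprintf("s%03d", seq_along(singles_regions)),
               ordinal = 1L, region = singles_regions,
               stringsAsFactors = FALSE))
}

test_that("chi-square goodness of fit matches the textbook formula", {
  # observed [hot=10, cold=90] against 50/50 at n=100 -> chi2 = 64, df 1
  tab <- dbl_table(c(rep("hot", 10), rep("cold", 90)), rep("hot", 5))
  res <- double_spacer_analysis(tab, single_dist = c(hot = 0.5, cold = 0.5))
  expect_equal(res$chi_square$statistic, 64)
  expect_equal(res$chi_square$df, 1)
  expect_equal(res$chi_square$statistic,
               sum((res$observed - res$expected)^2 / res$expected))

  # identical composition -> statistic 0, p = 1
  tab0 <- dbl_table(c(rep("hot", 30), rep("cold", 30)), rep("hot", 5))
  res0 <- double_spacer_analysis(tab0, single_dist = c(hot = 0.5, cold = 0.5))
  expect_equal(res0$chi_square$statistic, 0)
  expect_equal(res0$chi_square$p_value, 1)
})

test_that("double-read bookkeeping and ordinal fractions are exact", {
  tab <- dbl_table(c("hot", "cold", "hot", "cold", "cold", "cold"),
                   rep(c("hot", "cold"), c(8, 2)))
  res <- double_spacer_analysis(tab, n_reads_total = 100)
  expect_equal(res$n_reads_two_spacers, 3)
  expect_equal(res$fraction_double, 0.03)
  # cold doubles at ordinals: read d001 ordinal 2, d002 ordinal 2, d003 1+2
  expect_equal(res$leader_proximal_cold_fraction, 1 / 4)
  expect_equal(res$distal_cold_fraction, 3 / 4)

  all_lp <- dbl_table(rep(c("cold", "hot"), 3), rep(c("hot", "cold"), c(8, 2)))
  res2 <- double_spacer_analysis(all_lp, n_reads_total = 10)
  expect_equal(res2$leader_proximal_cold_fraction, 1.0)
})

test_that("a nonempty observed cell with zero expectation raises guidance", {
  tab <- dbl_table(c("hot", "cold"), rep("hot", 5))
  expect_error(double_spacer_analysis(tab, single_dist = c(hot = 1)),
               "zero expected")
  expect_error(double_spacer_analysis(tab,
                                      single_dist = c(hot = 1, cold = 0)),
               "expected count is 0")
})

test_that("chi-square p-values are calibrated under the generator null", {
  set.seed(54)
  p <- c(hot = 0.7, cold = 0.3)
  rej <- 0L
  for (i in 1:1000) {
    x <- rmultinom(1, 200, p)[, 1]
    regions <- rep(c("hot", "cold"), x)
    tab <- dbl_table(regions, rep(c("hot", "cold"), c(7, 3)))
    res <- double_spacer_analysis(tab, single_dist = p)
    rej <- rej + (res$chi_square$p_value < 0.05)
  }
  expect_gte(rej / 1000, 0.03)
  expect_lte(rej / 1000, 0.07)
})

test_that("flank matrix columns are base frequencies on the protospacer strand", {
  # reference of all A: every column must be pure A on +, pure T revcomps to A
  refA <- reference_genome("ref", strrep("A", 500))
  cl <- rbind(clus(100, "+"), clus(200, "+"))
  fm <- flank_matrix(cl, refA, flank = 4, spacer_window = 6)
  expect_equal(dim(fm$freq), c(4L, 14L))
  expect_true(all(fm$freq["A", ] == 1))
  expect_true(all(colSums(fm$freq) == 1))
  fm_minus <- flank_matrix(clus(100, "-"), refA, flank = 4)
  expect_true(all(fm_minus$freq["T", ] == 1))

  # boundary protospacer is skipped and counted
  fm_skip <- flank_matrix(rbind(clus(2, "+"), clus(100, "+")), refA, flank = 10)
  expect_equal(fm_skip$n_skipped, 1L)
  expect_equal(fm_skip$n_used, 1L)
  expect_error(flank_matrix(clus(2, "+"), refA, flank = 10), "skipped")
})

test_that("flanks of uniform-random protospacers are near 0.25 per base", {
  set.seed(55)
  ref <- reference_genome("ref", rand_dna(60000))
  starts <- sample(20:59900, 1200)
  cl <- clus(starts, sample(c("+", "-"), 1200, replace = TRUE))
  fm <- flank_matrix(cl, ref, flank = 10, spacer_window = 10)
  expect_true(all(abs(fm$freq - 0.25) < 0.05))
})
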