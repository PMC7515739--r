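test_that("phage genome carries identical terminal repeats and gene blocks", {
  cfg <- simulation_config(seed = 2)
  g <- generate_phage_genome(cfg)
  L <- cfg$ltr_length; G <- cfg$genome_length
  expect_equal(nchar(g$sequence), G)
  expect_identical(substr(g$sequence, 1, L),
                   substr(g$sequence, G - L + 1, G))
  expect_equal(g$regions$hot, c(0L, L))
  # early genes inside the LTR, middle/late outside
  f <- g$features
  expect_true(all(f$end[f$temporal_class == "early"] <= L))
  expect_true(all(f$start[f$temporal_class != "early"] >= L))
  expect_equal(g$metadata$packaging_start, 0L)
})

test_that("degenerate LTR length zero gives no terminal repeat", {
  cfg <- simulation_config(seed = 2, ltr_length = 0,
                           n_genes = c(early = 0L, middle = 5L, late = 5L))
  expect_error(generate_phage_genome(cfg), NA)
  g <- generate_phage_genome(cfg)
  expect_equal(diff(g$regions$hot), 0L)
  expect_null(g$regions$LTR_left)
})

test_that("infeasible gene packing is a parameter error", {
  cfg <- simulation_config(seed = 2, ltr_length = 600,
                           n_genes = c(early = 10L, middle = 2L, late = 2L))
  expect_error(generate_phage_genome(cfg), "infeasible")
})

test_that("all generators are deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 77, n_reads = 200, n_variants = 10)
  g1 <- generate_phage_genome(cfg); g2 <- generate_phage_genome(cfg)
  expect_identical(g1, g2)
  h <- generate_host_genome(cfg); arr <- generate_array_spec(cfg)
  s1 <- simulate_adaptation_reads(g1, h, arr, cfg)
  s2 <- simulate_adaptation_reads(g1, h, arr, cfg)
  expect_identical(s1, s2)
  e1 <- simulate_expression_counts(g1, cfg)
  e2 <- simulate_expression_counts(g1, cfg)
  expect_identical(e1, e2)
  amp <- substr(g1$sequence, 101, 500)
  d1 <- simulate_escaper_reads(amp, c(181, 219), TRUE, cfg)
  d2 <- simulate_escaper_reads(amp, c(181, 219), TRUE, cfg)
  expect_identical(d1, d2)
})

test_that("amplicon reads follow the leader + units + repeat + old-spacer design", {
  fx <- adaptation_fixture(seed = 4, n_reads = 150, error_rate = 0)
  arr <- fx$array
  # every error-free read reconstructs exactly from its truth spacers
  truth_by_read <- split(fx$truth, fx$truth$read_id)
  for (rid in names(truth_by_read)[1:20]) {
    tr <- truth_by_read[[rid]]
    tr <- tr[order(tr$ordinal), ]
    expected <- paste0(arr$leader,
                       paste0(arr$repeat_seq, tr$sequence, collapse = ""),
                       arr$repeat_seq, arr$spacers[1])
    expect_identical(fx$reads$sequences[fx$reads$ids == rid], expected)
  }
})

test_that("with no selection, implanted spacer strands are balanced", {
  fx <- adaptation_fixture(seed = 8, n_reads = 10000, error_rate = 0,
                           selection_factor = 1)
  uniq <- fx$truth[!duplicated(fx$truth$sequence), ]
  n <- nrow(uniq); x <- sum(uniq$strand == "+")
  ci <- binom.test(x, n)$conf.int
  expect_true(ci[1] <= 0.5 && 0.5 <= ci[2])
})

test_that("strong selection concentrates read weight on protective spacers", {
  cfg <- simulation_config(seed = 8, n_reads = 4000, error_rate = 0,
                           selection_factor = 100)
  g <- generate_phage_genome(cfg)
  h <- generate_host_genome(cfg)
  arr <- generate_array_spec(cfg)
  sim <- simulate_adaptation_reads(g, h, arr, cfg)
  # the generator law on per-spacer categorical weights (s per protective
  # spacer, 1 otherwise): weighted protective share >= 90%
  uniq <- sim$truth[!duplicated(paste(sim$truth$clone_id, sim$truth$ordinal)), ]
  w <- ifelse(uniq$protective, 100, 1)
  expect_gt(sum(w[uniq$protective]) / sum(w), 0.9)
  # realized read sampling sits below that bound only through within-clone
  # linkage (non-protective spacers hitchhiking in multi-spacer clones)
  expect_gt(mean(sim$truth$protective), 0.8)
})

test_that("reads can carry up to five new spacers and never more", {
  fx <- adaptation_fixture(seed = 12, n_reads = 5000, error_rate = 0)
  per_read <- table(fx$truth$read_id)
  expect_lte(max(per_read), 5)
  expect_gte(max(per_read), 3)  # multi-spacer tail is exercised
  expect_equal(sort(unique(fx$truth$ordinal[fx$truth$read_id ==
    names(per_read)[which.max(per_read)]])), seq_len(max(per_read)))
})

test_that("noiseless expression counts are recovered perfectly by the classifier", {
  cfg <- simulation_config(seed = 3, nb_size = 1e9)  # vanishing NB noise
  g <- generate_phage_genome(cfg)
  sx <- simulate_expression_counts(g, cfg)
  prof <- temporal_profiles(sx$counts, sx$gene_lengths)
  expect_equal(mean(prof$class == sx$truth[prof$gene_id]), 1.0)
})

test_that("uninfected control column carries zero phage counts", {
  cfg <- simulation_config(seed = 3)
  g <- generate_phage_genome(cfg)
  sx <- simulate_expression_counts(g, cfg, include_uninfected = TRUE)
  expect_true(all(sx$counts[[1]][, "uninfected"] == 0))
})

test_that("essential-gene escaper deletions are multiples of three", {
  cfg <- simulation_config(seed = 6, n_reads = 300, n_variants = 40)
  amp <- rand_dna(400, seed = 21)
  esc <- simulate_escaper_reads(amp, c(181, 219), essential = TRUE, cfg)
  expect_true(all(esc$truth$length %% 3 == 0))
  expect_true(all(esc$truth$frame_preserving))
  # every deletion overlaps the protospacer and spares the primers
  expect_true(all(esc$truth$start < 219 & esc$truth$start + esc$truth$length > 181))
  expect_true(all(esc$truth$start >= 20 &
                    esc$truth$start + esc$truth$length <= 380))
})

test_that("zero deletion rate leaves every read wild-type", {
  cfg <- simulation_config(seed = 6, n_reads = 100, n_variants = 5,
                           wt_fraction = 1, error_rate = 0)
  amp <- rand_dna(400, seed = 22)
  esc <- simulate_escaper_reads(amp, c(181, 219), essential = FALSE, cfg)
  expect_true(all(esc$reads$sequences == amp))
  expect_true(all(esc$truth$n_reads == 0))
})

test_that("oversized deletions are a parameter error", {
  cfg <- simulation_config(seed = 6, del_len_range = c(400L, 500L))
  expect_error(simulate_escaper_reads(rand_dna(300, seed = 1), c(100, 140),
                                      FALSE, cfg), "exceeds")
})
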