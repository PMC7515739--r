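test_that("find_repeats matches a brute-force scan on constructed reads", {
  set.seed(31)
  R <- rand_dna(36)
  S1 <- rand_dna(38); S2 <- rand_dna(38)
  read <- paste0(R, S1, R, S2, R)
  hits <- find_repeats(read, R, max_mismatch = 3)
  expect_equal(hits$offset, c(0L, 74L, 148L))
  expect_equal(hits$strand, rep("+", 3))
  oracle <- oracle_scan(R, read, 3)
  oracle <- oracle[oracle$strand == "+", ]
  expect_equal(hits$offset, oracle$start)

  rc_read <- revcomp(read)
  rhits <- find_repeats(rc_read, R, max_mismatch = 3)
  expect_equal(rhits$strand, rep("-", 3))
  n <- nchar(read)
  expect_equal(sort(n - (rhits$offset + 36)), c(0L, 74L, 148L))
})

test_that("find_repeats tolerates mismatches up to the cap and no further", {
  set.seed(32)
  R <- rand_dna(36)
  mutate_at <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    paste(ch, collapse = "")
  }
  read <- paste0(rand_dna(10), mutate_at(R, c(3, 9, 20)), rand_dna(10))
  expect_equal(nrow(find_repeats(read, R, max_mismatch = 3)), 1)
  expect_equal(find_repeats(read, R, max_mismatch = 3)$mismatches, 3L)
  expect_equal(nrow(find_repeats(read, R, max_mismatch = 2)), 0)
  expect_equal(nrow(find_repeats(rand_dna(100), R, max_mismatch = 3)), 0)
})

test_that("extract_spacers slices gaps with leader-proximal ordinals", {
  set.seed(33)
  arr <- toy_array()
  R <- arr$repeat_seq
  S1 <- rand_dna(38); S2 <- rand_dna(36)
  read <- paste0(arr$leader, R, S1, R, S2, R, arr$spacers[1])
  hits <- find_repeats(read, R, 3)
  sp <- extract_spacers(read, hits, arr, read_id = "r1")
  expect_equal(sp$sequence, c(S1, S2))
  expect_equal(sp$ordinal, c(1L, 2L))
  expect_equal(sp$length, c(38L, 36L))

  # single repeat hit -> no gap -> no spacers
  single <- paste0(arr$leader, R, arr$spacers[1])
  expect_equal(nrow(extract_spacers(single, find_repeats(single, R, 3), arr)), 0)
})

test_that("extraction is invariant under reverse-complementing the read", {
  set.seed(34)
  arr <- toy_array()
  R <- arr$repeat_seq
  S1 <- rand_dna(40); S2 <- rand_dna(35)
  read <- paste0(arr$leader, R, S1, R, S2, R, arr$spacers[1])
  rc <- revcomp(read)
  sp_fwd <- extract_spacers(read, find_repeats(read, R, 3), arr)
  sp_rc <- extract_spacers(rc, find_repeats(rc, R, 3), arr)
  expect_equal(sp_rc$sequence, sp_fwd$sequence)
  expect_equal(sp_rc$ordinal, sp_fwd$ordinal)
})

test_that("mixed-strand reads are rejected and over-long arrays truncated", {
  set.seed(35)
  arr <- toy_array()
  R <- arr$repeat_seq
  mixed <- data.frame(offset = c(0L, 74L), strand = c("+", "-"),
                      mismatches = c(0L, 0L))
  expect_error(extract_spacers("ACGT", mixed, arr), "mixed-strand")

  spacers <- replicate(7, rand_dna(38))
  read <- paste0(arr$leader,
                 paste0(R, spacers, collapse = ""), R, arr$spacers[1])
  hits <- find_repeats(read, R, 3)
  expect_warning(sp <- extract_spacers(read, hits, arr, max_spacers = 5),
                 "keeping the first 5")
  expect_equal(sp$sequence, spacers[1:5])
})

test_that("round-trip: repeats plus extracted spacers rebuild the array region", {
  fx <- adaptation_fixture(seed = 14, n_reads = 100, error_rate = 0)
  ex <- extract_readset(fx$reads, fx$array)
  by_read <- split(ex$candidates, ex$candidates$read_id)
  for (rid in names(by_read)[1:15]) {
    sp <- by_read[[rid]][order(by_read[[rid]]$ordinal), ]
    rebuilt <- paste0(fx$array$leader,
                      paste0(fx$array$repeat_seq, sp$sequence, collapse = ""),
                      fx$array$repeat_seq, fx$array$spacers[1])
    expect_identical(fx$reads$sequences[fx$reads$ids == rid], rebuilt)
  }
})

test_that("error-free extraction recovers the truth table perfectly", {
  fx <- adaptation_fixture(seed = 15, n_reads = 500, error_rate = 0)
  ex <- extract_readset(fx$reads, fx$array)
  tkey <- paste(fx$truth$read_id, fx$truth$ordinal, fx$truth$sequence)
  ckey <- paste(ex$candidates$read_id, ex$candidates$ordinal,
                ex$candidates$sequence)
  expect_equal(mean(tkey %in% ckey), 1.0)
  expect_equal(mean(ckey %in% tkey), 1.0)
})

test_that("recall degrades monotonically as errors rise", {
  recalls <- vapply(c(0, 0.01, 0.04), function(eps) {
    fx <- adaptation_fixture(seed = 16, n_reads = 300, error_rate = eps)
    ex <- extract_readset(fx$reads, fx$array)
    tkey <- paste(fx$truth$read_id, fx$truth$ordinal, fx$truth$sequence)
    ckey <- paste(ex$candidates$read_id, ex$candidates$ordinal,
                  ex$candidates$sequence)
    mean(tkey %in% ckey)
  }, 0)
  expect_true(all(diff(recalls) < 0))
  expect_equal(recalls[1], 1.0)
})

test_that("filter_new_spacers drops short and pre-existing spacers", {
  arr <- toy_array(seed = 36)
  novel <- rand_dna(38)
  cands <- data.frame(
    sequence = c(rand_dna(19), novel, arr$spacers[1], revcomp(arr$spacers[1])),
    read_id = paste0("r", 1:4), ordinal = 1L,
    length = c(19L, 38L, 38L, 38L), stringsAsFactors = FALSE)
  out <- filter_new_spacers(cands, arr)
  expect_equal(out$sequence, novel)
  # 20 bp is the inclusive boundary
  twenty <- data.frame(sequence = rand_dna(20), read_id = "r5", ordinal = 1L,
                       length = 20L, stringsAsFactors = FALSE)
  expect_equal(nrow(filter_new_spacers(twenty, arr)), 1)
  # near-identical to an old spacer (1 mismatch in 38 bp) is still "old"
  near <- arr$spacers[1]
  substr(near, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(near, 5, 5))[1]
  nearly <- data.frame(sequence = near, read_id = "r6", ordinal = 1L,
                       length = 38L, stringsAsFactors = FALSE)
  expect_equal(nrow(filter_new_spacers(nearly, arr)), 0)
})
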