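test_that("perfectly overlapping error-free pairs merge to the amplicon", {
  amp <- rand_dna(120, seed = 71)
  fwd <- substr(amp, 1, 80)
  mate <- revcomp(substr(amp, 41, 120))
  rs <- read_set("p1", fwd, pairing = "paired", mates = mate)
  merged <- merge_pairs(rs)
  expect_equal(merged$sequences, amp)
  expect_equal(attr(merged, "n_dropped"), 0L)
})

test_that("pairs below the overlap threshold are dropped with a count", {
  amp <- rand_dna(300, seed = 72)
  fwd <- substr(amp, 1, 100)
  mate <- revcomp(substr(amp, 191, 300))  # 10 bp overlap < 20
  rs <- read_set("p1", fwd, pairing = "paired", mates = mate)
  merged <- merge_pairs(rs, min_overlap = 20)
  expect_length(merged, 0)
  expect_equal(attr(merged, "n_dropped"), 1L)
})

test_that("overlap conflicts resolve toward the higher-quality base", {
  amp <- rand_dna(100, seed = 73)
  fwd <- substr(amp, 1, 70)
  # corrupt one overlap base on the forward read, give it low quality there
  pos <- 50
  truth_base <- substr(amp, pos, pos)
  bad <- setdiff(c("A", "C", "G", "T"), truth_base)[1]
  substr(fwd, pos, pos) <- bad
  mate <- revcomp(substr(amp, 31, 100))
  qf <- paste0(strrep("I", pos - 1), "#", strrep("I", 70 - pos))
  qr <- strrep("I", 70)
  rs <- read_set("p1", fwd, qualities = qf, pairing = "paired",
                 mates = mate, mate_qualities = qr)
  merged <- merge_pairs(rs)
  expect_equal(substr(merged$sequences, pos, pos), truth_base)
  expect_equal(merged$sequences, amp)
})

test_that("primer anchoring keeps, canonicalises and drops reads correctly", {
  amp <- rand_dna(200, seed = 74)
  fwd <- substr(amp, 1, 20)
  rev <- revcomp(substr(amp, 181, 200))
  rs <- read_set(c("ok", "rc", "no3prime"),
                 c(amp, revcomp(amp), substr(amp, 1, 150)))
  out <- filter_primer_anchored(rs, fwd, rev)
  expect_equal(out$ids, c("ok", "rc"))
  expect_equal(out$sequences, c(amp, amp))  # rc read canonicalised
  expect_equal(attr(out, "n_dropped"), 1L)
  expect_equal(length(out) + attr(out, "n_dropped"), length(rs))
})

test_that("dereplication counts and orders variants deterministically", {
  reads <- c("CCC", "AAA", "CCC", "TTT", "CCC", "AAA")
  v <- dereplicate(reads)
  expect_equal(v$sequence, c("CCC", "AAA", "TTT"))
  expect_equal(v$count, c(3L, 2L, 1L))
  set.seed(75)
  v2 <- dereplicate(sample(reads))
  expect_identical(v, v2)
  expect_equal(nrow(dereplicate(character())), 0)
})

test_that("call_deletions returns exact coordinates with leftmost placement", {
  set.seed(76)
  ref <- rand_dna(300)
  expect_equal(nrow(call_deletions(ref, ref)), 0)

  # 3 bp excised at offset 120, verified against the enumeration oracle
  var <- paste0(substr(ref, 1, 120), substr(ref, 124, 300))
  d <- call_deletions(var, ref)
  expect_equal(d$length, 3L)
  expect_equal(d$start, min(enumerate_single_deletions(ref, var)))

  # homopolymer context forces the leftmost equivalent placement
  hp <- paste0(rand_dna(50), strrep("T", 8), rand_dna(50))
  var_hp <- paste0(substr(hp, 1, 53), substr(hp, 57, 108))  # remove 3 of the Ts
  d_hp <- call_deletions(var_hp, hp)
  expect_equal(d_hp$length, 3L)
  expect_equal(d_hp$start, min(enumerate_single_deletions(hp, var_hp)))
  expect_equal(d_hp$start, 50L)
})

test_that("call_deletions agrees with enumeration on small two-deletion toys", {
  set.seed(77)
  for (i in 1:25) {
    ref <- rand_dna(60)
    l1 <- sample(2:5, 1); l2 <- sample(2:5, 1)
    s1 <- sample(5:20, 1); s2 <- sample(30:50, 1)
    v <- apply_deletions(ref, data.frame(start = c(s1, s2), length = c(l1, l2)))
    d <- call_deletions(v, ref)
    # reconstruction: applying the calls reproduces the variant exactly
    expect_identical(apply_deletions(ref, d), v)
    expect_equal(sum(d$length), l1 + l2)
  }
})

test_that("implanted 3, 99 and 270 bp deletions are recovered with exact lengths", {
  set.seed(78)
  ref <- rand_dna(900)
  for (len in c(3L, 99L, 270L)) {
    s <- 300L
    v <- paste0(substr(ref, 1, s), substr(ref, s + len + 1, 900))
    d <- call_deletions(v, ref)
    expect_equal(nrow(d), 1)
    expect_equal(d$length, len)
    expect_identical(apply_deletions(ref, d), v)
  }
})

test_that("variants longer than the insertion allowance are flagged, not called", {
  ref <- rand_dna(100, seed = 79)
  long <- paste0(ref, rand_dna(50))
  d <- call_deletions(long, ref, insertion_allowance = 10)
  expect_equal(nrow(d), 0)
  expect_true(attr(d, "flagged"))
})

test_that("deletion spectrum summarises frame status both ways", {
  set.seed(80)
  ref <- rand_dna(400)
  mk_var <- function(s, len) paste0(substr(ref, 1, s), substr(ref, s + len + 1, 400))
  variants <- data.frame(
    sequence = c(ref, mk_var(180, 3), mk_var(190, 99), mk_var(185, 4)),
    count = c(10L, 4L, 2L, 4L), stringsAsFactors = FALSE)
  spec <- deletion_spectrum(variants, ref, c(181, 219))
  vt <- spec$variants
  expect_equal(vt$is_wildtype, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(vt$frame_preserving[2:4], c(TRUE, TRUE, FALSE))
  expect_true(all(vt$overlaps_protospacer[2:4]))
  s <- spec$summary
  expect_equal(s$wildtype_read_fraction, 0.5)
  expect_equal(s$frame_preserving_fraction_variants, 2 / 3)
  expect_equal(s$frame_preserving_fraction_reads, 6 / 10)
  expect_equal(unname(s$deletion_size_stats[c("min", "median", "max")]),
               c(3, 4, 99))
})

test_that("read counts are conserved through filter and dereplication", {
  cfg <- simulation_config(seed = 26, n_reads = 500, n_variants = 20)
  amp <- rand_dna(400, seed = 81)
  esc <- simulate_escaper_reads(amp, c(181, 219), essential = TRUE, cfg)
  filt <- filter_primer_anchored(esc$reads, esc$primer_fwd, esc$primer_rev)
  expect_equal(length(filt) + attr(filt, "n_dropped"), length(esc$reads))
  v <- dereplicate(filt)
  expect_equal(sum(v$count), length(filt))
  spec <- deletion_spectrum(v, esc$reference, c(181, 219))
  expect_equal(spec$summary$n_reads, length(filt))
})
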