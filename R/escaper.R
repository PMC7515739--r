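#' Merge overlapping read pairs into amplicon sequences
#'
#' Overlap-consensus merging: the longest suffix/prefix overlap of at least
#' `min_overlap` bases with a mismatch fraction below `max_mismatch_frac`
#' is used; at conflicting bases the higher-quality base wins (first read
#' wins without qualities). Pairs without an acceptable overlap are dropped
#' and counted.
#'
#' @param reads A paired [read_set()] (`sequences` = forward reads,
#'   `mates` = reverse reads as sequenced).
#' @param min_overlap Minimum overlap length (default 20).
#' @param max_mismatch_frac Maximum mismatch fraction inside the overlap.
#' @return A merged `ReadSet`; the number of dropped pairs is attached as
#'   attribute `n_dropped`.
#' @export
merge_pairs <- function(reads, min_overlap = 20L, max_mismatch_frac = 0.1) {
  stopifnot(inherits(reads, "ReadSet"))
  if (reads$pairing != "paired") stop("merge_pairs expects a paired ReadSet")
  n <- length(reads)
  merged <- character(n); ok <- logical(n)
  for (i in seq_len(n)) {
    fwd <- reads$sequences[i]
    rcm <- revcomp(reads$mates[i])
    qf <- if (!is.null(reads$qualities)) reads$qualities[i] else NULL
    qr <- if (!is.null(reads$mate_qualities))
      paste(rev(strsplit(reads$mate_qualities[i], "")[[1]]), collapse = "")
      else NULL
    m <- merge_one(fwd, rcm, qf, qr, min_overlap, max_mismatch_frac)
    if (!is.null(m)) { merged[i] <- m; ok[i] <- TRUE }
  }
  out <- read_set(reads$ids[ok], merged[ok], pairing = "merged")
  attr(out, "n_dropped") <- sum(!ok)
  out
}

merge_one <- function(fwd, rcm, qf, qr, min_overlap, max_mismatch_frac) {
  n1 <- nchar(fwd); n2 <- nchar(rcm)
  if (min(n1, n2) < min_overlap) return(NULL)
  a <- charToRaw(fwd); b <- charToRaw(rcm)
  for (olen in seq(min(n1, n2), min_overlap, by = -1L)) {
    sa <- a[(n1 - olen + 1L):n1]; sb <- b[1:olen]
    mm <- which(sa != sb)
    if (length(mm) > olen * max_mismatch_frac) next
    if (length(mm)) {
      qa <- if (!is.null(qf)) charToRaw(qf)[(n1 - olen + 1L):n1] else NULL
      qb <- if (!is.null(qr)) charToRaw(qr)[1:olen] else NULL
      for (p in mm) {
        use_b <- !is.null(qa) && !is.null(qb) && qb[p] > qa[p]
        if (use_b) sa[p] <- sb[p]
      }
    }
    return(paste0(substr(fwd, 1L, n1 - olen), rawToChar(sa),
                  substr(rcm, olen + 1L, n2)))
  }
  NULL
}

hamming_prefix <- function(x, p) {
  if (nchar(x) < nchar(p)) return(Inf)
  sum(charToRaw(substr(x, 1L, nchar(p))) != charToRaw(p))
}

#' Keep reads anchored by both amplicon primers
#'
#' A read passes when the forward primer sits at its 5' end and the
#' reverse complement of the reverse primer at its 3' end (each within
#' `max_mismatch`); reads in the opposite orientation are
#' reverse-complemented first (canonicalised), primer bases are retained.
#'
#' @param reads A merged [read_set()].
#' @param fwd,rev Primer sequences, 5'->3' on their own strands.
#' @param max_mismatch Per-primer Hamming tolerance (default 2).
#' @return A filtered, canonicalised `ReadSet` with attribute `n_dropped`.
#' @export
filter_primer_anchored <- function(reads, fwd, rev, max_mismatch = 2L) {
  stopifnot(inherits(reads, "ReadSet"))
  fwd <- toupper(fwd); rev_rc <- revcomp(toupper(rev))
  anchored <- function(s) {
    hamming_prefix(s, fwd) <= max_mismatch &&
      hamming_prefix(paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                     paste(rev(strsplit(rev_rc, "")[[1]]), collapse = "")) <=
        max_mismatch
  }
  keep <- logical(length(reads)); seqs <- reads$sequences
  for (i in seq_along(seqs)) {
    if (anchored(seqs[i])) {
      keep[i] <- TRUE
    } else {
      rc <- revcomp(seqs[i])
      if (anchored(rc)) { seqs[i] <- rc; keep[i] <- TRUE }
    }
  }
  out <- read_set(reads$ids[keep], seqs[keep], pairing = reads$pairing)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Dereplicate identical read sequences into variants
#'
#' @param reads A merged [read_set()] (or character vector of sequences).
#' @return Data frame `sequence`, `count`, sorted by count descending,
#'   ties broken lexicographically by sequence.
#' @export
dereplicate <- function(reads) {
  seqs <- if (inherits(reads, "ReadSet")) reads$sequences else reads
  if (!length(seqs)) {
    return(data.frame(sequence = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(seqs)
  out <- data.frame(sequence = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call deletions in a variant relative to the reference amplicon
#'
#' Global alignment with affine gaps (defaults: match +1, mismatch -2,
#' gap open -6, gap extend -0.5 — a single long deletion is preferred over
#' scattered mismatches); gaps in the variant relative to the reference
#' are reported as deletions. In repetitive context each deletion is
#' shifted to its leftmost equivalent placement, the convention shared
#' with standard variant normalisation.
#'
#' @param variant_sequence Variant (escaper) sequence.
#' @param reference_amplicon Reference amplicon sequence.
#' @param match,mismatch,gap_open,gap_extend Alignment scores.
#' @param insertion_allowance Maximum excess variant length before the
#'   variant is flagged instead of called.
#' @return Data frame `start` (0-based position in the reference),
#'   `length`; zero rows for an identical sequence. Attribute `flagged` is
#'   `TRUE` when the variant exceeded the insertion allowance and no calls
#'   were attempted; attribute `n_mismatches` records aligned mismatches
#'   (recorded, not interpreted).
#' @export
call_deletions <- function(variant_sequence, reference_amplicon,
                           match = 1, mismatch = -2,
                           gap_open = 6, gap_extend = 0.5,
                           insertion_allowance = 10L) {
  empty <- data.frame(start = integer(), length = integer(),
                      stringsAsFactors = FALSE)
  attr(empty, "flagged") <- FALSE
  attr(empty, "n_mismatches") <- 0L
  if (variant_sequence == reference_amplicon) return(empty)
  if (nchar(variant_sequence) > nchar(reference_amplicon) + insertion_allowance) {
    attr(empty, "flagged") <- TRUE
    return(empty)
  }
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(variant_sequence),
    Biostrings::DNAString(reference_amplicon),
    type = "global", substitutionMatrix = sm,
    gapOpening = gap_open, gapExtension = gap_extend)
  out <- del_on_subject(aln, reference_amplicon)
  attr(out, "flagged") <- FALSE
  attr(out, "n_mismatches") <- Biostrings::nmismatch(aln)
  out
}

# Convert the pattern-gap ranges of a global alignment into 0-based
# reference coordinates and shift each deletion leftmost.
del_on_subject <- function(aln, reference) {
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  is_gap <- pat == "-" & sub != "-"
  ref_pos <- cumsum(sub != "-")  # 1-based reference coordinate per column
  r <- rle(is_gap)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  gidx <- which(r$values)
  starts1 <- ref_pos[starts[gidx]]  # 1-based start of each deleted block
  lens <- r$lengths[gidx]
  refch <- strsplit(reference, "")[[1]]
  prev_end <- 0L
  for (i in seq_along(starts1)) {
    s <- starts1[i]; e <- s + lens[i] - 1L
    while (s - 1L > prev_end && refch[s - 1L] == refch[e]) {
      s <- s - 1L; e <- e - 1L
    }
    starts1[i] <- s
    prev_end <- e
  }
  data.frame(start = starts1 - 1L, length = lens, stringsAsFactors = FALSE)
}

#' Deletion spectrum of escaper variants
#'
#' Calls deletions for every dereplicated variant and summarises the
#' spectrum: per-variant reading-frame status (total deleted length
#' divisible by 3), frame-preserving fraction both over unique variants
#' and weighted by reads, deletion-size box statistics, wild-type read
#' fraction and the top variants.
#'
#' @param variants Data frame from [dereplicate()] (`sequence`, `count`).
#' @param reference_amplicon Reference amplicon sequence.
#' @param protospacer Length-2 vector `c(start, end)` (0-based half-open)
#'   of the targeted protospacer within the amplicon.
#' @param top_n Number of top variants to retain in the summary.
#' @param ... Alignment parameters passed to [call_deletions()].
#' @return Object of class `DeletionSpectrum`: `variants` (per-variant
#'   table with `count`, `n_deletions`, `del_starts`, `del_lengths`,
#'   `total_deleted`, `frame_preserving`, `overlaps_protospacer`,
#'   `is_wildtype`, `flagged`) and `summary` (list with
#'   `n_variants`, `n_reads`, `wildtype_read_fraction`,
#'   `frame_preserving_fraction_variants`,
#'   `frame_preserving_fraction_reads`, `deletion_size_stats`
#'   (min/Q1/median/Q3/max), `top_variants`).
#' @export
deletion_spectrum <- function(variants, reference_amplicon, protospacer,
                              top_n = 10L, ...) {
  ps <- as.integer(protospacer)
  n <- nrow(variants)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    dels <- call_deletions(variants$sequence[i], reference_amplicon, ...)
    overlaps <- nrow(dels) > 0 &&
      any(iv_overlap(dels$start, dels$start + dels$length, ps[1], ps[2]) > 0L)
    rows[[i]] <- data.frame(
      variant = sprintf("variant_%04d", i),
      count = variants$count[i],
      n_deletions = nrow(dels),
      del_starts = paste(dels$start, collapse = ","),
      del_lengths = paste(dels$length, collapse = ","),
      total_deleted = sum(dels$length),
      frame_preserving = sum(dels$length) %% 3L == 0L,
      overlaps_protospacer = overlaps,
      is_wildtype = variants$sequence[i] == reference_amplicon,
      flagged = isTRUE(attr(dels, "flagged")),
      stringsAsFactors = FALSE)
  }
  vt <- if (n) do.call(rbind, rows) else
    data.frame(variant = character(), count = integer(),
               n_deletions = integer(), del_starts = character(),
               del_lengths = character(), total_deleted = integer(),
               frame_preserving = logical(), overlaps_protospacer = logical(),
               is_wildtype = logical(), flagged = logical(),
               stringsAsFactors = FALSE)
  with_del <- vt[vt$n_deletions > 0L, , drop = FALSE]
  all_lens <- as.integer(unlist(strsplit(with_del$del_lengths, ","), use.names = FALSE))
  size_stats <- if (length(all_lens)) {
    setNames(fivenum(all_lens), c("min", "q1", "median", "q3", "max"))
  } else NULL
  total_reads <- sum(vt$count)
  summary <- list(
    n_variants = n,
    n_reads = total_reads,
    wildtype_read_fraction = frac_or_na(sum(vt$count[vt$is_wildtype]),
                                        total_reads),
    frame_preserving_fraction_variants =
      frac_or_na(sum(with_del$frame_preserving), nrow(with_del)),
    frame_preserving_fraction_reads =
      frac_or_na(sum(with_del$count[with_del$frame_preserving]),
                 sum(with_del$count)),
    deletion_size_stats = size_stats,
    top_variants = head(vt[order(-vt$count), , drop = FALSE], top_n))
  structure(list(variants = vt, summary = summary),
            class = "DeletionSpectrum")
}

#' @export
print.DeletionSpectrum <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("DeletionSpectrum: %d variants / %d reads; ",
                     "wild-type read fraction %.3f\n"),
              s$n_variants, s$n_reads, s$wildtype_read_fraction))
  cat(sprintf("  frame-preserving: %.3f of variants, %.3f of reads\n",
              s$frame_preserving_fraction_variants,
              s$frame_preserving_fraction_reads))
  invisible(x)
}
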