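#' Find CRISPR repeat occurrences in a read
#'
#' Scans one read for all non-overlapping occurrences of the repeat or its
#' reverse complement within a Hamming-distance tolerance. Overlaps are
#' resolved greedily left to right (leftmost hit wins); at equal offset the
#' forward orientation wins.
#'
#' @param read Read sequence (character scalar).
#' @param repeat_seq Repeat sequence.
#' @param max_mismatch Maximum Hamming distance per occurrence (default 3,
#'   about 8% of a 36 bp repeat).
#' @return Data frame with columns `offset` (0-based start in the read),
#'   `strand` (`"+"` read carries the repeat, `"-"` its reverse complement)
#'   and `mismatches`, sorted by offset. Zero rows when nothing matches.
#' @export
find_repeats <- function(read, repeat_seq, max_mismatch = 3L) {
  if (nchar(repeat_seq) > nchar(read)) {
    stop("repeat is longer than the read")
  }
  subj <- Biostrings::DNAString(read)
  hits_one <- function(pattern, strand) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pattern), subj,
                                  max.mismatch = max_mismatch, fixed = TRUE)
    if (!length(m)) return(NULL)
    mm <- Biostrings::neditAt(Biostrings::DNAString(pattern), subj,
                              at = BiocGenerics::start(m))
    data.frame(offset = BiocGenerics::start(m) - 1L, strand = strand,
               mismatches = as.integer(mm), stringsAsFactors = FALSE)
  }
  hits <- rbind(hits_one(repeat_seq, "+"), hits_one(revcomp(repeat_seq), "-"))
  if (is.null(hits) || !nrow(hits)) {
    return(data.frame(offset = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  resolve_overlaps(hits, nchar(repeat_seq))
}

# Greedy left-to-right non-overlap resolution; '+' preferred at ties.
resolve_overlaps <- function(hits, rep_len) {
  hits <- hits[order(hits$offset, hits$strand), , drop = FALSE]
  keep <- logical(nrow(hits))
  last_end <- -1L
  for (i in seq_len(nrow(hits))) {
    if (hits$offset[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- hits$offset[i] + rep_len
    }
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract candidate spacers between consecutive repeat hits
#'
#' The read is first canonicalised to leader-first orientation (reads whose
#' repeats match on the `"-"` strand are reverse-complemented, offsets
#' mirrored), then each gap between consecutive repeat occurrences becomes
#' one candidate spacer. Ordinal 1 is the leader-proximal (most recently
#' acquired) position. Reads with repeat hits on both strands are rejected,
#' and at most `max_spacers` spacers are emitted per read (extras discarded
#' with a warning).
#'
#' @param read Read sequence.
#' @param hits Repeat hits from [find_repeats()].
#' @param array A [crispr_array_spec()] (provides the repeat length).
#' @param read_id Identifier recorded on the candidates.
#' @param max_spacers Cap on emitted spacers per read (default 5).
#' @return Data frame with columns `sequence`, `read_id`, `ordinal`,
#'   `length`. Zero rows when fewer than two repeat hits.
#' @export
extract_spacers <- function(read, hits, array, read_id = "read",
                            max_spacers = 5L) {
  if (length(unique(hits$strand)) > 1L) {
    stop("mixed-strand repeat hits; read should be flagged and skipped")
  }
  empty <- data.frame(sequence = character(), read_id = character(),
                      ordinal = integer(), length = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(hits) < 2L) return(empty)
  rep_len <- nchar(array$repeat_seq)
  if (nrow(hits) && hits$strand[1] == "-") {
    n <- nchar(read)
    read <- revcomp(read)
    hits$offset <- n - (hits$offset + rep_len)
    hits <- hits[order(hits$offset), , drop = FALSE]
  }
  gaps_start <- hits$offset[-nrow(hits)] + rep_len
  gaps_end <- hits$offset[-1L]
  keep <- gaps_end > gaps_start
  gaps_start <- gaps_start[keep]; gaps_end <- gaps_end[keep]
  if (!length(gaps_start)) return(empty)
  seqs <- substring(read, gaps_start + 1L, gaps_end)
  if (length(seqs) > max_spacers) {
    warning("read '", read_id, "' yielded ", length(seqs),
            " spacers; keeping the first ", max_spacers)
    seqs <- seqs[seq_len(max_spacers)]
  }
  data.frame(sequence = seqs, read_id = read_id,
             ordinal = seq_along(seqs), length = nchar(seqs),
             stringsAsFactors = FALSE)
}

#' Extract candidate spacers from a whole ReadSet
#'
#' Vectorised repeat detection (both orientations at once) followed by
#' per-read gap extraction. Reads with mixed-strand repeat hits are skipped
#' and counted.
#'
#' @param reads A [read_set()] of merged amplicon reads.
#' @param array A [crispr_array_spec()].
#' @param max_mismatch Hamming tolerance per repeat occurrence.
#' @param max_spacers Per-read cap on emitted spacers.
#' @return List with `candidates` (data frame as in [extract_spacers()]) and
#'   `qc`: counts of reads total / with repeats / mixed-strand skipped /
#'   over-cap truncated.
#' @export
extract_readset <- function(reads, array, max_mismatch = 3L, max_spacers = 5L) {
  stopifnot(inherits(reads, "ReadSet"), inherits(array, "CRISPRArraySpec"))
  n <- length(reads)
  qc <- c(reads_total = n, reads_with_repeats = 0L,
          reads_mixed_strand = 0L, reads_truncated = 0L)
  if (!n) {
    return(list(candidates = data.frame(sequence = character(),
                                        read_id = character(),
                                        ordinal = integer(), length = integer(),
                                        stringsAsFactors = FALSE),
                qc = qc))
  }
  subj <- Biostrings::DNAStringSet(reads$sequences)
  rep_len <- nchar(array$repeat_seq)
  fwd <- Biostrings::vmatchPattern(array$repeat_seq, subj,
                                   max.mismatch = max_mismatch, fixed = TRUE)
  rev <- Biostrings::vmatchPattern(revcomp(array$repeat_seq), subj,
                                   max.mismatch = max_mismatch, fixed = TRUE)
  fs <- BiocGenerics::start(fwd); rs <- BiocGenerics::start(rev)
  seq_out <- vector("list", n); id_out <- vector("list", n)
  for (i in seq_len(n)) {
    off <- c(fs[[i]], rs[[i]]) - 1L
    if (length(off) < 2L) next
    minus <- rep(c(FALSE, TRUE), c(length(fs[[i]]), length(rs[[i]])))
    o <- order(off, minus)
    off <- off[o]; minus <- minus[o]
    # greedy left-to-right non-overlap resolution on plain vectors
    keep <- logical(length(off)); last_end <- -1L
    for (j in seq_along(off)) {
      if (off[j] >= last_end) { keep[j] <- TRUE; last_end <- off[j] + rep_len }
    }
    off <- off[keep]; minus <- minus[keep]
    if (length(off) < 2L) next
    qc[["reads_with_repeats"]] <- qc[["reads_with_repeats"]] + 1L
    if (any(minus) && !all(minus)) {
      qc[["reads_mixed_strand"]] <- qc[["reads_mixed_strand"]] + 1L
      next
    }
    read <- reads$sequences[i]
    if (all(minus)) {  # canonicalise to leader-first orientation
      read <- revcomp(read)
      off <- sort(nchar(read) - (off + rep_len))
    }
    gs <- off[-length(off)] + rep_len
    ge <- off[-1L]
    ok <- ge > gs
    gs <- gs[ok]; ge <- ge[ok]
    if (!length(gs)) next
    if (length(gs) > max_spacers) {
      qc[["reads_truncated"]] <- qc[["reads_truncated"]] + 1L
      gs <- gs[seq_len(max_spacers)]; ge <- ge[seq_len(max_spacers)]
    }
    seq_out[[i]] <- substring(read, gs + 1L, ge)
    id_out[[i]] <- reads$ids[i]
  }
  got <- !vapply(seq_out, is.null, TRUE)
  nsp <- lengths(seq_out[got])
  seqs <- unlist(seq_out[got], use.names = FALSE)
  candidates <- if (length(seqs)) {
    data.frame(sequence = seqs,
               read_id = rep(unlist(id_out[got], use.names = FALSE), nsp),
               ordinal = unlist(lapply(nsp, seq_len), use.names = FALSE),
               length = nchar(seqs), stringsAsFactors = FALSE)
  } else {
    data.frame(sequence = character(), read_id = character(),
               ordinal = integer(), length = integer(),
               stringsAsFactors = FALSE)
  }
  list(candidates = candidates, qc = qc)
}

#' Filter candidates to newly acquired spacers
#'
#' Drops candidates shorter than `min_len` (default 20 bp) and candidates
#' matching any pre-existing array spacer in either orientation at the
#' mapping identity threshold; survivors pass through unchanged.
#'
#' @param candidates Candidate data frame from [extract_readset()].
#' @param array A [crispr_array_spec()].
#' @param min_len Minimum spacer length retained.
#' @param min_identity Identity threshold used for the self-match test.
#' @return The surviving subset of `candidates`.
#' @export
filter_new_spacers <- function(candidates, array, min_len = 20L,
                               min_identity = 0.95) {
  if (!nrow(candidates)) return(candidates)
  keep <- candidates$length >= min_len
  old <- array$spacers
  if (length(old)) {
    uniq <- unique(candidates$sequence[keep])
    old_set <- uniq[matches_old_spacer(uniq, old, min_identity)]
    keep <- keep & !(candidates$sequence %in% old_set)
  }
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# TRUE when the shorter of a/b occurs in the longer (either orientation)
# with at most floor(len_short * (1 - min_identity)) mismatches.
approx_contains <- function(a, b, min_identity) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  mm <- floor(nchar(a) * (1 - min_identity) + 1e-9)
  p <- Biostrings::DNAString(a)
  s <- Biostrings::DNAString(b)
  length(Biostrings::matchPattern(p, s, max.mismatch = mm)) > 0L ||
    length(Biostrings::matchPattern(Biostrings::reverseComplement(p), s,
                                    max.mismatch = mm)) > 0L
}

# Vectorised approx_contains over many candidates against few old spacers:
# byte-matrix Hamming comparison at every admissible offset.
matches_old_spacer <- function(cands, old, min_identity) {
  hit <- logical(length(cands))
  clean <- grepl(DNA_STRICT, cands)
  for (i in which(!clean)) {
    hit[i] <- any(vapply(old, function(o)
      approx_contains(cands[i], o, min_identity), TRUE))
  }
  cl <- which(clean & !hit)
  if (!length(cl)) return(hit)
  for (o in old) {
    no <- nchar(o)
    # candidate contained in (or equal to) the old spacer
    shorter <- cl[nchar(cands[cl]) <= no]
    for (grp in split(shorter, nchar(cands[shorter]))) {
      w <- nchar(cands[grp[1]])
      mm <- max_mm(w, min_identity)
      mat <- matrix(charToRaw(paste(cands[grp], collapse = "")),
                    ncol = w, byrow = TRUE)
      for (target in c(o, revcomp(o))) {
        for (off in 0:(no - w)) {
          tb <- charToRaw(substr(target, off + 1L, off + w))
          d <- rowSums(mat != matrix(tb, nrow(mat), w, byrow = TRUE))
          hit[grp] <- hit[grp] | (d <= mm)
        }
      }
    }
    # old spacer contained in a longer candidate: vectorised pattern match
    longer <- cl[nchar(cands[cl]) > no]
    if (length(longer)) {
      mm <- max_mm(no, min_identity)
      subj <- Biostrings::DNAStringSet(cands[longer])
      n_fwd <- Biostrings::vcountPattern(o, subj, max.mismatch = mm)
      n_rev <- Biostrings::vcountPattern(revcomp(o), subj, max.mismatch = mm)
      hit[longer] <- hit[longer] | (n_fwd + n_rev > 0L)
    }
    cl <- cl[!hit[cl]]
    if (!length(cl)) break
  }
  hit
}
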