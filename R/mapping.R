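ref_seqs <- function(references) {
  if (inherits(references, "ReferenceGenome")) references <- list(references)
  if (is.list(references)) {
    setNames(vapply(references, `[[`, "", "sequence"),
             vapply(references, `[[`, "", "id"))
  } else {
    stopifnot(is.character(references), !is.null(names(references)))
    toupper(references)
  }
}

empty_hits <- function() {
  data.frame(sequence = character(), reference_id = character(),
             start = integer(), length = integer(), strand = character(),
             identity = numeric(), unique = logical(),
             stringsAsFactors = FALSE)
}

max_mm <- function(len, min_identity) as.integer(floor(len * (1 - min_identity) + 1e-9))

#' Map one spacer to reference genomes
#'
#' Finds every locus on either strand of any reference where the ungapped
#' identity (matches / spacer length) reaches `min_identity`. Hit strand
#' `"+"` means the spacer sequence matches the stored top strand. The
#' `unique` flag is `TRUE` iff exactly one locus passes across *all*
#' references jointly, so a spacer matching both the phage and the host is
#' non-unique.
#'
#' @param spacer Spacer sequence (>= 20 bp).
#' @param references A `ReferenceGenome`, list thereof, or named character
#'   vector of sequences.
#' @param min_identity Identity threshold (default 0.95).
#' @return Data frame of hits with columns `sequence`, `reference_id`,
#'   `start` (0-based), `length`, `strand`, `identity`, `unique`; zero rows
#'   when unmapped.
#' @export
map_spacer <- function(spacer, references, min_identity = 0.95) {
  if (nchar(spacer) < 20L) stop("spacer must be at least 20 bp")
  refs <- ref_seqs(references)
  mm <- max_mm(nchar(spacer), min_identity)
  p_fwd <- Biostrings::DNAString(spacer)
  p_rev <- Biostrings::reverseComplement(p_fwd)
  rows <- list()
  for (rid in names(refs)) {
    subj <- Biostrings::DNAString(refs[[rid]])
    for (strand in c("+", "-")) {
      p <- if (strand == "+") p_fwd else p_rev
      m <- Biostrings::matchPattern(p, subj, max.mismatch = mm, fixed = TRUE)
      if (!length(m)) next
      ned <- Biostrings::neditAt(p, subj, at = BiocGenerics::start(m))
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = spacer, reference_id = rid,
        start = BiocGenerics::start(m) - 1L, length = nchar(spacer),
        strand = strand, identity = (nchar(spacer) - ned) / nchar(spacer),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_hits())
  hits <- do.call(rbind, rows)
  hits$unique <- nrow(hits) == 1L
  hits <- hits[order(hits$reference_id, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

count_mismatches <- function(a, b) {
  mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b,
         USE.NAMES = FALSE)
}

#' Map many spacers to reference genomes at once
#'
#' Same contract as [map_spacer()], vectorised: spacers are grouped by
#' length and matched with a preprocessed dictionary against both strands
#' of every reference. Sequences containing `N` fall back to the
#' single-spacer path.
#'
#' @param spacers Character vector of spacer sequences (deduplicated
#'   internally; the output carries one row per hit per distinct sequence).
#' @param references As in [map_spacer()].
#' @param min_identity Identity threshold.
#' @return Data frame of hits as in [map_spacer()].
#' @export
map_spacers <- function(spacers, references, min_identity = 0.95) {
  spacers <- unique(spacers)
  spacers <- spacers[nchar(spacers) >= 20L]
  if (!length(spacers)) return(empty_hits())
  refs <- ref_seqs(references)
  clean <- grepl(DNA_STRICT, spacers)
  rows <- list()
  for (s in spacers[!clean]) {
    r <- map_spacer(s, refs, min_identity)
    r$unique <- NULL
    rows[[length(rows) + 1L]] <- r
  }

  sp <- spacers[clean]
  if (length(sp)) {
    # seed-and-verify: a constant-width prefix dictionary is matched once
    # per reference and strand at the loosest mismatch cap, then every seed
    # hit is verified against the full-length per-spacer cap. Any locus
    # within a spacer's own cap also puts <= cap mismatches in its prefix,
    # so seeding loses nothing.
    lens <- nchar(sp)
    w_seed <- min(lens)
    mm_caps <- max_mm(lens, min_identity)
    mm_seed <- max(mm_caps)
    rc_sp <- revcomp(sp)
    seeds <- list("+" = substr(sp, 1L, w_seed),
                  "-" = substr(rc_sp, 1L, w_seed))
    pdicts <- lapply(seeds, function(s)
      Biostrings::PDict(Biostrings::DNAStringSet(s), max.mismatch = mm_seed))
    for (rid in names(refs)) {
      subj <- Biostrings::DNAString(refs[[rid]])
      n_ref <- length(subj)
      for (strand in c("+", "-")) {
        m <- Biostrings::matchPDict(pdicts[[strand]], subj,
                                    max.mismatch = mm_seed)
        nh <- S4Vectors::elementNROWS(m)
        if (!sum(nh)) next
        pat_idx <- rep(seq_along(sp), nh)
        starts <- unlist(BiocGenerics::start(m), use.names = FALSE)
        fits <- starts + lens[pat_idx] - 1L <= n_ref
        pat_idx <- pat_idx[fits]; starts <- starts[fits]
        if (!length(starts)) next
        full <- if (strand == "+") sp[pat_idx] else rc_sp[pat_idx]
        found <- substring(refs[[rid]], starts, starts + lens[pat_idx] - 1L)
        ned <- count_mismatches(full, found)
        ok <- ned <= mm_caps[pat_idx]
        if (!any(ok)) next
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = sp[pat_idx[ok]], reference_id = rid,
          start = starts[ok] - 1L, length = lens[pat_idx[ok]],
          strand = strand,
          identity = (lens[pat_idx[ok]] - ned[ok]) / lens[pat_idx[ok]],
          stringsAsFactors = FALSE)
      }
    }
  }
  rows <- rows[vapply(rows, nrow, 0L) > 0L]
  if (!length(rows)) return(empty_hits())
  hits <- do.call(rbind, rows)
  if (is.null(hits$unique)) hits$unique <- NA
  nloci <- table(hits$sequence)
  hits$unique <- as.integer(nloci[hits$sequence]) == 1L
  hits <- hits[order(hits$sequence, hits$reference_id, hits$start,
                     hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Map candidate spacers and keep uniquely mapped ones
#'
#' Joins per-read candidates (from [extract_readset()] and
#' [filter_new_spacers()]) with genome-wide hits of their distinct
#' sequences, retaining only uniquely mapped spacers.
#'
#' @param candidates Candidate data frame (`sequence`, `read_id`,
#'   `ordinal`, `length`).
#' @param references As in [map_spacer()].
#' @param min_identity Identity threshold.
#' @return Data frame with one row per mapped candidate: candidate columns
#'   plus `reference_id`, `start`, `strand`, `identity`.
#' @export
map_candidates <- function(candidates, references, min_identity = 0.95) {
  hits <- map_spacers(candidates$sequence, references, min_identity)
  hits <- hits[hits$unique, , drop = FALSE]
  merged <- merge(candidates, hits[c("sequence", "reference_id", "start",
                                     "strand", "identity")],
                  by = "sequence", sort = FALSE)
  merged <- merged[order(merged$read_id, merged$ordinal), , drop = FALSE]
  rownames(merged) <- NULL
  merged
}

#' Aggregate unique hits into protospacer clusters
#'
#' Groups hits by `(reference_id, start, length, strand)` and accumulates
#' read counts and the number of distinct spacer sequences per cluster.
#'
#' @param hits Data frame of uniquely mapped per-read hits (one row per
#'   read's spacer), e.g. from [map_candidates()].
#' @return Data frame of clusters ordered by `(reference_id, start)`:
#'   `reference_id`, `start`, `length`, `strand`, `read_count`,
#'   `unique_sequences`.
#' @export
dedupe_to_clusters <- function(hits) {
  cols <- c("reference_id", "start", "length", "strand", "read_count",
            "unique_sequences")
  if (!nrow(hits)) {
    out <- data.frame(reference_id = character(), start = integer(),
                      length = integer(), strand = character(),
                      read_count = integer(), unique_sequences = integer(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  if (!is.null(hits$unique) && !all(hits$unique)) {
    stop("dedupe_to_clusters expects uniquely mapped hits only")
  }
  key <- paste(hits$reference_id, hits$start, hits$length, hits$strand,
               sep = "\r")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  out <- data.frame(reference_id = hits$reference_id[first],
                    start = hits$start[first], length = hits$length[first],
                    strand = hits$strand[first],
                    read_count = tabulate(idx, nbins = sum(first)),
                    unique_sequences = as.integer(
                      tapply(hits$sequence, idx,
                             function(s) length(unique(s)))),
                    stringsAsFactors = FALSE)
  out <- out[order(out$reference_id, out$start, out$length, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[cols]
}

#' Combine clusters into a positional profile
#'
#' Read counts are summed over spacer lengths per `(reference_id, start,
#' strand)`, the representation used to draw protospacer coverage along a
#' genome. Total counts are conserved.
#'
#' @param clusters Cluster data frame from [dedupe_to_clusters()].
#' @return Data frame `reference_id`, `start`, `strand`, `read_count`,
#'   ordered by `(reference_id, start, strand)`.
#' @export
positional_profile <- function(clusters) {
  if (!nrow(clusters)) {
    return(data.frame(reference_id = character(), start = integer(),
                      strand = character(), read_count = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(clusters$reference_id, clusters$start, clusters$strand,
               sep = "\r")
  cnt <- tapply(clusters$read_count, key, sum)
  parts <- do.call(rbind, strsplit(names(cnt), "\r", fixed = TRUE))
  out <- data.frame(reference_id = parts[, 1],
                    start = as.integer(parts[, 2]), strand = parts[, 3],
                    read_count = as.integer(cnt), stringsAsFactors = FALSE)
  out <- out[order(out$reference_id, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a positional profile as strand-split bedGraph tracks
#'
#' @param profile Data frame from [positional_profile()].
#' @param prefix Output path prefix; files `<prefix>.plus.bedGraph` and
#'   `<prefix>.minus.bedGraph` are written.
#' @return Character vector of the two paths, invisibly.
#' @export
write_profile_bedgraph <- function(profile, prefix) {
  paths <- c(paste0(prefix, ".plus.bedGraph"), paste0(prefix, ".minus.bedGraph"))
  for (i in 1:2) {
    strand <- c("+", "-")[i]
    sub <- profile[profile$strand == strand, , drop = FALSE]
    lines <- sprintf("%s\t%d\t%d\t%d", sub$reference_id, sub$start,
                     sub$start + 1L, sub$read_count)
    writeLines(lines, paths[i])
  }
  invisible(paths)
}
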