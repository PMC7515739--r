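# Fixtures and independent oracles shared across the suite. Oracles are
# deliberately naive re-derivations (byte-level scans, enumeration) that do
# not touch the code paths they check.

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

toy_array <- function(repeat_seq = NULL, spacer1 = NULL, seed = 11) {
  set.seed(seed)
  if (is.null(repeat_seq)) repeat_seq <- rand_dna(36)
  leader <- rand_dna(60)
  if (is.null(spacer1)) spacer1 <- rand_dna(38)
  crispr_array_spec("toy", repeat_seq, spacers = spacer1, leader = leader,
                    primer_fwd = substr(leader, 1, 20),
                    primer_rev = revcomp(substr(spacer1, 19, 38)))
}

# Exhaustive both-strand ungapped scan: every offset, byte-level mismatch
# count. The independent oracle for repeat finding and spacer mapping.
oracle_scan <- function(pattern, refseq, max_mm) {
  scan_one <- function(p, strand) {
    m <- nchar(p); n <- nchar(refseq)
    if (m > n) return(NULL)
    pr <- charToRaw(p); rr <- charToRaw(refseq)
    # every offset is examined; offsets are discarded exactly when their
    # accumulated mismatch count already exceeds the cap (it cannot drop)
    offs <- seq_len(n - m + 1L)
    mm <- integer(length(offs))
    for (j in seq_len(m)) {
      mm <- mm + (rr[offs + j - 1L] != pr[j])
      if (j %% 8L == 0L || j == m) {
        keep <- mm <= max_mm
        offs <- offs[keep]; mm <- mm[keep]
        if (!length(offs)) return(NULL)
      }
    }
    data.frame(start = offs - 1L, strand = strand, mismatches = as.integer(mm),
               stringsAsFactors = FALSE)
  }
  out <- rbind(scan_one(pattern, "+"), scan_one(revcomp(pattern), "-"))
  if (is.null(out)) {
    out <- data.frame(start = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE)
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

# Excise called deletions from a reference (right to left); the
# construct-by-deletion oracle for call_deletions.
apply_deletions <- function(ref, dels) {
  if (!nrow(dels)) return(ref)
  for (i in rev(order(dels$start))) {
    ref <- paste0(substr(ref, 1, dels$start[i]),
                  substr(ref, dels$start[i] + dels$length[i] + 1, nchar(ref)))
  }
  ref
}

# All single-deletion placements of length len reproducing the variant;
# enumeration oracle for leftmost placement.
enumerate_single_deletions <- function(ref, variant) {
  len <- nchar(ref) - nchar(variant)
  if (len <= 0) return(integer())
  starts <- integer()
  for (s in 0:(nchar(ref) - len)) {
    cand <- paste0(substr(ref, 1, s), substr(ref, s + len + 1, nchar(ref)))
    if (cand == variant) starts <- c(starts, s)
  }
  starts
}

adaptation_fixture <- function(seed = 5, n_reads = 400, ...) {
  cfg <- simulation_config(seed = seed, n_reads = n_reads, ...)
  genome <- generate_phage_genome(cfg)
  host <- generate_host_genome(cfg)
  array <- generate_array_spec(cfg)
  sim <- simulate_adaptation_reads(genome, host, array, cfg)
  list(cfg = cfg, genome = genome, host = host, array = array,
       reads = sim$reads, truth = sim$truth,
       refs = list(nonredundant_reference(genome), host))
}
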