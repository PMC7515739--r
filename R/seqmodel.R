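#' @import methods
#' @importFrom stats rbinom rnbinom runif setNames quantile fivenum chisq.test binom.test rlnorm
#' @importFrom utils write.table read.table head modifyList
NULL

DNA_STRICT <- "^[ACGT]*$"
DNA_WITH_N <- "^[ACGTN]*$"

#' Reference genome with gene features and named regions
#'
#' Container for a replicon (phage genome, host chromosome or megaplasmid):
#' the sequence, strand-annotated gene features, and named regions such as
#' the left/right long terminal repeats (LTRs) or the spacer-acquisition
#' "hot" region. All coordinates are 0-based half-open intervals on the
#' stored top strand.
#'
#' @param id Replicon identifier.
#' @param sequence DNA string over `{A,C,G,T}` (uppercased on input).
#' @param topology `"linear"` or `"circular"`.
#' @param features Data frame of gene features with columns `gene_id`,
#'   `start`, `end` (0-based half-open), `strand` (`"+"`/`"-"`), and
#'   optionally `temporal_class` (`early`/`middle`/`late`/`unassigned`) and
#'   `essential` (logical; used only by the simulator).
#' @param regions Named list of length-2 integer vectors `c(start, end)`,
#'   0-based half-open (e.g. `LTR_left`, `hot`, `cold`).
#' @param metadata Free-form list (e.g. packaging start coordinate).
#' @return An object of class `ReferenceGenome`.
#' @export
reference_genome <- function(id, sequence, topology = c("linear", "circular"),
                             features = empty_features(), regions = list(),
                             metadata = list()) {
  topology <- match.arg(topology)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("reference sequence must be non-empty")
  if (!grepl(DNA_STRICT, sequence)) {
    stop("reference sequence contains characters outside {A,C,G,T}")
  }
  features <- as_feature_frame(features)
  n <- nchar(sequence)
  if (nrow(features)) {
    if (anyDuplicated(features$gene_id)) stop("feature gene_ids must be unique")
    if (any(features$start < 0L) || any(features$end > n)) {
      stop("feature intervals must lie within [0, ", n, ")")
    }
  }
  for (nm in names(regions)) {
    iv <- regions[[nm]]
    if (length(iv) != 2L || iv[1] > iv[2] || iv[1] < 0L || iv[2] > n) {
      stop("region '", nm, "' is not a valid interval within the sequence")
    }
  }
  structure(list(id = id, sequence = sequence, topology = topology,
                 features = features, regions = regions, metadata = metadata),
            class = "ReferenceGenome")
}

empty_features <- function() {
  data.frame(gene_id = character(), start = integer(), end = integer(),
             strand = character(), temporal_class = character(),
             essential = logical(), stringsAsFactors = FALSE)
}

as_feature_frame <- function(features) {
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (!nrow(features)) return(empty_features())
  need <- c("gene_id", "start", "end", "strand")
  miss <- setdiff(need, names(features))
  if (length(miss)) stop("features lack column(s): ", paste(miss, collapse = ", "))
  if (is.null(features$temporal_class)) features$temporal_class <- "unassigned"
  if (is.null(features$essential)) features$essential <- FALSE
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (any(features$start >= features$end)) stop("feature start must be < end")
  if (!all(features$strand %in% c("+", "-"))) stop("feature strand must be '+' or '-'")
  if (!all(features$temporal_class %in% c("early", "middle", "late", "unassigned"))) {
    stop("temporal_class must be early/middle/late/unassigned")
  }
  features[c("gene_id", "start", "end", "strand", "temporal_class", "essential")]
}

#' @export
print.ReferenceGenome <- function(x, ...) {
  cat(sprintf("ReferenceGenome '%s': %d bp (%s), %d features, %d regions\n",
              x$id, nchar(x$sequence), x$topology, nrow(x$features),
              length(x$regions)))
  invisible(x)
}

#' CRISPR array specification
#'
#' Describes one CRISPR array as assayed by leader-anchored PCR: the repeat,
#' the ordered pre-existing spacers (index 1 = leader-proximal), the leader
#' sequence, and the amplicon primer pair (forward anneals to the leader,
#' reverse to the leader-proximal spacer).
#'
#' @param array_id Array identifier.
#' @param repeat_seq Repeat sequence (>= 20 bp).
#' @param spacers Character vector of pre-existing spacers, leader-proximal
#'   first; may be empty.
#' @param leader Leader sequence.
#' @param primer_fwd,primer_rev Amplicon primers, 5'->3' on their own strands.
#' @return An object of class `CRISPRArraySpec`.
#' @export
crispr_array_spec <- function(array_id, repeat_seq, spacers = character(),
                              leader, primer_fwd, primer_rev) {
  repeat_seq <- toupper(repeat_seq); leader <- toupper(leader)
  spacers <- toupper(spacers)
  primer_fwd <- toupper(primer_fwd); primer_rev <- toupper(primer_rev)
  if (nchar(repeat_seq) < 20L) stop("repeat must be at least 20 bp")
  if (!nzchar(primer_fwd) || !nzchar(primer_rev)) stop("primers must be non-empty")
  for (s in c(repeat_seq, leader, primer_fwd, primer_rev, spacers)) {
    if (!grepl(DNA_STRICT, s)) stop("array sequences must be over {A,C,G,T}")
  }
  structure(list(array_id = array_id, repeat_seq = repeat_seq,
                 spacers = spacers, leader = leader,
                 primers = c(fwd = primer_fwd, rev = primer_rev)),
            class = "CRISPRArraySpec")
}

#' @export
print.CRISPRArraySpec <- function(x, ...) {
  cat(sprintf("CRISPRArraySpec '%s': %d bp repeat, %d pre-existing spacers\n",
              x$array_id, nchar(x$repeat_seq), length(x$spacers)))
  invisible(x)
}

#' Set of sequencing reads
#'
#' @param ids Character vector of unique read identifiers.
#' @param sequences Character vector of read sequences over `{A,C,G,T,N}`.
#' @param qualities Optional character vector of Phred+33 quality strings.
#' @param pairing `"single"`, `"paired"` or `"merged"`. For `"paired"`,
#'   `mates` holds the second read of each pair (same order).
#' @param mates,mate_qualities Mate sequences/qualities for paired sets.
#' @return An object of class `ReadSet`.
#' @export
read_set <- function(ids, sequences, qualities = NULL,
                     pairing = c("single", "paired", "merged"),
                     mates = NULL, mate_qualities = NULL) {
  pairing <- match.arg(pairing)
  if (anyDuplicated(ids)) stop("read ids must be unique")
  sequences <- toupper(sequences)
  if (length(sequences) && !all(grepl(DNA_WITH_N, sequences))) {
    stop("read sequences must be over {A,C,G,T,N}")
  }
  if (pairing == "paired") {
    if (is.null(mates) || length(mates) != length(sequences)) {
      stop("paired ReadSet requires mates of equal length")
    }
    mates <- toupper(mates)
  }
  structure(list(ids = as.character(ids), sequences = sequences,
                 qualities = qualities, pairing = pairing,
                 mates = mates, mate_qualities = mate_qualities),
            class = "ReadSet")
}

#' @export
length.ReadSet <- function(x) length(x$sequences)

#' @export
print.ReadSet <- function(x, ...) {
  cat(sprintf("ReadSet: %d %s reads\n", length(x), x$pairing))
  invisible(x)
}

#' Read a FASTA file into reference genomes
#'
#' One `ReferenceGenome` (sequence only) per record, in file order. Sequences
#' are uppercased and RNA `U` is mapped to `T`.
#'
#' @param path Path to a FASTA file.
#' @return List of [reference_genome()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e)))
  if (!length(set)) stop("FASTA file has no records: ", path)
  seqs <- chartr("u", "t", tolower(unname(as.character(set))))
  seqs <- toupper(seqs)
  ids <- sub("\\s.*$", "", names(set))
  empties <- which(!nzchar(seqs))
  if (length(empties)) {
    stop("empty sequence for FASTA record '", ids[empties[1]], "'")
  }
  lapply(seq_along(seqs), function(i) reference_genome(ids[i], seqs[i]))
}

#' Write reference genomes to FASTA
#'
#' @param genomes A `ReferenceGenome` or list thereof.
#' @param path Output path.
#' @export
write_fasta <- function(genomes, path) {
  if (inherits(genomes, "ReferenceGenome")) genomes <- list(genomes)
  set <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(set) <- vapply(genomes, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read gene annotations from GFF3 or BED
#'
#' GFF3 1-based closed coordinates are converted to the package-wide 0-based
#' half-open convention; BED intervals are taken as-is. Strand is preserved.
#' A `temporal_class` GFF3 attribute, when present, is carried through.
#'
#' @param path Path to the annotation file.
#' @param format `"gff3"` or `"bed"`.
#' @return Feature data frame as used in [reference_genome()].
#' @export
read_annotations <- function(path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed")
  if (!length(gr)) return(empty_features())
  md <- S4Vectors::mcols(gr)
  ids <- if (format == "gff3" && !is.null(md$ID)) as.character(md$ID)
         else if (!is.null(md$name)) as.character(md$name)
         else paste0("feature_", seq_along(gr))
  tc <- if (!is.null(md$temporal_class)) as.character(md$temporal_class)
        else "unassigned"
  tc[is.na(tc)] <- "unassigned"
  start0 <- BiocGenerics::start(gr) - 1L  # GRanges is 1-based closed either way
  end0 <- BiocGenerics::end(gr)
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*")) stop("features must be stranded (+/-): ", path)
  if (any(end0 <= start0)) stop("invalid interval (end <= start) in ", path)
  as_feature_frame(data.frame(gene_id = ids, start = start0, end = end0,
                              strand = strand, temporal_class = tc,
                              stringsAsFactors = FALSE))
}

#' Write gene annotations to GFF3
#'
#' Internal 0-based half-open intervals are converted back to the GFF3
#' 1-based closed convention. The temporal class is written as a
#' `temporal_class` attribute.
#'
#' @param features Feature data frame.
#' @param path Output path.
#' @param seqid Sequence name to place in column 1.
#' @export
write_annotations <- function(features, path, seqid = "genome") {
  features <- as_feature_frame(features)
  gr <- GenomicRanges_from_features(features, seqid)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

GenomicRanges_from_features <- function(features, seqid) {
  gr <- GenomicRanges::GRanges(
    seqnames = rep(seqid, nrow(features)),
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = features$strand)
  S4Vectors::mcols(gr)$ID <- features$gene_id
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$temporal_class <- features$temporal_class
  gr
}

#' Reverse complement of a DNA sequence
#'
#' Vectorised over its argument; `N` is allowed and maps to `N`.
#'
#' @param seq Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  if (!length(seq)) return(character())
  bad <- !grepl(DNA_WITH_N, seq)
  if (any(bad)) stop("non-DNA character in sequence: ", seq[bad][1])
  out <- character(length(seq))
  nz <- nzchar(seq)
  out[!nz] <- ""
  if (any(nz)) {
    out[nz] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seq[nz])))
  }
  out
}

#' Read amplicon reads from FASTQ
#'
#' @param path Path to an (uncompressed or gzipped) FASTQ file.
#' @param pairing Pairing label to attach to the resulting [read_set()].
#' @return A `ReadSet`.
#' @export
read_fastq <- function(path, pairing = "merged") {
  if (!file.exists(path)) stop("no such file: ", path)
  qs <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  read_set(ids = sub("\\s.*$", "", names(qs)),
           sequences = unname(as.character(qs)),
           qualities = unname(as.character(Biostrings::quality(qs))),
           pairing = pairing)
}

#' Write a ReadSet to FASTQ
#'
#' Reads without stored qualities are written with a constant Q40 string.
#'
#' @param reads A `ReadSet`.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$sequences)
  names(seqs) <- reads$ids
  quals <- reads$qualities
  if (is.null(quals)) {
    quals <- vapply(nchar(reads$sequences),
                    function(n) strrep("I", n), "")
  }
  S4Vectors::mcols(seqs) <- NULL
  x <- Biostrings::QualityScaledDNAStringSet(
    seqs, Biostrings::PhredQuality(quals))
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Write a CRISPR array spec to a plain-text key:value file
#'
#' Format: one `key: value` pair per line with keys `array_id`, `repeat`,
#' `leader`, `primer_fwd`, `primer_rev`, and one `spacer:` line per
#' pre-existing spacer (leader-proximal first).
#'
#' @param array A `CRISPRArraySpec`.
#' @param path Output path.
#' @export
write_array_spec <- function(array, path) {
  lines <- c(paste0("array_id: ", array$array_id),
             paste0("repeat: ", array$repeat_seq),
             paste0("leader: ", array$leader),
             paste0("primer_fwd: ", array$primers[["fwd"]]),
             paste0("primer_rev: ", array$primers[["rev"]]),
             paste0("spacer: ", array$spacers))
  writeLines(lines, path)
  invisible(path)
}

#' Read a CRISPR array spec from a plain-text key:value file
#'
#' @param path Path written by [write_array_spec()].
#' @return A `CRISPRArraySpec`.
#' @export
read_array_spec <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  m <- regmatches(lines, regexec("^([a-z_]+):\\s*(.*)$", lines))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad)) stop("malformed array spec line: '", lines[bad][1], "'")
  keys <- vapply(m, `[`, "", 2L); vals <- vapply(m, `[`, "", 3L)
  get1 <- function(k) {
    v <- vals[keys == k]
    if (length(v) != 1L) stop("array spec needs exactly one '", k, "' line")
    v
  }
  crispr_array_spec(array_id = get1("array_id"), repeat_seq = get1("repeat"),
                    spacers = vals[keys == "spacer"], leader = get1("leader"),
                    primer_fwd = get1("primer_fwd"),
                    primer_rev = get1("primer_rev"))
}

# Does [s1,e1) overlap [s2,e2)?  (0-based half-open)
iv_overlap <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2))
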