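#' Normalise a count matrix to TPM or CPM
#'
#' `tpm`: counts are first divided by gene length (per-kb rate), then each
#' column is scaled to sum to 1e6 — transcripts per million. `cpm`: counts
#' per million without length normalisation ("normalisation on the total
#' number of counted reads"). The mode is recorded as an attribute.
#'
#' @param counts Genes x timepoints matrix of non-negative counts.
#' @param gene_lengths Named (or positionally matched) gene lengths in bp;
#'   required for `tpm`.
#' @param mode `"tpm"` (default) or `"cpm"`.
#' @return Abundance matrix of the same shape; every column sums to 1e6.
#' @export
normalize_abundance <- function(counts, gene_lengths = NULL,
                                mode = c("tpm", "cpm")) {
  mode <- match.arg(mode)
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  zero_cols <- colSums(counts) == 0
  if (any(zero_cols)) {
    stop("all-zero count column at timepoint: ",
         paste(colnames(counts)[zero_cols], collapse = ", "))
  }
  if (mode == "tpm") {
    if (is.null(gene_lengths)) stop("tpm mode requires gene_lengths")
    if (!is.null(names(gene_lengths)) && !is.null(rownames(counts))) {
      gene_lengths <- gene_lengths[rownames(counts)]
    }
    if (any(is.na(gene_lengths)) || any(gene_lengths <= 0)) {
      stop("gene_lengths must be positive for every gene")
    }
    rate <- counts / (gene_lengths / 1000)
    ab <- sweep(rate, 2L, colSums(rate), "/") * 1e6
  } else {
    ab <- sweep(counts, 2L, colSums(counts), "/") * 1e6
  }
  attr(ab, "normalization") <- mode
  ab
}

#' Log10 fold change between two abundances
#'
#' `log10(A_y + c) - log10(A_x + c)` with pseudocount `c` guarding zeros;
#' antisymmetric in its arguments.
#'
#' @param a_x,a_y Non-negative abundances (vectorised).
#' @param pseudocount Pseudocount `c` (default 1).
#' @return Numeric vector of log fold changes.
#' @export
logfc <- function(a_x, a_y, pseudocount = 1) {
  if (any(a_x < 0) || any(a_y < 0)) stop("abundances must be non-negative")
  log10(a_y + pseudocount) - log10(a_x + pseudocount)
}

#' Assign early/middle/late temporal classes from LogFC values
#'
#' Rules applied in order: *early* if `LogFC_30vs50 < 0`; else *middle* if
#' `LogFC_30vs50 > 0` and `LogFC_50vs70 < 0`; else *late* if
#' `LogFC_50vs70 > 0`; genes satisfying none (exact zeros) are
#' `unclassified`. The early rule anchors the class to a pre-30-min
#' abundance maximum, so a gene that also rises after 50 min still counts
#' as early.
#'
#' @param logfc_30v50,logfc_50v70 Numeric vectors of log fold changes.
#' @return Character vector of classes.
#' @export
assign_temporal_class <- function(logfc_30v50, logfc_50v70) {
  ifelse(logfc_30v50 < 0, "early",
         ifelse(logfc_30v50 > 0 & logfc_50v70 < 0, "middle",
                ifelse(logfc_50v70 > 0, "late", "unclassified")))
}

#' Temporal profiles and classes for a gene x timepoint experiment
#'
#' Normalises each replicate, averages normalised abundances across
#' replicates, computes `LogFC_30vs50` and `LogFC_50vs70`, and assigns the
#' temporal class; per-replicate classes are also reported.
#'
#' @param counts A genes x timepoints matrix or list of replicate matrices
#'   with identical dimnames. Column names must be `t<minutes>` or plain
#'   minutes; timepoints 30, 50 and 70 are required.
#' @param gene_lengths Gene lengths for TPM (see [normalize_abundance()]).
#' @param mode Normalisation mode.
#' @param pseudocount Pseudocount for [logfc()].
#' @return An object of class `TemporalProfiles`: data frame with
#'   `gene_id`, one `A_t<min>` column per timepoint (replicate-averaged),
#'   `logfc_30v50`, `logfc_50v70`, `class`, and `class_rep<i>` columns;
#'   the abundance matrix is attached as attribute `abundance`.
#' @export
temporal_profiles <- function(counts, gene_lengths = NULL,
                              mode = c("tpm", "cpm"), pseudocount = 1) {
  mode <- match.arg(mode)
  if (is.matrix(counts) || is.data.frame(counts)) counts <- list(counts)
  tp <- parse_timepoints(colnames(counts[[1]]))
  for (need in c(30, 50, 70)) {
    if (!need %in% tp) stop("missing required timepoint: ", need, " min")
  }
  abund <- lapply(counts, normalize_abundance, gene_lengths = gene_lengths,
                  mode = mode)
  avg <- Reduce(`+`, abund) / length(abund)
  i30 <- which(tp == 30); i50 <- which(tp == 50); i70 <- which(tp == 70)
  lf1 <- logfc(avg[, i30], avg[, i50], pseudocount)
  lf2 <- logfc(avg[, i50], avg[, i70], pseudocount)
  out <- data.frame(gene_id = rownames(avg), stringsAsFactors = FALSE)
  for (j in seq_along(tp)) out[[paste0("A_t", tp[j])]] <- avg[, j]
  out$logfc_30v50 <- lf1
  out$logfc_50v70 <- lf2
  out$class <- assign_temporal_class(lf1, lf2)
  for (r in seq_along(abund)) {
    a <- abund[[r]]
    out[[paste0("class_rep", r)]] <- assign_temporal_class(
      logfc(a[, i30], a[, i50], pseudocount),
      logfc(a[, i50], a[, i70], pseudocount))
  }
  attr(out, "abundance") <- avg
  attr(out, "normalization") <- mode
  class(out) <- c("TemporalProfiles", "data.frame")
  out
}

parse_timepoints <- function(labels) {
  if (is.null(labels)) stop("count matrix needs timepoint column names")
  tp <- suppressWarnings(as.numeric(sub("^t", "", labels)))
  if (any(is.na(tp))) stop("cannot parse timepoints from column names: ",
                           paste(labels, collapse = ", "))
  tp
}

#' Row-normalised heatmap matrix of temporal profiles
#'
#' Each gene's abundance trajectory is divided by its own maximum, the
#' representation used to draw expression heatmaps. All-zero genes stay
#' zero and are flagged.
#'
#' @param profiles A `TemporalProfiles` object or abundance matrix.
#' @return Matrix in `[0, 1]` with attribute `zero_genes` (character
#'   vector of flagged all-zero genes).
#' @export
heatmap_rows <- function(profiles) {
  m <- if (inherits(profiles, "TemporalProfiles")) attr(profiles, "abundance")
       else as.matrix(profiles)
  mx <- apply(m, 1L, max)
  zero <- mx == 0
  out <- m / ifelse(mx == 0, 1, mx)
  attr(out, "zero_genes") <- rownames(m)[zero]
  out
}

#' Write temporal classes back into a feature table
#'
#' @param features Feature data frame (see [reference_genome()]).
#' @param profiles A `TemporalProfiles` object.
#' @return `features` with `temporal_class` replaced where classified.
#' @export
apply_temporal_classes <- function(features, profiles) {
  idx <- match(features$gene_id, profiles$gene_id)
  cls <- profiles$class[idx]
  ok <- !is.na(cls) & cls != "unclassified"
  features$temporal_class[ok] <- cls[ok]
  features
}
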