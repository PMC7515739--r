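#' Classify protospacer clusters as transcript-targeting or not
#'
#' A protospacer is *targeting* when the spacer sequence equals the gene's
#' template (transcribed) strand there, so the crRNA base-pairs with the
#' mRNA: a gene on `"+"` is targeted by hits on strand `"-"` and vice
#' versa. Clusters not overlapping any gene are `intergenic`. A protospacer
#' straddling two genes is assigned by majority overlap (exact tie: the
#' gene with the smaller start).
#'
#' @param clusters Cluster data frame (needs `reference_id`, `start`,
#'   `length`, `strand`).
#' @param references List of [reference_genome()] (or a single one)
#'   providing gene features and named regions per `reference_id`.
#' @return `clusters` with added columns `gene_id`, `gene_strand`,
#'   `temporal_class`, `targeting` (`targeting` / `non_targeting` /
#'   `intergenic`) and `region` (name of the covering region, majority
#'   rule, or `NA`).
#' @export
classify_targeting <- function(clusters, references) {
  if (inherits(references, "ReferenceGenome")) references <- list(references)
  names(references) <- vapply(references, `[[`, "", "id")
  n <- nrow(clusters)
  gene_id <- rep(NA_character_, n); gene_strand <- rep(NA_character_, n)
  tclass <- rep(NA_character_, n); region <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    ref <- references[[clusters$reference_id[i]]]
    if (is.null(ref)) next
    s <- clusters$start[i]; e <- s + clusters$length[i]
    gi <- majority_gene_index(s, e, ref$features)
    if (!is.na(gi)) {
      gene_id[i] <- ref$features$gene_id[gi]
      gene_strand[i] <- ref$features$strand[gi]
      tclass[i] <- ref$features$temporal_class[gi]
    }
    if (length(ref$regions)) {
      ov <- vapply(ref$regions, function(iv) iv_overlap(s, e, iv[1], iv[2]), 0L)
      ov <- ov[setdiff(names(ov), c("LTR_left", "LTR_right"))]
      if (length(ov) && any(ov * 2L > (e - s))) {
        region[i] <- names(ov)[ov * 2L > (e - s)][1]
      }
    }
  }
  clusters$gene_id <- gene_id
  clusters$gene_strand <- gene_strand
  clusters$temporal_class <- tclass
  clusters$targeting <- ifelse(is.na(gene_strand), "intergenic",
                               ifelse(clusters$strand != gene_strand,
                                      "targeting", "non_targeting"))
  clusters$region <- region
  clusters
}

frac_or_na <- function(num, den) ifelse(den > 0, num / den, NA_real_)

#' Strand-bias report over replicons, temporal classes and regions
#'
#' For each category the number of transcript-targeting and non-targeting
#' protospacers among gene-overlapping clusters is reported twice:
#' abundance-weighted ("all spacers", weights = read counts) and unweighted
#' ("unique spacers", each cluster once). The phage-derived fraction of all
#' spacers is also computed.
#'
#' @param clusters Classified clusters from [classify_targeting()] (must
#'   have `read_count`).
#' @param replicon_class Named character vector mapping `reference_id` to
#'   `chromosome` / `megaplasmid` / `phage`.
#' @return An object of class `StrandBiasReport`: list with `per_category`
#'   (data frame: `category_type`, `category`, `weighting`, `n_targeting`,
#'   `n_nontargeting`, `fraction_targeting`) and `phage_fraction`
#'   (named numeric, weighted and unweighted).
#' @export
strand_bias_report <- function(clusters, replicon_class) {
  clusters$replicon <- unname(replicon_class[clusters$reference_id])
  genic_mask <- clusters$targeting != "intergenic"
  one_cat <- function(column, label) {
    values <- clusters[[column]]
    do.call(rbind, lapply(sort(unique(values[!is.na(values)])), function(v) {
      sub <- clusters[genic_mask & !is.na(values) & values == v, ,
                      drop = FALSE]
      tg <- sub$targeting == "targeting"
      data.frame(category_type = label, category = v,
                 weighting = c("weighted", "unweighted"),
                 n_targeting = c(sum(sub$read_count[tg]), sum(tg)),
                 n_nontargeting = c(sum(sub$read_count[!tg]), sum(!tg)),
                 stringsAsFactors = FALSE)
    }))
  }
  per <- rbind(one_cat("replicon", "replicon"),
               one_cat("temporal_class", "temporal_class"),
               one_cat("region", "region"))
  if (is.null(per)) {
    per <- data.frame(category_type = character(), category = character(),
                      weighting = character(), n_targeting = numeric(),
                      n_nontargeting = numeric(), stringsAsFactors = FALSE)
  }
  per$fraction_targeting <- frac_or_na(per$n_targeting,
                                       per$n_targeting + per$n_nontargeting)
  is_phage <- !is.na(clusters$replicon) & clusters$replicon == "phage"
  phage_fraction <- c(
    weighted = frac_or_na(sum(clusters$read_count[is_phage]),
                          sum(clusters$read_count)),
    unweighted = frac_or_na(sum(is_phage), nrow(clusters)))
  structure(list(per_category = per, phage_fraction = phage_fraction),
            class = "StrandBiasReport")
}

#' @export
print.StrandBiasReport <- function(x, ...) {
  cat("StrandBiasReport\n")
  cat(sprintf("  phage-derived fraction: %.3f weighted / %.3f unweighted\n",
              x$phage_fraction[["weighted"]], x$phage_fraction[["unweighted"]]))
  print(x$per_category)
  invisible(x)
}

#' Jaccard overlap of two spacer sets
#'
#' Number of shared spacers divided by the number of distinct spacers in
#' the combined sets. Symmetric; `NA` when both sets are empty.
#'
#' @param setA,setB Character vectors of spacer sequences (duplicates
#'   ignored).
#' @return Fraction in `[0, 1]`, or `NA`.
#' @export
jaccard_overlap <- function(setA, setB) {
  setA <- unique(setA); setB <- unique(setB)
  u <- length(union(setA, setB))
  if (u == 0L) return(NA_real_)
  length(intersect(setA, setB)) / u
}

#' Double-spacer selection analysis
#'
#' Quantifies reads whose amplified array region contains exactly two new
#' spacers and tests whether their genomic-region composition differs from
#' the single-spacer distribution (chi-square goodness of fit, no
#' continuity correction, df = number of regions - 1). Among double-read
#' spacers mapped to the `cold` region, the ordinal composition is reported
#' both ways: the fraction at ordinal 1 (leader-proximal, i.e. acquired
#' last) and the fraction at ordinal > 1.
#'
#' @param spacers Data frame with one row per mapped spacer: `read_id`,
#'   `ordinal`, `region` (region labels; `NA` rows are excluded from the
#'   test).
#' @param n_reads_total Total reads in the experiment (default: number of
#'   distinct `read_id`s in `spacers`).
#' @param single_dist Optional named expected proportions per region;
#'   default: the observed region distribution of single-spacer reads.
#' @return An object of class `DoubleSpacerStats`: `n_reads_total`,
#'   `n_reads_two_spacers`, `fraction_double`, `observed`, `expected`,
#'   `chi_square` (`statistic`, `df`, `p_value`),
#'   `leader_proximal_cold_fraction`, `distal_cold_fraction`.
#' @export
double_spacer_analysis <- function(spacers, n_reads_total = NULL,
                                   single_dist = NULL) {
  per_read <- table(spacers$read_id)
  if (is.null(n_reads_total)) n_reads_total <- length(per_read)
  doubles <- names(per_read)[per_read == 2L]
  singles <- names(per_read)[per_read == 1L]
  dbl <- spacers[spacers$read_id %in% doubles & !is.na(spacers$region), ,
                 drop = FALSE]
  if (is.null(single_dist)) {
    sg <- spacers[spacers$read_id %in% singles & !is.na(spacers$region), ,
                  drop = FALSE]
    if (!nrow(sg)) stop("no single-spacer reads to form the expected distribution")
    tab <- table(sg$region)
    single_dist <- as.numeric(tab) / sum(tab)
    names(single_dist) <- names(tab)
  }
  regions <- names(single_dist)
  obs <- as.numeric(table(factor(dbl$region, levels = regions)))
  names(obs) <- regions
  missing_region <- setdiff(unique(dbl$region), regions)
  if (length(missing_region)) {
    stop("observed double-read spacers in region(s) with zero expected ",
         "probability (", paste(missing_region, collapse = ", "),
         "); supply a single_dist covering them")
  }
  expected <- single_dist * sum(obs)
  if (any(expected == 0 & obs > 0)) {
    stop("expected count is 0 in a nonempty observed cell; ",
         "merge regions or supply a nonzero single_dist")
  }
  chi <- if (sum(obs) > 0) {
    suppressWarnings(chisq.test(obs, p = single_dist, correct = FALSE))
  } else NULL
  cold <- dbl[dbl$region == "cold", , drop = FALSE]
  structure(list(
    n_reads_total = n_reads_total,
    n_reads_two_spacers = length(doubles),
    fraction_double = frac_or_na(length(doubles), n_reads_total),
    observed = obs, expected = expected,
    chi_square = if (is.null(chi)) NULL else
      list(statistic = unname(chi$statistic), df = unname(chi$parameter),
           p_value = chi$p.value),
    leader_proximal_cold_fraction = frac_or_na(sum(cold$ordinal == 1L),
                                               nrow(cold)),
    distal_cold_fraction = frac_or_na(sum(cold$ordinal > 1L), nrow(cold))),
    class = "DoubleSpacerStats")
}

#' @export
print.DoubleSpacerStats <- function(x, ...) {
  cat(sprintf("DoubleSpacerStats: %d/%d reads with two spacers (%.3f%%)\n",
              x$n_reads_two_spacers, x$n_reads_total,
              100 * x$fraction_double))
  if (!is.null(x$chi_square)) {
    cat(sprintf("  chi-square = %.3f (df = %d), p = %.3g\n",
                x$chi_square$statistic, x$chi_square$df, x$chi_square$p_value))
  }
  cat(sprintf("  cold-region double-read spacers at ordinal 1: %.3f\n",
              x$leader_proximal_cold_fraction))
  invisible(x)
}

#' Position frequency matrix of protospacer flanks
#'
#' Builds a 4 x (2*flank + spacer_window) base-frequency matrix over the
#' upstream flank, the protospacer-proximal window, and the downstream
#' flank, oriented 5'->3' on the protospacer strand — the input for a
#' sequence logo and the check that Type III acquisition has no
#' PAM-like flank preference. Protospacers closer than `flank` to a
#' reference end are skipped and counted.
#'
#' @param clusters Cluster data frame (`reference_id`, `start`, `length`,
#'   `strand`, `read_count`).
#' @param references As in [classify_targeting()].
#' @param flank Flank width in bp (default 10).
#' @param spacer_window Protospacer-proximal bases included (default 10,
#'   capped at the shortest cluster length).
#' @param weighted Weight columns by read counts instead of one per
#'   cluster.
#' @return Object of class `FlankMatrix`: list with `freq` (4 x C matrix,
#'   columns sum to 1), `counts`, `n_used`, `n_skipped`, `flank`,
#'   `spacer_window`.
#' @export
flank_matrix <- function(clusters, references, flank = 10L,
                         spacer_window = 10L, weighted = FALSE) {
  if (!nrow(clusters)) stop("flank_matrix needs at least one cluster")
  if (inherits(references, "ReferenceGenome")) references <- list(references)
  names(references) <- vapply(references, `[[`, "", "id")
  spacer_window <- min(spacer_window, min(clusters$length))
  width <- 2L * flank + spacer_window
  counts <- matrix(0, nrow = 4L, ncol = width,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  n_used <- 0L; n_skipped <- 0L
  for (i in seq_len(nrow(clusters))) {
    ref <- references[[clusters$reference_id[i]]]
    if (is.null(ref)) { n_skipped <- n_skipped + 1L; next }
    s <- clusters$start[i]; len <- clusters$length[i]
    rl <- nchar(ref$sequence)
    if (s - flank < 0L || s + len + flank > rl) { n_skipped <- n_skipped + 1L; next }
    up <- substr(ref$sequence, s - flank + 1L, s)
    proto <- substr(ref$sequence, s + 1L, s + len)
    down <- substr(ref$sequence, s + len + 1L, s + len + flank)
    win <- if (clusters$strand[i] == "+") {
      paste0(up, substr(proto, 1L, spacer_window), down)
    } else {
      rc <- revcomp(paste0(up, proto, down))
      paste0(substr(rc, 1L, flank),
             substr(rc, flank + 1L, flank + spacer_window),
             substr(rc, nchar(rc) - flank + 1L, nchar(rc)))
    }
    ch <- strsplit(win, "", fixed = TRUE)[[1]]
    w <- if (weighted) clusters$read_count[i] else 1
    ok <- ch %in% rownames(counts)
    counts[cbind(match(ch[ok], rownames(counts)), which(ok))] <-
      counts[cbind(match(ch[ok], rownames(counts)), which(ok))] + w
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("all protospacers were skipped (too close to ends?)")
  freq <- sweep(counts, 2L, pmax(colSums(counts), 1), "/")
  structure(list(freq = freq, counts = counts, n_used = n_used,
                 n_skipped = n_skipped, flank = flank,
                 spacer_window = spacer_window),
            class = "FlankMatrix")
}

#' @export
print.FlankMatrix <- function(x, ...) {
  cat(sprintf("FlankMatrix: %d protospacers (%d skipped), flank %d bp, window %d bp\n",
              x$n_used, x$n_skipped, x$flank, x$spacer_window))
  invisible(x)
}
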