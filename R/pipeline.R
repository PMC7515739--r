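run_config_defaults <- function() {
  list(seed = 1L,
       n_reads = 10000L,
       n_replicates_adapt = 2L,
       selection_factor = 1,
       error_rate = 0.001,
       min_identity = 0.95,
       min_len = 20L,
       max_mismatch = 3L,
       max_spacers = 5L,
       flank = 10L,
       spacer_window = 10L,
       pseudocount = 1,
       normalization = "tpm",
       align_match = 1, align_mismatch = -2,
       align_gap_open = 6, align_gap_extend = 0.5,
       n_variants = 30L,
       escaper_n_reads = 2000L,
       log_level = "info",
       sim = list())
}

#' Build a pipeline run configuration
#'
#' All stage parameters in one validated list; unknown keys are rejected.
#' The `sim` entry is a list of overrides passed to [simulation_config()]
#' for simulated runs.
#'
#' @param ... Named overrides of the defaults (see
#'   `spaceracq:::run_config_defaults()`).
#' @return An object of class `RunConfig`.
#' @export
run_config <- function(...) {
  defaults <- run_config_defaults()
  dots <- list(...)
  if (length(dots) && is.null(names(dots))) stop("run_config arguments must be named")
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown)) {
    stop("unknown run_config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- modifyList(defaults, dots)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "RunConfig")
}

sim_config_for <- function(config, seed_offset = 0L) {
  args <- modifyList(
    list(seed = config$seed + seed_offset,
         n_reads = config$n_reads,
         selection_factor = config$selection_factor,
         error_rate = config$error_rate,
         n_variants = config$n_variants),
    config$sim)
  do.call(simulation_config, args)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_run_metadata <- function(config, outdir, extra = list()) {
  meta <- c(list(tool = "spaceracq",
                 version = as.character(utils::packageVersion("spaceracq")),
                 seed = config$seed,
                 config = unclass(config)), extra)
  jsonlite::write_json(meta, file.path(outdir, "run_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

log_msg <- function(config, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message("[spaceracq] ", ...)
}

#' Run the adaptation analysis end to end on simulated data
#'
#' Generates the phage/host genomes, array spec and amplicon reads for
#' `n_replicates_adapt` biological replicates, then chains spacer
#' extraction, filtering, mapping, clustering and the bias/selection
#' statistics, writing a deterministic report bundle (TSV/JSON/bedGraph
#' plus the resolved configuration) to `outdir`. Truth-table scores
#' (extraction recall/precision, mapping locus accuracy) are appended when
#' `score_truth` is set.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if needed).
#' @param score_truth Append recall/precision scoring against the
#'   generator's truth tables.
#' @return Invisible list with the per-replicate tables and reports.
#' @export
run_adaptation <- function(config = run_config(), outdir, score_truth = TRUE) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim0 <- sim_config_for(config)
  genome <- generate_phage_genome(sim0)
  host <- generate_host_genome(sim0)
  array <- generate_array_spec(sim0)
  nr <- nonredundant_reference(genome)
  refs <- list(nr, host)
  replicon_class <- setNames(c("phage", "chromosome"),
                             c(nr$id, host$id))

  write_fasta(list(genome, host), file.path(outdir, "references.fasta"))
  write_annotations(genome$features, file.path(outdir, "phage_genes.gff3"),
                    seqid = genome$id)
  write_array_spec(array, file.path(outdir, "array_spec.txt"))

  reps <- vector("list", config$n_replicates_adapt)
  manifest <- list()
  for (r in seq_len(config$n_replicates_adapt)) {
    sim <- sim_config_for(config, seed_offset = 1000L * (r - 1L))
    simdat <- simulate_adaptation_reads(genome, host, array, sim)
    write_fastq(simdat$reads, file.path(outdir, sprintf("reads_rep%d.fastq", r)))
    ex <- extract_readset(simdat$reads, array,
                          max_mismatch = config$max_mismatch,
                          max_spacers = config$max_spacers)
    new_sp <- filter_new_spacers(ex$candidates, array,
                                 min_len = config$min_len,
                                 min_identity = config$min_identity)
    mapped <- map_candidates(new_sp, refs, min_identity = config$min_identity)
    clusters <- dedupe_to_clusters(
      cbind(mapped[c("sequence", "reference_id", "start", "length",
                     "strand")], unique = TRUE))
    clusters <- classify_targeting(clusters, refs)
    write_tsv(new_sp, file.path(outdir, sprintf("candidates_rep%d.tsv", r)))
    write_tsv(mapped, file.path(outdir, sprintf("mapped_rep%d.tsv", r)))
    write_tsv(clusters, file.path(outdir, sprintf("clusters_rep%d.tsv", r)))
    profile <- positional_profile(clusters)
    write_profile_bedgraph(profile,
                           file.path(outdir, sprintf("profile_rep%d", r)))
    reps[[r]] <- list(sim = simdat, candidates = new_sp, mapped = mapped,
                      clusters = clusters, qc = ex$qc)
    manifest[[sprintf("rep%d", r)]] <- list(
      reads = length(simdat$reads),
      reads_with_repeats = unname(ex$qc[["reads_with_repeats"]]),
      candidates = nrow(ex$candidates),
      new_spacers = nrow(new_sp),
      mapped = nrow(mapped),
      clusters = nrow(clusters))
    log_msg(config, sprintf("replicate %d: %d reads -> %d new spacers -> %d clusters",
                            r, length(simdat$reads), nrow(new_sp), nrow(clusters)))
  }

  rep1 <- reps[[1]]
  mapped_regions <- classify_targeting(
    cbind(rep1$mapped[c("read_id", "ordinal", "sequence", "reference_id",
                        "start", "length", "strand")]), refs)
  bias <- strand_bias_report(rep1$clusters, replicon_class)
  write_tsv(bias$per_category, file.path(outdir, "strand_bias.tsv"))
  dbl <- double_spacer_analysis(
    mapped_regions[c("read_id", "ordinal", "region")],
    n_reads_total = length(rep1$sim$reads))
  fl <- flank_matrix(rep1$clusters[rep1$clusters$reference_id == nr$id, ,
                                   drop = FALSE],
                     refs, flank = config$flank,
                     spacer_window = config$spacer_window)
  write_tsv(as.data.frame(fl$freq), file.path(outdir, "flank_matrix.tsv"))

  jac <- NA_real_
  if (length(reps) >= 2L) {
    jac <- jaccard_overlap(reps[[1]]$candidates$sequence,
                           reps[[2]]$candidates$sequence)
  }

  scores <- NULL
  if (score_truth) {
    scores <- lapply(reps, function(rp) score_extraction(rp$sim, rp$candidates,
                                                         rp$mapped))
    names(scores) <- sprintf("rep%d", seq_along(reps))
  }

  report <- list(
    manifest = manifest,
    phage_fraction = as.list(bias$phage_fraction),
    double_spacer = list(
      fraction_double = dbl$fraction_double,
      chi_square = dbl$chi_square,
      leader_proximal_cold_fraction = dbl$leader_proximal_cold_fraction,
      distal_cold_fraction = dbl$distal_cold_fraction),
    jaccard_replicates = jac,
    flank_skipped = fl$n_skipped,
    truth_scores = scores)
  jsonlite::write_json(report, file.path(outdir, "adaptation_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  write_run_metadata(config, outdir, list(stage = "adaptation"))
  invisible(list(replicates = reps, bias = bias, double_spacer = dbl,
                 flanks = fl, jaccard = jac, report = report))
}

# Recall/precision of extracted spacers and mapping locus accuracy against
# the generator truth table.
score_extraction <- function(simdat, candidates, mapped) {
  truth <- simdat$truth
  if (!nrow(truth)) {
    return(list(recall = NA_real_, precision = NA_real_,
                locus_accuracy = NA_real_))
  }
  tkey <- paste(truth$read_id, truth$ordinal, truth$sequence)
  ckey <- paste(candidates$read_id, candidates$ordinal, candidates$sequence)
  recall <- mean(tkey %in% ckey)
  precision <- if (length(ckey)) mean(ckey %in% tkey) else NA_real_
  phage_truth <- truth[truth$source == "phage", , drop = FALSE]
  mkey <- paste(mapped$sequence, mapped$start, mapped$strand)
  pkey <- paste(phage_truth$sequence, phage_truth$start, phage_truth$strand)
  locus <- if (nrow(phage_truth)) {
    hit <- match(paste(mapped$read_id, mapped$ordinal),
                 paste(phage_truth$read_id, phage_truth$ordinal))
    ok <- !is.na(hit)
    if (any(ok)) mean(mkey[ok] == pkey[hit[ok]]) else NA_real_
  } else NA_real_
  list(recall = recall, precision = precision, locus_accuracy = locus)
}

#' Run the escaper deletion analysis end to end on simulated data
#'
#' Builds amplicons around an essential (early, frame-constrained) and a
#' non-essential gene protospacer, simulates escaper reads, then chains
#' primer filtering, dereplication, deletion calling and the spectrum
#' summary, writing a deterministic report bundle to `outdir`.
#'
#' @param config A [run_config()].
#' @param outdir Output directory.
#' @return Invisible list with both `DeletionSpectrum` objects and truth
#'   tables.
#' @export
run_escapers <- function(config = run_config(), outdir) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim0 <- sim_config_for(config)
  genome <- generate_phage_genome(sim0)
  out <- list()
  manifest <- list()
  setups <- list(
    essential = list(gene_class = "early", amp_len = 400L, offset = 7L),
    nonessential = list(gene_class = "middle", amp_len = 700L, offset = 8L))
  for (nm in names(setups)) {
    st <- setups[[nm]]
    gene <- genome$features[genome$features$temporal_class == st$gene_class, ][1, ]
    center <- (gene$start + gene$end) %/% 2L
    amp_start <- max(0L, center - st$amp_len %/% 2L)
    amplicon <- substr(genome$sequence, amp_start + 1L, amp_start + st$amp_len)
    ps <- c(st$amp_len %/% 2L - 19L, st$amp_len %/% 2L + 19L)
    sim <- sim_config_for(config, seed_offset = st$offset)
    sim$n_reads <- config$escaper_n_reads
    esc <- simulate_escaper_reads(amplicon, ps, essential = nm == "essential",
                                  config = sim)
    write_fastq(esc$reads, file.path(outdir, paste0("escaper_", nm, ".fastq")))
    filt <- filter_primer_anchored(esc$reads, esc$primer_fwd, esc$primer_rev)
    variants <- dereplicate(filt)
    spec <- deletion_spectrum(variants, esc$reference, ps,
                              match = config$align_match,
                              mismatch = config$align_mismatch,
                              gap_open = config$align_gap_open,
                              gap_extend = config$align_gap_extend)
    write_tsv(spec$variants, file.path(outdir, paste0("variants_", nm, ".tsv")))
    write_tsv(esc$truth, file.path(outdir, paste0("truth_", nm, ".tsv")))
    out[[nm]] <- list(spectrum = spec, truth = esc$truth,
                      reference = esc$reference, protospacer = ps)
    manifest[[nm]] <- list(
      reads = length(esc$reads),
      reads_primer_anchored = length(filt),
      dropped = attr(filt, "n_dropped"),
      variants = nrow(variants),
      frame_preserving_fraction_variants =
        spec$summary$frame_preserving_fraction_variants,
      wildtype_read_fraction = spec$summary$wildtype_read_fraction)
    log_msg(config, sprintf("%s: %d reads -> %d variants", nm,
                            length(esc$reads), nrow(variants)))
  }
  summaries <- lapply(out, function(x) {
    s <- x$spectrum$summary
    s$top_variants <- NULL
    s
  })
  jsonlite::write_json(list(manifest = manifest, summaries = summaries),
                       file.path(outdir, "escaper_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  write_run_metadata(config, outdir, list(stage = "escapers"))
  invisible(out)
}

#' Run the temporal-class analysis end to end on simulated data
#'
#' Simulates replicate expression count matrices from the phage genome's
#' implanted classes, recovers classes with [temporal_profiles()], and
#' writes the profile table, the row-normalised heatmap matrix, the
#' class-annotated GFF3 and a recovery summary.
#'
#' @param config A [run_config()].
#' @param outdir Output directory.
#' @return Invisible list with `profiles`, `truth` and `recovery`.
#' @export
run_temporal <- function(config = run_config(), outdir) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim0 <- sim_config_for(config)
  genome <- generate_phage_genome(sim0)
  simx <- simulate_expression_counts(genome, sim0)
  for (r in seq_along(simx$counts)) {
    write_tsv(data.frame(gene_id = rownames(simx$counts[[r]]),
                         length = simx$gene_lengths,
                         simx$counts[[r]], check.names = FALSE),
              file.path(outdir, sprintf("counts_rep%d.tsv", r)))
  }
  prof <- temporal_profiles(simx$counts, simx$gene_lengths,
                            mode = config$normalization,
                            pseudocount = config$pseudocount)
  write_tsv(as.data.frame(prof), file.path(outdir, "temporal_profiles.tsv"))
  hm <- heatmap_rows(prof)
  write_tsv(data.frame(gene_id = rownames(hm), hm, check.names = FALSE),
            file.path(outdir, "heatmap_rows.tsv"))
  feats <- apply_temporal_classes(genome$features, prof)
  write_annotations(feats, file.path(outdir, "phage_genes_classified.gff3"),
                    seqid = genome$id)
  recovery <- mean(prof$class == simx$truth[prof$gene_id])
  jsonlite::write_json(list(class_recovery = recovery,
                            n_genes = nrow(prof)),
                       file.path(outdir, "temporal_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  write_run_metadata(config, outdir, list(stage = "temporal"))
  invisible(list(profiles = prof, truth = simx$truth, recovery = recovery))
}

#' Run every stage of the pipeline
#'
#' Chains [run_adaptation()], [run_temporal()] and [run_escapers()] into
#' subdirectories of `outdir`. With a fixed seed the whole bundle is
#' byte-identical across reruns.
#'
#' @param config A [run_config()].
#' @param outdir Output directory.
#' @return Invisible list of the three stage results.
#' @export
run_all <- function(config = run_config(), outdir) {
  res <- list(
    adaptation = run_adaptation(config, file.path(outdir, "adaptation")),
    temporal = run_temporal(config, file.path(outdir, "temporal")),
    escapers = run_escapers(config, file.path(outdir, "escapers")))
  write_run_metadata(config, outdir, list(stage = "all"))
  invisible(res)
}
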