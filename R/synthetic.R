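#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators. Defaults encode
#' the study conditions the package models: a 6639 bp long terminal repeat
#' (LTR) carrying the early genes, newly acquired spacers of 35-42 bp,
#' about 3.2% of amplicon reads carrying two new spacers, and a minority
#' (5%) of host-derived spacers.
#'
#' @param seed Integer seed; a fixed seed makes every generator
#'   deterministic.
#' @param ltr_length LTR length in bp (default 6639).
#' @param genome_length Phage genome length in bp including both LTR copies.
#' @param n_genes Named integer vector `c(early=, middle=, late=)`.
#' @param selection_factor Abundance multiplier `s >= 1` for protective
#'   spacers (selection modelled as clonal amplification after acquisition,
#'   not biased acquisition): a clone's sampling weight is the mean of its
#'   per-spacer multipliers, `s` for each protective spacer and 1 otherwise.
#' @param error_rate Per-base substitution error rate in `[0, 0.05]`.
#' @param n_reads Number of amplicon reads to emit.
#' @param spacer_length_range Length-2 vector, new-spacer lengths in bp
#'   (uniform; default `c(35, 42)`).
#' @param p_zero,p_double,p_multi Probabilities that a read carries 0 or 2
#'   new spacers, and total probability of 3-5 spacers (split equally);
#'   the single-spacer probability is the remainder.
#' @param host_fraction Fraction of new spacers drawn from the host genome.
#' @param protective_model `"ltr"`: a spacer protects only if it targets a
#'   transcript of an LTR ("hot" region) gene; `"any_gene"`: any
#'   transcript-targeting spacer protects.
#' @param timepoints Sampling times (minutes post-infection) for the
#'   expression simulator.
#' @param n_replicates Biological replicates for the expression simulator.
#' @param nb_size Negative-binomial size (inverse dispersion) of count noise.
#' @param base_mean_log,base_sd_log Log-normal parameters of per-gene base
#'   expression.
#' @param wt_fraction Fraction of wild-type reads in escaper amplicons.
#' @param n_variants Distinct deletion variants per escaper simulation.
#' @param del_len_range Deletion lengths (bp) for a non-essential gene
#'   (uniform over the range). For an essential gene, lengths are the
#'   multiples of 3 within the same range.
#' @param primer_len Primer length used by the escaper amplicon simulator.
#' @return An object of class `SimulationConfig`.
#' @export
simulation_config <- function(seed = 1L,
                              ltr_length = 6639L,
                              genome_length = 38000L,
                              n_genes = c(early = 10L, middle = 10L, late = 10L),
                              selection_factor = 1,
                              error_rate = 0.001,
                              n_reads = 10000L,
                              spacer_length_range = c(35L, 42L),
                              p_zero = 0.01, p_double = 0.032, p_multi = 0.006,
                              host_fraction = 0.05,
                              protective_model = c("ltr", "any_gene"),
                              timepoints = c(0, 10, 30, 50, 70),
                              n_replicates = 2L,
                              nb_size = 10,
                              base_mean_log = log(500), base_sd_log = 1,
                              wt_fraction = 0.5,
                              n_variants = 30L,
                              del_len_range = c(1L, 300L),
                              primer_len = 20L) {
  protective_model <- match.arg(protective_model)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  if (error_rate < 0 || error_rate > 0.05) stop("error_rate must be in [0, 0.05]")
  if (selection_factor < 1) stop("selection_factor must be >= 1")
  if (spacer_length_range[1] < 20L) stop("minimum spacer length must be >= 20")
  if (ltr_length < 0L) stop("ltr_length must be >= 0")
  if (p_zero + p_double + p_multi >= 1) stop("spacer multiplicity probabilities exceed 1")
  stopifnot(all(c("early", "middle", "late") %in% names(n_genes)))
  structure(list(seed = seed, ltr_length = as.integer(ltr_length),
                 genome_length = as.integer(genome_length), n_genes = n_genes,
                 selection_factor = selection_factor, error_rate = error_rate,
                 n_reads = as.integer(n_reads),
                 spacer_length_range = as.integer(spacer_length_range),
                 p_zero = p_zero, p_double = p_double, p_multi = p_multi,
                 host_fraction = host_fraction,
                 protective_model = protective_model,
                 timepoints = timepoints,
                 n_replicates = as.integer(n_replicates), nb_size = nb_size,
                 base_mean_log = base_mean_log, base_sd_log = base_sd_log,
                 wt_fraction = wt_fraction, n_variants = as.integer(n_variants),
                 del_len_range = as.integer(del_len_range),
                 primer_len = as.integer(primer_len)),
            class = "SimulationConfig")
}

random_dna <- function(n) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Apply iid substitution errors at rate eps to a character vector of reads.
mutate_seqs <- function(seqs, eps) {
  if (eps <= 0 || !length(seqs)) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    k <- rbinom(1L, n, eps)
    if (k == 0L) return(s)
    pos <- sample.int(n, k)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    for (p in pos) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    }
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

# Tile n genes of random sizes into [lo, hi); returns start/end vectors or
# NULL if they do not fit.
tile_genes <- function(n, lo, hi, len_range = c(300L, 700L), gap_range = c(20L, 80L)) {
  if (n == 0L) return(data.frame(start = integer(), end = integer()))
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  gaps <- sample(gap_range[1]:gap_range[2], n, replace = TRUE)
  starts <- lo + cumsum(c(0L, (lens + gaps)[-n])) + gaps[1]
  ends <- starts + lens
  if (ends[n] > hi) return(NULL)
  data.frame(start = as.integer(starts), end = as.integer(ends))
}

#' Generate an LTR-bearing phage genome
#'
#' Emulates a phage whose genome carries identical long terminal repeats:
#' the first and last `ltr_length` bp are byte-identical, the LTR houses the
#' early genes (the spacer-acquisition "hot" region), and middle and late
#' gene blocks lie in the unique internal portion ("cold" region). The
#' packaging start coordinate (0: the virion genome begins at the LTR) is
#' stored as metadata.
#'
#' @param config A [simulation_config()].
#' @return A [reference_genome()] with regions `LTR_left`, `LTR_right`,
#'   `hot` and `cold`.
#' @export
generate_phage_genome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  L <- config$ltr_length; G <- config$genome_length
  if (L >= G / 2) stop("ltr_length must be smaller than genome_length/2")
  set.seed(config$seed)
  core <- random_dna(G - L)
  sequence <- paste0(core, substr(core, 1L, L))

  ng <- config$n_genes
  early <- tile_genes(ng[["early"]], 50L, L - 50L)
  if (is.null(early)) stop("infeasible gene packing: early genes do not fit the LTR")
  mid_lo <- L + 100L; mid_hi <- G - L - 100L
  middle <- tile_genes(ng[["middle"]], mid_lo, mid_hi)
  if (is.null(middle)) stop("infeasible gene packing: middle genes do not fit")
  late <- tile_genes(ng[["late"]], if (nrow(middle)) max(middle$end) + 100L else mid_lo,
                     mid_hi)
  if (is.null(late)) stop("infeasible gene packing: late genes do not fit")

  block_df <- function(df, cls) {
    if (!nrow(df)) return(NULL)
    cbind(df, temporal_class = cls)
  }
  blocks <- rbind(block_df(early, "early"), block_df(middle, "middle"),
                  block_df(late, "late"))
  if (is.null(blocks)) stop("at least one gene is required")
  n <- nrow(blocks)
  features <- data.frame(gene_id = sprintf("gene_%02d", seq_len(n)),
                         start = blocks$start, end = blocks$end,
                         strand = sample(c("+", "-"), n, replace = TRUE),
                         temporal_class = blocks$temporal_class,
                         essential = blocks$temporal_class == "early",
                         stringsAsFactors = FALSE)
  regions <- if (L > 0L) {
    list(LTR_left = c(0L, L), LTR_right = c(G - L, G),
         hot = c(0L, L), cold = c(L, G - L))
  } else {
    list(hot = c(0L, 0L), cold = c(0L, G))
  }
  reference_genome(id = "phage_sim", sequence = sequence,
                   topology = "linear", features = features,
                   regions = regions, metadata = list(packaging_start = 0L))
}

#' Drop the redundant right LTR copy for mapping
#'
#' A spacer acquired from the LTR matches both terminal copies of the
#' repeat, so against the full virion genome it can never be uniquely
#' mapped. Mapping is therefore done against the non-redundant genome
#' `[0, G - ltr_length)`, which contains each phage position exactly once.
#'
#' @param genome A phage [reference_genome()] with an `LTR_right` region.
#' @return A `ReferenceGenome` truncated before the right LTR copy.
#' @export
nonredundant_reference <- function(genome) {
  rr <- genome$regions$LTR_right
  if (is.null(rr)) return(genome)
  cut <- rr[1]
  feats <- genome$features[genome$features$end <= cut, , drop = FALSE]
  regions <- genome$regions[setdiff(names(genome$regions), "LTR_right")]
  regions <- lapply(regions, function(iv) pmin(iv, cut))
  reference_genome(id = genome$id, sequence = substr(genome$sequence, 1L, cut),
                   topology = genome$topology, features = feats,
                   regions = regions, metadata = genome$metadata)
}

#' Generate a CRISPR array spec matching the simulator's amplicon design
#'
#' Random repeat (36 bp), leader (60 bp) and one pre-existing
#' leader-proximal spacer (38 bp); the forward primer is the first 20 bp of
#' the leader and the reverse primer anneals to the 3' end of the
#' leader-proximal spacer.
#'
#' @param config A [simulation_config()].
#' @return A [crispr_array_spec()].
#' @export
generate_array_spec <- function(config) {
  set.seed(config$seed + 101L)
  repeat_seq <- random_dna(36L)
  leader <- random_dna(60L)
  spacer1 <- random_dna(38L)
  crispr_array_spec(array_id = "array_sim", repeat_seq = repeat_seq,
                    spacers = spacer1, leader = leader,
                    primer_fwd = substr(leader, 1L, 20L),
                    primer_rev = revcomp(substr(spacer1, 19L, 38L)))
}

# Majority-overlap gene lookup used by both the generator and the stats
# module: index of the feature with the largest overlap (ties -> smaller
# start), or NA when no feature overlaps.
majority_gene_index <- function(start, end, features) {
  if (!nrow(features)) return(NA_integer_)
  ov <- iv_overlap(start, end, features$start, features$end)
  if (!any(ov > 0L)) return(NA_integer_)
  cand <- which(ov == max(ov))
  cand[which.min(features$start[cand])]
}

#' Simulate expanded-array amplicon reads with a selection model
#'
#' Each read is `leader + k x (repeat + new spacer) + repeat +
#' leader-proximal old spacer`, k in 0..5. New spacers are drawn uniformly
#' from the non-redundant phage genome (majority) and the host (minority).
#' A spacer is *protective* iff it is transcript-targeting (spacer matches
#' the gene's template strand) and its protospacer lies in the protective
#' region (the LTR under the `"ltr"` model, any gene under `"any_gene"`).
#' Selection acts as clonal amplification: each spacer carries multiplier
#' `selection_factor` when protective and 1 otherwise, and a clone's
#' sampling weight is the mean multiplier over its spacers. Within a clone,
#' protective spacers are acquired first and therefore end up
#' leader-distal; the most recent acquisition has ordinal 1. Substitution
#' errors are applied at `error_rate`.
#'
#' @param genome Phage [reference_genome()] from [generate_phage_genome()].
#' @param host Host `ReferenceGenome` (chromosome or megaplasmid model).
#' @param array A [crispr_array_spec()] whose primers flank the
#'   leader-proximal region.
#' @param config A [simulation_config()].
#' @return List with `reads` (a [read_set()]) and `truth`, a data frame with
#'   one row per implanted spacer: `read_id`, `clone_id`, `ordinal` (1 =
#'   leader-proximal), `source` (`"phage"`/`"host"`), `start` (0-based on
#'   the non-redundant source), `strand`, `length`, `sequence` (error-free),
#'   `targeting`, `region` (`hot`/`cold`/`NA`), `protective`.
#' @export
simulate_adaptation_reads <- function(genome, host, array, config) {
  stopifnot(inherits(config, "SimulationConfig"),
            inherits(array, "CRISPRArraySpec"))
  if (!grepl(array$primers[["fwd"]], array$leader, fixed = TRUE)) {
    stop("forward primer does not anneal to the leader")
  }
  if (!length(array$spacers) ||
      !grepl(revcomp(array$primers[["rev"]]), array$spacers[1], fixed = TRUE)) {
    stop("reverse primer does not anneal to the leader-proximal spacer")
  }
  set.seed(config$seed + 1L)

  nr_phage <- nonredundant_reference(genome)
  phage_len <- nchar(nr_phage$sequence)
  host_len <- nchar(host$sequence)
  hot <- nr_phage$regions$hot
  lr <- config$spacer_length_range
  if (lr[2] >= phage_len || lr[2] >= host_len) {
    stop("spacer length exceeds reference capacity")
  }

  n_clones <- config$n_reads
  k_probs <- c(config$p_zero,
               1 - config$p_zero - config$p_double - config$p_multi,
               config$p_double, rep(config$p_multi / 3, 3))
  k <- sample(0:5, n_clones, replace = TRUE, prob = k_probs)

  total <- sum(k)
  src_phage <- runif(total) >= config$host_fraction
  len <- sample(lr[1]:lr[2], total, replace = TRUE)
  strand <- sample(c("+", "-"), total, replace = TRUE)
  max_start <- ifelse(src_phage, phage_len, host_len) - len
  start <- floor(runif(total) * (max_start + 1))

  seqs <- character(total)
  idx_p <- which(src_phage); idx_h <- which(!src_phage)
  seqs[idx_p] <- substring(nr_phage$sequence, start[idx_p] + 1L,
                           start[idx_p] + len[idx_p])
  seqs[idx_h] <- substring(host$sequence, start[idx_h] + 1L,
                           start[idx_h] + len[idx_h])
  neg <- strand == "-"
  seqs[neg] <- revcomp(seqs[neg])

  feats <- nr_phage$features
  gi <- rep(NA_integer_, total)
  gi[idx_p] <- vapply(idx_p, function(i)
    majority_gene_index(start[i], start[i] + len[i], feats), 0L)
  targeting <- !is.na(gi) & strand != feats$strand[ifelse(is.na(gi), 1L, gi)]
  in_hot <- src_phage &
    iv_overlap(start, start + len, hot[1], hot[2]) * 2L > len
  region <- ifelse(!src_phage, NA_character_, ifelse(in_hot, "hot", "cold"))
  protective <- switch(config$protective_model,
                       ltr = targeting & in_hot,
                       any_gene = targeting & src_phage)

  clone_id <- rep(seq_len(n_clones), k)
  # acquisition order: protective spacers first (leader-distal); ordinal 1 is
  # the most recent unit, adjacent to the leader
  ord <- integer(total)
  sp_clones <- vector("list", n_clones)
  by_clone <- split(seq_len(total), clone_id)
  sp_clones[as.integer(names(by_clone))] <- by_clone
  for (ix in by_clone) {
    o <- order(!protective[ix], seq_along(ix))  # protective acquired first
    ord[ix[o]] <- rev(seq_along(ix))
  }

  # clone weight = average per-spacer multiplier: a spacer contributes s
  # when protective, 1 otherwise. Bounded by s, so no single multi-spacer
  # clone can swamp the read pool.
  n_prot <- tabulate(clone_id[protective], nbins = n_clones)
  w <- rep(1, n_clones)
  has_k <- k > 0L
  w[has_k] <- 1 + (config$selection_factor - 1) * n_prot[has_k] / k[has_k]
  picked <- sample.int(n_clones, config$n_reads, replace = TRUE, prob = w)

  # assemble one amplicon per clone (units leader-first, ordinal 1 innermost)
  clone_body <- vapply(sp_clones, function(ix) {
    if (is.null(ix) || !length(ix)) return("")
    paste0(array$repeat_seq, seqs[ix[order(ord[ix])]], collapse = "")
  }, "")
  amplicon <- paste0(array$leader, clone_body, array$repeat_seq,
                     array$spacers[1])
  read_seq <- mutate_seqs(amplicon[picked], config$error_rate)
  read_ids <- sprintf("read_%06d", seq_along(picked))

  sel <- sp_clones[picked]
  nper <- lengths(sel)
  ixs <- unlist(sel, use.names = FALSE)
  truth <- if (length(ixs)) {
    data.frame(read_id = rep(read_ids, nper),
               clone_id = rep(picked, nper),
               ordinal = ord[ixs],
               source = ifelse(src_phage[ixs], "phage", "host"),
               start = start[ixs], strand = strand[ixs], length = len[ixs],
               sequence = seqs[ixs], targeting = targeting[ixs],
               region = region[ixs], protective = protective[ixs],
               stringsAsFactors = FALSE)
  } else data.frame()
  list(reads = read_set(read_ids, read_seq, pairing = "merged"),
       truth = truth)
}

#' Simulate phage gene expression count matrices over an infection
#'
#' Implants class-specific transcript-abundance trajectories: early genes
#' peak before 30 min then decline, middle genes peak at 30-50 min, late
#' genes keep rising after 50 min. Counts are negative-binomial around the
#' implanted means; two biological replicates by default.
#'
#' @param genome Phage [reference_genome()]; every feature must carry a
#'   temporal class.
#' @param config A [simulation_config()].
#' @param include_uninfected Add an all-zero `uninfected` control column
#'   (phage genes are absent before infection).
#' @return List with `counts` (list of genes x timepoints integer matrices,
#'   one per replicate), `gene_lengths`, `timepoints` and `truth` (named
#'   character vector of implanted classes).
#' @export
simulate_expression_counts <- function(genome, config, include_uninfected = FALSE) {
  stopifnot(inherits(config, "SimulationConfig"))
  feats <- genome$features
  if (!nrow(feats)) stop("genome has no gene features")
  if (any(feats$temporal_class == "unassigned")) {
    stop("every gene needs a temporal_class for expression simulation")
  }
  set.seed(config$seed + 2L)
  tp <- config$timepoints
  shapes <- list(
    early  = stats::approx(c(0, 10, 30, 50, 70), c(0.30, 1, 0.8, 0.3, 0.10), xout = tp)$y,
    middle = stats::approx(c(0, 10, 30, 50, 70), c(0.05, 0.15, 0.5, 1, 0.4), xout = tp)$y,
    late   = stats::approx(c(0, 10, 30, 50, 70), c(0.02, 0.05, 0.15, 0.4, 1), xout = tp)$y)
  base <- rlnorm(nrow(feats), config$base_mean_log, config$base_sd_log)
  mu <- t(vapply(seq_len(nrow(feats)),
                 function(i) base[i] * shapes[[feats$temporal_class[i]]],
                 numeric(length(tp))))
  dimnames(mu) <- list(feats$gene_id, paste0("t", tp))
  counts <- lapply(seq_len(config$n_replicates), function(r) {
    m <- matrix(rnbinom(length(mu), mu = as.numeric(mu), size = config$nb_size),
                nrow = nrow(mu), dimnames = dimnames(mu))
    if (include_uninfected) m <- cbind(uninfected = 0L, m)
    m
  })
  list(counts = counts,
       gene_lengths = setNames(feats$end - feats$start, feats$gene_id),
       timepoints = tp,
       truth = setNames(feats$temporal_class, feats$gene_id))
}

#' Simulate escaper-phage amplicon reads with implanted deletions
#'
#' Roughly half of the reads are wild type; the rest carry one deletion
#' overlapping the targeted protospacer. For an essential gene, deletion
#' lengths are multiples of 3 (frame-preserving); for a non-essential gene
#' they are uniform over `del_len_range`. Both primers (taken as the
#' terminal `primer_len` bases of the amplicon) are present on every read.
#'
#' @param amplicon_ref Reference amplicon sequence (character).
#' @param protospacer Length-2 vector `c(start, end)`, 0-based half-open,
#'   inside the amplicon.
#' @param essential Logical: restrict deletions to frame-preserving lengths.
#' @param config A [simulation_config()].
#' @return List with `reads` (a [read_set()]), `reference` (the amplicon),
#'   `primer_fwd`/`primer_rev`, and `truth`: one row per variant with
#'   `variant_id`, `start`, `length`, `frame_preserving`, `n_reads`.
#' @export
simulate_escaper_reads <- function(amplicon_ref, protospacer, essential, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  amplicon_ref <- toupper(amplicon_ref)
  n <- nchar(amplicon_ref)
  P <- config$primer_len
  ps <- as.integer(protospacer)
  if (ps[1] < 0L || ps[2] > n || ps[1] >= ps[2]) {
    stop("protospacer interval must lie inside the amplicon")
  }
  lens_all <- config$del_len_range[1]:config$del_len_range[2]
  if (essential) lens_all <- lens_all[lens_all %% 3L == 0L]
  if (!length(lens_all)) stop("no admissible deletion lengths in del_len_range")
  if (max(lens_all) > n - 2L * P) {
    stop("deletion length exceeds amplicon minus primers")
  }
  set.seed(config$seed + 3L)

  pick_variant <- function() {
    len <- sample(lens_all, 1L)
    lo <- max(P, ps[1] - len + 1L)
    hi <- min(n - P - len, ps[2] - 1L)
    if (hi < lo) return(NULL)
    c(start = sample(lo:hi, 1L), length = len)
  }
  seen <- character(); vars <- list()
  guard <- 0L
  while (length(vars) < config$n_variants && guard < 50L * config$n_variants) {
    guard <- guard + 1L
    v <- pick_variant()
    if (is.null(v)) next
    key <- paste(v, collapse = "_")
    if (key %in% seen) next
    seen <- c(seen, key); vars[[length(vars) + 1L]] <- v
  }
  if (length(vars) < config$n_variants) {
    stop("could not place ", config$n_variants,
         " distinct deletions overlapping the protospacer")
  }
  vt <- do.call(rbind, vars)
  variant_seq <- vapply(seq_len(nrow(vt)), function(i) {
    paste0(substr(amplicon_ref, 1L, vt[i, "start"]),
           substr(amplicon_ref, vt[i, "start"] + vt[i, "length"] + 1L, n))
  }, "")

  n_wt <- round(config$n_reads * config$wt_fraction)
  assign <- c(rep(0L, n_wt),
              sample(rep_len(seq_len(nrow(vt)), config$n_reads - n_wt)))
  seqs <- ifelse(assign == 0L, amplicon_ref, variant_seq[pmax(assign, 1L)])
  seqs <- mutate_seqs(seqs, config$error_rate)
  ids <- sprintf("esc_%06d", seq_along(seqs))
  truth <- data.frame(variant_id = sprintf("var_%03d", seq_len(nrow(vt))),
                      start = as.integer(vt[, "start"]),
                      length = as.integer(vt[, "length"]),
                      frame_preserving = vt[, "length"] %% 3L == 0L,
                      n_reads = as.integer(tabulate(assign, nbins = nrow(vt))),
                      stringsAsFactors = FALSE)
  list(reads = read_set(ids, seqs, pairing = "merged"),
       reference = amplicon_ref,
       primer_fwd = substr(amplicon_ref, 1L, P),
       primer_rev = revcomp(substr(amplicon_ref, n - P + 1L, n)),
       truth = truth)
}

#' Generate a featureless host replicon model
#'
#' Random sequence with sparsely tiled genes, used as the chromosome or
#' megaplasmid source of the minority host-derived spacers.
#'
#' @param config A [simulation_config()].
#' @param id Replicon id.
#' @param length Sequence length in bp.
#' @param n_genes Number of genes to tile.
#' @return A [reference_genome()].
#' @export
generate_host_genome <- function(config, id = "host_chromosome",
                                 length = 20000L, n_genes = 10L) {
  set.seed(config$seed + 4L + sum(utf8ToInt(id)) %% 1000L)
  genes <- tile_genes(n_genes, 100L, length - 100L,
                      len_range = c(400L, 900L), gap_range = c(200L, 1200L))
  if (is.null(genes)) stop("infeasible gene packing for host genome")
  feats <- data.frame(gene_id = sprintf("%s_g%02d", id, seq_len(nrow(genes))),
                      start = genes$start, end = genes$end,
                      strand = sample(c("+", "-"), nrow(genes), replace = TRUE),
                      stringsAsFactors = FALSE)
  reference_genome(id = id, sequence = random_dna(length),
                   topology = "circular", features = feats)
}
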