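# spaceracq

Analysis of Type III CRISPR–Cas spacer acquisition and phage escape from
amplicon sequencing.

During phage infection, bacteria with Type III CRISPR–Cas systems acquire
new spacers into their arrays. Because Type III interference is
transcription-dependent, only *transcript-targeting* spacers — those whose
crRNA base-pairs with a phage mRNA — protect the cell, and protected clones
outgrow the culture. `spaceracq` is for researchers who sequence expanded
CRISPR arrays (leader-anchored amplicons), phage transcriptomes and
escaper-phage protospacer regions, and want the acquisition, selection and
escape statistics computed reproducibly:

- **Spacer extraction** — CRISPR repeats are found in merged amplicon reads
  by Hamming matching in both orientations; the sequences between
  consecutive repeats are the newly acquired spacers, ordinal 1 being
  leader-proximal. Candidates shorter than 20 bp or matching a
  pre-existing array spacer are removed.
- **Protospacer mapping** — ungapped mapping to phage and host replicons at
  ≥95% identity (matches / spacer length), keeping only spacers with
  exactly one passing locus across all references; hits are clustered by
  (start, length, strand) and combined into strand-split positional
  profiles.
- **Bias statistics** — transcript-targeting fractions per replicon,
  temporal class and genome region, both read-weighted ("all spacers") and
  unweighted ("unique spacers"); replicate overlap as the Jaccard index
  |A∩B| / |A∪B|; a chi-square goodness-of-fit test for the region
  composition of reads carrying two new spacers against the single-spacer
  expectation; and a flank position-frequency matrix (the PAM check).
- **Temporal classes** — TPM/CPM normalisation, `LogFC_XvsY = log10 A(Y) −
  log10 A(X)`, and the rules *early*: `LogFC_30vs50 < 0`; *middle*:
  `LogFC_30vs50 > 0` and `LogFC_50vs70 < 0`; *late*: `LogFC_50vs70 > 0`,
  applied in that order over replicate-averaged abundances.
- **Escaper spectra** — primer-anchored filtering, exact dereplication,
  deletion calling by global affine-gap alignment (match +1, mismatch −2,
  gap open −6, gap extend −0.5; leftmost placement in repeats), and
  reading-frame summaries (a variant is frame-preserving when its total
  deleted length is a multiple of 3).
- **Synthetic data** — a generator that emulates every input at study
  conditions (an LTR-bearing phage genome with early/middle/late gene
  blocks, expanded-array amplicons under a tunable selection model,
  negative-binomial expression counts, escaper amplicons with implanted
  deletions) together with truth tables that score every stage.

See `vignettes/spacer-acquisition-methods.Rmd` for the models, parameter
choices and limitations.

## Worked example

Simulate an infection with moderate selection (`s = 20`) and run the
adaptation analysis:

```r
library(spaceracq)

cfg    <- simulation_config(seed = 42, n_reads = 2000, selection_factor = 20)
genome <- generate_phage_genome(cfg)
host   <- generate_host_genome(cfg)
array  <- generate_array_spec(cfg)
sim    <- simulate_adaptation_reads(genome, host, array, cfg)

refs   <- list(nonredundant_reference(genome), host)
ex     <- extract_readset(sim$reads, array)
new_sp <- filter_new_spacers(ex$candidates, array)
mapped <- map_candidates(new_sp, refs)

clusters <- dedupe_to_clusters(
  cbind(mapped[c("sequence", "reference_id", "start", "length", "strand")],
        unique = TRUE))
clusters <- classify_targeting(clusters, refs)
bias <- strand_bias_report(clusters,
                           setNames(c("phage", "chromosome"),
                                    c(genome$id, host$id)))
per <- bias$per_category
per[per$category_type == "region", ]
```

```
 category_type category  weighting n_targeting n_nontargeting fraction_targeting
        region     cold   weighted         139            139          0.5000000
        region     cold unweighted         113            105          0.5183486
        region      hot   weighted        1325             56          0.9594497
        region      hot unweighted         177             46          0.7937220
```

Selection leaves the cold region at the 50/50 null while read weight piles
onto transcript-targeting protospacers in the hot region (the LTR) — the
signature that the positional/strand bias is selection-driven rather than
an acquisition preference. Reads with two new spacers show the
complementary signature:

```r
dbl <- double_spacer_analysis(
  classify_targeting(mapped, refs)[c("read_id", "ordinal", "region")],
  n_reads_total = length(sim$reads))
dbl
```

```
DoubleSpacerStats: 73/2000 reads with two spacers (3.650%)
  chi-square = 18.216 (df = 1), p = 1.97e-05
  cold-region double-read spacers at ordinal 1: 0.763
```

Cold-region spacers in double-spacer reads are enriched relative to the
single-spacer distribution and sit mostly at the leader-proximal position,
i.e. they were acquired *after* a protective hot-region spacer.
`run_adaptation()`, `run_temporal()`, `run_escapers()` and `run_all()`
chain the stages and write deterministic TSV/JSON/bedGraph report bundles;
`inst/scripts/spaceracq-cli.R` exposes them as shell subcommands.

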