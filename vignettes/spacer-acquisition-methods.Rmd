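---
title: "Methods: spacer acquisition, temporal classes and escaper spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spacer acquisition, temporal classes and escaper spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spaceracq)
```

# Scope

`spaceracq` analyses Type III CRISPR–Cas spacer acquisition during phage
infection from expanded-array amplicon sequencing, classifies phage genes
into temporal expression classes, and characterises the deletion spectra of
CRISPR-escaper phages. Because Type III interference is
transcription-dependent, the central quantity throughout is whether an
acquired spacer is *transcript-targeting*: whether its crRNA can base-pair
with an mRNA of the phage.

This vignette explains the models and the procedures, the parameters that
matter, what the synthetic-data generator does and does not emulate, and the
numerical choices made where the design was genuinely open. It states no
empirical result that the package's tests and acceptance script do not
themselves compute.

# Coordinate and strand conventions

All internal coordinates are 0-based half-open intervals on the top strand
of the stored reference; GFF3's 1-based closed convention is converted at
I/O only. A mapping hit on strand `+` means the spacer sequence matches the
stored top strand.

**Targeting convention.** A protospacer is called *targeting* when the
spacer sequence equals the gene's template (transcribed) strand, so the
crRNA is complementary to the mRNA: a gene annotated on `+` is targeted by
hits on `-`, and vice versa. Descriptions of strandedness in this assay are
easy to invert ("targeting the non-transcribed strand" of a gene is the
configuration that targets the mRNA), so every report states the convention
rather than relying on parallel/antiparallel vocabulary. Protospacers
spanning two genes are assigned by majority overlap; an exact tie goes to
the gene with the smaller start, which keeps the assignment deterministic.

# Spacer extraction

Amplicons of expanded arrays are sequenced from the leader side: each read
is `leader + k × (repeat + new spacer) + repeat + old leader-proximal
spacer`. Repeats are detected in both orientations by Hamming matching with
`max_mismatch = 3` by default (~8% of a 36 bp repeat; the tolerance is a
knob because sequencing chemistry and repeat conservation vary). Overlapping
occurrences are resolved greedily left to right, which is deterministic and,
after canonicalisation, orientation-invariant. Reads whose repeat hits fall
on both strands are skipped and counted; terminal partial repeats do not
delimit spacers (conservative: avoids chimeric candidates). Candidates are
the gaps between consecutive repeats, ordinal 1 being leader-proximal (the
most recent acquisition); at most five spacers are taken per read.

Candidates shorter than 20 bp, and candidates matching a pre-existing array
spacer at the mapping identity threshold in either orientation, are removed
so that only newly acquired spacers remain.

# Mapping and clustering

Spacers are mapped ungapped to every reference (phage plus host replicons)
on both strands at `min_identity = 0.95`, computed as matches divided by
spacer length. For 35–42 bp spacers this threshold admits at most
`floor(0.05·len)` mismatches — 1 for a 36-mer (34/36 = 0.944 is rejected), 2
for a 40-mer. Ungapped identity over the full spacer length is the natural
reading for spacers this short; the denominator choice is recorded in
output metadata. "Uniquely mapped" means exactly one passing locus across
*all* references jointly, so a spacer matching both phage and host is
dropped rather than double-counted, and ties at equal identity are not
broken.

Unique hits are clustered by `(reference, start, length, strand)` with read
counts and distinct-sequence counts accumulated; clusters sharing
`(start, strand)` are combined into a positional profile for visualisation
(exported as strand-split bedGraph).

The bulk mapper seeds with a constant-width prefix dictionary matched once
per reference and strand at the loosest mismatch cap, then verifies every
seed hit by full-length Hamming count against the per-spacer cap. Any locus
within a spacer's cap puts no more than that many mismatches in its prefix,
so seeding loses nothing; tests prove equality with the single-spacer
matcher and with an exhaustive every-offset scan.

# Bias and selection statistics

For each category (replicon; temporal class; hot/cold region) the fraction
of transcript-targeting protospacers is reported twice: weighted by read
counts ("all spacers") and unweighted over clusters ("unique spacers").
The two weightings separate acquisition bias from post-acquisition
selection: clonal amplification of protected cells inflates read counts but
not the set of distinct loci.

Replicate agreement uses the Jaccard index — shared spacers over distinct
spacers in the combined replicates; `NA` when both sets are empty.

Reads whose amplified region contains exactly two new spacers are tested
for enrichment of cold-region protospacers with a chi-square goodness-of-fit
against the region composition expected from single-spacer reads
(no continuity correction, df = regions − 1). Among cold-region spacers in
double reads, the ordinal composition is reported both ways — the fraction
at ordinal 1 (leader-proximal, acquired last) and at ordinal > 1 — because
the two phrasings of "leader-proximal" in this assay (position in the
array vs order of acquisition) are easy to conflate.

Flank preferences (the PAM check; Type III systems are expected to show
none) use a position frequency matrix over the upstream flank, the
protospacer-proximal window and the downstream flank, oriented 5'→3' on the
protospacer strand; protospacers closer than one flank width to a reference
end are skipped and counted.

# Temporal classes

Counts are normalised per timepoint to TPM by default (counts divided by
gene length, columns scaled to 1e6) with a CPM mode provided, because
"normalisation on the total number of counted reads" can be read either
way; the class calls are insensitive to the choice since gene length
cancels in within-gene ratios. Log fold changes are
`LogFC_XvsY = log10(A(Y)+c) − log10(A(X)+c)` with pseudocount `c = 1`
guarding zero counts. Classes are assigned in order: *early* if
`LogFC_30vs50 < 0`; else *middle* if `LogFC_30vs50 > 0` and
`LogFC_50vs70 < 0`; else *late* if `LogFC_50vs70 > 0`. Early-first
precedence resolves the overlap between the early and late clauses (a gene
declining after 30 min and rising after 50 min keeps its pre-30-min
maximum); exact zeros satisfy no strict inequality and are reported
`unclassified` rather than forced. Replicates are averaged on normalised
abundances before LogFC — the combination rule is a config option and
per-replicate classes are always reported alongside. Heatmap rows divide
each gene's trajectory by its own maximum.

# Escaper deletion spectra

Protospacer-region amplicons are merged (overlap consensus, higher-quality
base at conflicts), required to carry both primers at their ends within 2
mismatches each (reads in the opposite orientation are reverse-complemented
first), and dereplicated exactly — identical sequences only, no similarity
clustering, because escaper variants differ by discrete deletions.

Deletions are called by global alignment with affine gaps, default scores
match +1, mismatch −2, gap open −6, gap extend −0.5. The extension penalty
is far below the mismatch penalty so that one long deletion is preferred
over scattered mismatches at the observed deletion sizes (tens to hundreds
of bp); the scores are config-exposed. Within repetitive context each
deletion is shifted to its leftmost equivalent placement, the convention
shared with standard variant normalisation, so calls are deterministic and
comparable across variants. Variants longer than the reference by more than
an insertion allowance are flagged rather than called; aligned point
mutations are recorded but not interpreted. A variant is frame-preserving
when its total deleted length is a multiple of 3; the frame-preserving
fraction is reported both over unique variants and weighted by reads, since
either weighting is a defensible reading of "fraction of deletions".

# The synthetic-data generator

The generator produces every input the pipeline consumes, with truth
tables sufficient to score extraction (recall/precision), mapping (locus
accuracy), classification (class recovery) and deletion calling (start and
length recovery) without any external data.

**Genome model.** A linear phage genome whose first and last `ltr_length`
bp (default 6639) are identical long terminal repeats; early genes tile the
LTR (the acquisition "hot" region), middle and late blocks tile the unique
interior. Defaults: 38 kb genome, 30 genes (10 per class), gene lengths
300–700 bp, random strands. Because the virion genome carries two identical
LTR copies, an LTR spacer cannot be uniquely mapped against it; mapping
therefore uses `nonredundant_reference()`, which trims the right copy so
every phage position occurs exactly once, and the "cold" region is the
unique interior `[L, G−L)`.

**Adaptation reads.** Each clone acquires `k` spacers with
`P(k=0) = 0.01`, `P(k=2) = 0.032` (the observed double-read rate is the
study condition), `P(k∈{3,4,5}) = 0.002` each, remainder single. Spacers
are drawn uniformly (position, strand, length 35–42 bp) from the
non-redundant phage genome with a 5% host-derived minority. A spacer is
*protective* iff it is transcript-targeting and its protospacer lies in the
protective region (the LTR under the default `"ltr"` model; any gene under
`"any_gene"`). Selection is modelled as post-acquisition clonal
amplification, not biased acquisition: each spacer carries an abundance
multiplier — `s` when protective, 1 otherwise — and a clone's sampling
weight is the mean multiplier over its spacers. The weight is therefore
bounded by `s`, so the expected read-weighted protective fraction follows
the closed form `p·s / (p·s + 1 − p)` (with `p` the per-spacer protective
probability) and no rare multi-protective clone can swamp the read pool,
which a compounding `s^k` weight would allow. The `s = 1` null reproduces
an unbiased unique-spacer picture while large `s` skews read weight
exactly as protection-driven outgrowth would. The selection advantage per
protective spacer is not quantified by any measurement we emulate, so `s`
is a free parameter. Within a clone, protective spacers are acquired first
and end up
leader-distal; the most recent unit has ordinal 1. Substitution errors are
applied at `error_rate` (default 0.001); reads are emitted pre-merged, as
the analysed amplicons are short enough for read pairs to overlap.

**Expression counts.** Class-specific mean trajectories over 0/10/30/50/70
min (early peaking at 10 min, middle at 50, late rising to 70) scaled by
log-normal per-gene base expression, with negative-binomial noise
(`size = 10`, a realistic amplicon/RNA-seq dispersion) and two replicates.

**Escaper amplicons.** Half the reads are wild type; the rest carry one
deletion overlapping the protospacer, with both primers always present.
Essential-gene deletions are restricted to multiples of 3; non-essential
lengths are uniform over 1–300 bp, making the expected frame-preserving
fraction exactly 1/3.

**What the generator does not emulate.** Quality-score structure and indel
sequencing errors; PCR chimeras and amplification bias; phage population
dynamics over multiple infection cycles; packaging/termini read signatures;
genuine biological spacer-length or position preferences beyond the
selection model. Passing tests therefore demonstrate correctness of the
pipeline's logic under the stated statistical assumptions, not robustness
to every artefact of real libraries.

# Determinism and problem sizes

Every generator is a pure function of its `SimulationConfig`; the pipeline
runners write byte-identical report bundles on reruns with the same seed
(outputs carry the resolved configuration, package version and seed, and no
timestamps). The test-suite and acceptance-script problem sizes — 10,000
amplicon reads for extraction/bias checks, a 50 kb reference with 1,000
spacers for the mapping oracle, 1,000 simulated tables for chi-square
calibration, 30 genes × 2 replicates for class recovery, 1,000 escaper
variants for the frame-fraction law — were chosen as the package's standard
desk-scale study conditions, large enough for the binomial and chi-square
checks to be informative.

# Known limitations

- Mapping is ungapped; an indel-containing protospacer would be missed.
  This is intentional at spacer scale and a gapped fallback is a natural
  extension.
- `merge_pairs` is a simple longest-acceptable-overlap merger, adequate for
  simulated and clean amplicon data but not a replacement for a dedicated
  read merger on noisy libraries.
- Circular topology is carried as metadata only; no coordinate arithmetic
  wraps the origin.
- The double-spacer test conditions on reads with exactly two mapped new
  spacers; reads where one of the two spacers fails the mapping filters are
  counted by their surviving spacer.
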