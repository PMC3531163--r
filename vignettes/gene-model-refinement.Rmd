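---
title: "Refining gene models with RNA-Seq evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining gene models with RNA-Seq evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmrefine)
```

## The problem

Gene annotations in non-model organisms lean heavily on *ab initio* and
comparative predictions, and their fine-scale structure — exact exon-intron
boundaries, UTR extents, the full exon complement — is often wrong. Deep
strand-specific RNA-Seq provides direct evidence for the real structures:
junction-spanning reads pin down splice sites, base-level coverage delimits
transcribed extents, and coverage in annotated "intergenic" space reveals
missed exons and transcripts. `gmrefine` implements a conservative,
rule-based refinement of a putative annotation against such evidence, plus
the statistics used to judge whether the revisions are credible.

The package deliberately consumes *processed* evidence — per-sample
strand-specific base coverage (bedGraph) and a junction read-count table
(TSV) — rather than alignments. Read mapping, duplicate handling and
multi-mapper resolution are upstream concerns; keeping them outside the
contract makes every rule in the package independently checkable.

## The four revision procedures

`refine()` runs four procedures in a fixed order, each against the
progressively revised models, and returns a typed event ledger alongside
the revised `gene_model_set`.

**1. Exon-intron boundary revision.** An annotated intron with *zero*
junction-spanning reads is eligible for replacement by an evidence
junction that (a) has at least `min_junction_reads` (default 2) reads
summed over samples; (b) carries canonical splice dinucleotides in
transcription sense — GT-AG, GC-AG or AT-AC; (c) lies within the span from
the leading exon's start to the following exon's end; and (d) leaves both
revised flanking exons within 80–120% of their annotated lengths. When
several candidates pass, the highest read count wins, then the smallest
coordinate shift, then the leftmost candidate. Ties are rare in practice;
the deterministic order matters for reproducibility.

**2. UTR extension.** From each annotated transcript end the algorithm
walks outward over strand-matched coverage. A position stops the walk iff
(i) its depth is below `utr_depth_threshold` (default 15) in at least
`utr_min_low_samples` (default 2) samples, **and** (ii) in *every* sample
the mean depth over the maximal identical-depth run containing the
position, merged with the adjacent identical-depth run on each side, is
below the threshold. The second clause makes the rule robust to single-base
dips inside genuinely transcribed sequence: a one-base dip inherits the
high mean of its flanking runs and does not stop the walk. The new end is
the base before the first stop; extensions shorter than
`utr_min_extension` (default 100 bases) are discarded. The walk is clamped
at the nearest same-strand annotated transcript boundary so extension can
never fuse neighbouring genes; a clamped extension can still be reported if
it reaches the minimum length. Opposite-strand neighbours do not block,
because the evidence is strand-specific.

**3. Missed exons.** Transcribed islands are called directly from pooled
coverage: maximal runs with pooled depth at least `island_min_depth`
(default 5) and length at least `island_min_length` (default 50 bases).
This internal caller replaces an external assembly step so that the stage
is self-contained and its thresholds explicit. An island inside a
transcript's span becomes a new exon when supported canonical junctions
link *both* of its ends to annotated exon boundaries of that transcript,
and its overlap with all annotated exons is below `new_exon_max_overlap`
(default 30%) of its length; the exon's boundaries are snapped to the
linking junctions' intron ends, so recovered coordinates are exact.

**4. Novel intergenic transcripts.** Islands overlapping no annotated
transcript span (introns included, either strand — the conservative
reading of "intergenic") are chained by supported canonical junctions;
chains of at least `min_new_transcript_exons` (default 2) islands whose
full span stays intergenic become new transcripts with junction-snapped
exons. New transcripts are clustered into genes by single linkage, where
two transcripts are linked if they share a splice junction or overlap
exonically by at least one base on the same strand.

The overlap-fraction denominator in rule 3 is the new exon's length, and
the 80–120% band in rule 1 is enforced on both flanking exons; both points
are genuinely open in the procedure's informal description, and these
choices are the stricter readings.

## ORF auditing

A boundary revision between coding exons changes the exonic length by
`delta = old intron length − new intron length`. When `delta %% 3 != 0`
the annotated reading frame downstream of the revision was wrong — the
annotation had a frame-shift error. Strikingly often such errors occur in
*pairs whose deltas cancel modulo 3*: two compensating mistakes that leave
the annotated ORF spuriously intact. `orf_audit()` flags frame-shifting
events and reports, for each, the co-events on the same transcript whose
summed delta restores frame (`find_companion_anomalies()`); no distance
bound is applied beyond same-transcript membership, since any
frame-complementary co-event is mechanistically capable of rescuing the
ORF. `scan_orf()` provides the supporting longest-ORF scan (three frames,
ATG-to-stop, stop codon counted) used to demonstrate that applying one
member of a compensating pair alone destroys ORF intactness. Homology
checks against a reference proteome are out of scope; ORF intactness is
the implemented proxy.

## Evaluation statistics

- `boundary_coverage_categories()` classifies every base around a revised
  junction into exonic/intronic under the old and new models, normalizes
  pooled depth by the window maximum, and compares the two disputed
  categories with a two-sided Wilcoxon rank-sum test (normal approximation
  with tie correction, via `stats::wilcox.test`). Credible revisions put
  high coverage on newly exonic bases and near-zero on newly intronic ones.
- `splice_pfm()` builds position frequency matrices around donors
  (window [−3, +6), negative offsets exonic) and acceptors
  (window [−13, +3), negative offsets intronic), with per-column
  information content in bits. The same transcription-sense offset
  convention is used for conservation profiles
  (`conservation_junction_profile()`); donor profiles put the exon on the
  negative side, acceptor profiles the intron, so the consensus GT sits at
  donor offsets 0–1 and AG at acceptor offsets −2–−1.
- `hexamer_end_profile()` reports the per-offset frequency of the poly(A)
  signal (AAUAAA; scanned as DNA `AATAAA`) around transcript 3' ends, with
  a negative control anchored at 5' starts. Window extents
  ([−60, +10) for the hexamer, ±5 kb in 100-base bins for the
  peak-distance histogram `end_distance_profile()`) cover the relevant
  consensus elements and are exposed as arguments.
- `summary_report()` produces the evidence-coverage and revision
  accounting tables; every percentage is `round(100 * n / d, 1)`
  (`summary_percentage()`), and transcripts with several revisions are
  counted once in the total row.

## The synthetic benchmark

`simulate_dataset()` is the package's self-contained test surface: it
generates a genome, true gene models, a corrupted annotation with a plant
ledger, and evidence that always reflects the *true* models.

What it emulates: canonical splice sites at every intron (95% GT-AG, 5%
GC-AG), an AATAAA signal planted 15–40 bases upstream of each 3' end, an
intact ORF spanning each annotated CDS, exon-level Poisson coverage per
sample and strand, per-sample junction reads for every true junction, and
a conservation track elevated on exons. Errors are planted per category:
boundary shifts of 4–30 bases in both directions (kept inside the 80–120%
band so they are recoverable, with the corrupted splice site left
non-canonical), UTR truncations of at least 100 bases, internal exon
deletions, and whole-transcript deletions; a configurable fraction of
boundary shifts come as frame-restoring pairs on one transcript. One
below-threshold decoy per rule family (1-read junction, still-supported
old junction, out-of-band shift, 80-base truncation, terminal-exon
deletion, single-exon transcript deletion) is flagged unsatisfiable and
must *not* be reported.

What it does not emulate: read-level artefacts (mapping bias, duplicates,
soft-clipping), expression heterogeneity across tissues, overlapping gene
loci, alternative isoforms, and — by default — intronic background
coverage. The default intronic/intergenic noise depth is 0, idealising a
clean strand-specific library; this makes planted UTR endpoints exactly
recoverable under the identical-run stopping rule, which is what the
recovery benchmark asserts. A nonzero noise mean is available in
`sim_config()` for robustness exploration, in which case stop positions
become stochastic within a few bases. Consequently, passing the benchmark
demonstrates that the rules are implemented exactly as stated, not that
the thresholds are optimal for any particular real library.

Default problem size is two 400-kb chromosomes, 50 single-transcript
genes, 3 samples per strand, exonic depth 30: large enough that every
stage sees multiple events, small enough that a full
simulate-corrupt-refine-evaluate cycle runs in seconds on one CPU.
All generator randomness flows from the single `sim_config()` seed, so
every artefact is reproducible byte for byte.

## Numerical and degenerate-input choices

- Coordinates are 0-based half-open internally; GTF I/O converts to
  1-based closed, BED/bedGraph are native. The GTF frame column is
  converted to the codon offset of the first coding base on read and back
  to a phase on write, so round-trips are exact.
- Information content uses plain frequencies without pseudocounts (IC of
  an empty column is defined as 0); PFM columns always sum to 1 when any
  anchor contributed.
- The rank-sum p-value is `NA` when either disputed category is empty
  (e.g. on an annotation needing no revision).
- Junctions shorter than the PFM windows are skipped and counted in
  `n_skipped` rather than silently dropped.
- `junction_support()` sums reads across samples; the two-read rule is
  applied to that pooled total. A per-sample minimum variant can be
  expressed by filtering the junction table before refinement.
- Single-exon transcripts have no junctions and are untouched by stages 1
  and 3; empty model sets and empty evidence tables are valid inputs
  everywhere and yield empty results.

## A worked run

```{r example, eval = FALSE}
ds <- simulate_dataset(sim_config(seed = 7))
res <- refine(ds$models, ds$evidence)
res
rec <- recovery_report(ds$ledger, res)
rec$recovery_rate      # 1: every satisfiable plant recovered exactly
rec$decoys_reported    # 0
rec$off_ledger_events  # 0
orf_audit(ds$models, res$events)
```

The same flow is scripted in `scripts/acceptance.R`, which additionally
recomputes the summary-accounting percentages from a built-in table of
reference genome-wide counts through `summary_percentage()`.

## Known limitations

- One transcript per gene is assumed throughout refinement; overlapping
  isoforms are not merged or disambiguated, and events on shared introns
  are proposed per transcript.
- Stage order (junctions → UTRs → new exons → new transcripts) is fixed;
  an error whose correction depends on a later stage's output (e.g. a
  boundary revision inside a not-yet-recovered exon) will take two passes.
- "Intergenic" is judged against the annotation being refined; novel
  transcripts adjacent to unannotated real genes will still be called.
- The UTR identical-run rule is one operationalization of an informally
  stated stopping criterion; its behaviour on plateaued low-coverage tails
  is documented by the unit fixtures rather than asserted as the only
  reading.
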