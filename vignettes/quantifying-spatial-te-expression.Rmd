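---
title: "Quantifying spatial transposable element expression with spotTE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spatial transposable element expression with spotTE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotTE)
```

## The model

Spatial transcriptomics (ST) attaches a spatial barcode to every cDNA
fragment, so each aligned read can be traced to a capture spot on the
tissue grid. Transposable elements (TEs) are absent from standard ST
gene quantification for the same reason they are hard in bulk RNA-seq:
a TE subfamily is a set of dispersed, highly similar genomic copies, and
a short read drawn from one copy often aligns equally well to several.
`spotTE` resolves this with a per-locus *mapping score* and a two-way
partition of loci between locus-level and subfamily-level reporting.

The pipeline is:

1. **Non-exonic restriction.** Only reads mapping outside annotated
   exons are considered. A read is exonic if *any* of its aligned
   blocks, at *any* of its reported alignment locations, overlaps an
   exon by one or more bases. This is deliberately conservative: a
   multi-mapper with one exonic location is more plausibly mRNA signal
   (many TE fragments are embedded in UTRs) than TE transcription.
2. **Assignment.** A read is assigned to a TE locus when the union of
   its block overlaps with that locus reaches `minOverlapBases`
   (default 1). A uniquely mapped read overlapping several loci — which
   happens with nested annotations, e.g. a SINE inserted into an L1 —
   is assigned to the single locus with the largest overlap, ties
   broken by lexicographically smallest locus id, so results are
   deterministic. A multi-mapped read is assigned, as a multi-mapper,
   to every locus any of its alignment locations overlaps, at most once
   per locus.
3. **Metrics.** For each locus with at least one assigned read:
   coverage (percentage of locus bases covered by the union of assigned
   reads' blocks, pooled across all spots) and the mapping score
   \(MS = 100\,\mathrm{UMR}/(\mathrm{UMR}+\mathrm{MMR})\), the
   percentage of assigned reads that map uniquely.
4. **Partition.** Loci below the coverage threshold are dropped
   (default 0, so nothing is). Loci with \(MS \ge\) `msLocusMin`
   (default 100) are reported per locus; loci with \(MS \le\)
   `msSubfamilyMax` (default 0) are pooled per subfamily. Loci strictly
   between the thresholds are reported in neither matrix; they are
   counted in the run log so that every locus has exactly one
   disposition. Coverage and MS are pooled sample-wide rather than per
   spot because the partition is a property of the locus, not of a
   (locus, spot) pair; the per-spot matrices then distribute each
   locus's reads over spots.
5. **Output.** TSV matrices with spots as rows (labels `"XxY"`, sorted
   by grid coordinates) and features as columns, at locus, subfamily
   and class (LINE/SINE/LTR/DNA/Other) resolution, plus a JSON run log
   with all read-disposition tallies.

## Parameters that matter

| parameter | unit | default | role |
|---|---|---|---|
| `coverageMin` | % of locus length | 0 | drop weakly covered loci; raise to demand full-length transcription, keep low to admit truncated TE transcripts |
| `msLocusMin` | % unique reads | 100 | admission to locus-level reporting; 100 = only unambiguous loci |
| `msSubfamilyMax` | % unique reads | 0 | admission to subfamily-level pooling; 0 = only fully ambiguous loci |
| `minOverlapBases` | bases | 1 | minimum read/locus overlap to count an assignment |
| `uniqueMapq` | MAPQ | 255 | "unique" MAPQ convention used only when the hit-count tag is absent |

The two MS thresholds are percentages, and the defaults (100 and 0) are
the exact boundary cases: a locus enters the locus matrix only if it has
no multi-mapped reads at all, and the subfamily matrix only if it has no
unique reads at all. Users who relax `msLocusMin` below 100 should know
that all assigned reads of an admitted locus are counted, including its
multi-mappers; likewise a multi-mapper touching loci of several
subfamilies contributes once to each such subfamily column, a documented
over-count that we prefer to silent fractional weights.

## Input dialects

The reader accepts two spatial conventions. In the original-ST dialect
each record carries two integer tags with the spot's grid coordinates
(defaults `B1` = x, `B2` = y, configurable); a barcode tag plus a
barcode/x/y table is accepted as a fallback. In the 10X dialect, records
carry a corrected cell barcode (default `CB`) which is resolved through
a tissue-positions table; out-of-tissue spots are kept unless
`inTissueOnly` is set, since excluding them is an analysis decision, not
an alignment fact. Reads whose spatial information cannot be resolved
are never silently dropped: they are skipped and tallied. Multi-mapper
status comes from the `NH` hit-count tag when present; otherwise hits
are counted across records sharing the read name, and for single
untagged records the aligner's unique-MAPQ convention decides. UMI
deduplication is off by default and, when enabled, collapses reads by
(spot, UMI, locus).

## The synthetic benchmark

There is no public simulator for spot-barcoded TE reads, so the package
carries its own, mirroring the validation design of spatial TE tools: a
mini-genome with planted TE copies, per-spot read plans, and per-read
ground truth.

**What it emulates.** Each subfamily gets a random consensus; copies are
the consensus with independent per-base substitutions at the planned
divergence. Divergence is the lever that reproduces TE age: at ≥ 15%
divergence a 100-base read essentially never matches a sibling copy
within the 3-mismatch budget, so reads map uniquely (old TEs); at ≤ 1%
copies are near-identical and every read multi-maps (young TEs). Reads
are drawn uniformly along each planned locus; read 1 carries the spot
barcode (FASTQ mode), or alignment records are emitted directly
(aligned mode) with hit counts determined by exhaustively matching each
read against every planted locus at up to 3 mismatches — an explicit,
testable stand-in for an aligner.

**What it does not emulate.** Fragment-length and positional bias,
indels, base-quality-dependent errors, barcode sequencing errors,
reads from unannotated repeats, and background-genome alignment: the
exhaustive matcher searches only the planted loci, because a ≥ 97%
identity match between a 100-mer and an i.i.d. random background is
vanishingly improbable. Passing benchmarks therefore demonstrate the
correctness of the quantification logic — spot resolution, exon
filtering, assignment, partitioning, accounting — not robustness to
alignment artefacts in real data.

The default study conditions are a two-spot design with spot `11x5`
receiving 6420 LINE reads and spot `10x10` receiving 9593 LTR reads,
drawn over randomly selected planted loci; the default genome is 2
chromosomes × 100 kb with four subfamilies × five copies (one young at
1% divergence, three old at 15–20%), sized so that a full
simulate–quantify–score round runs in seconds on one CPU.

```{r benchmark, eval = FALSE}
res <- runBenchmark(genomeSpec(seed = 5))
res$report
```

The report contains: reads counted at a spot other than their true spot
(zero whenever barcodes are error-free — spatial resolution is exact by
construction, and the pipeline must not break it); Pearson correlations
between estimated and true counts at locus and at subfamily resolution
over the union of occupied cells; and the percentage of reads whose
locus-level assignment is not exactly their true source locus. The
benchmark builds both matrices over *all* covered loci (rather than the
default partition) so that locus-level accuracy is measurable even when
every locus is fully ambiguous; with the default mixed-age genome the
locus-level misassignment lands in the tens of percent, driven entirely
by the young subfamily, while subfamily-level counts match truth
exactly.

The misassignment fraction is defined per read (a read is misassigned
unless its assigned locus set is exactly its true source locus) rather
than from matrix cell differences: a multi-mapper counted at *k* loci
would otherwise contribute *k* − 1 excess counts and the "fraction"
could exceed 100%.

## Numerical and design choices

- **Coordinates.** All in-memory intervals are `GRanges` (1-based,
  closed), the native convention of the underlying Bioconductor stack;
  conversion to/from the 0-based half-open convention of BED-style
  files and the 1-based RepeatMasker/GTF conventions happens only in
  the parsers and writers. One internal convention, converted at the
  boundary, avoids off-by-one drift between modules.
- **Locus identifiers** are `"subfamily|chrom:start-end(strand)"` with
  1-based inclusive coordinates — unique, human-readable and reversible.
  Should an annotation contain exact duplicate rows, ids are
  disambiguated with a `#k` suffix.
- **Annotation hygiene.** Non-TE RepeatMasker classes (simple repeats,
  low complexity, satellites, structural RNAs) are excluded at parse
  time by default but retainable; `?`-suffixed uncertain classes are
  normalized; classes outside LINE/SINE/LTR/DNA (e.g. Retroposon/SVA)
  map to `Other`. Nested or overlapping annotation rows are all
  retained; overlap is resolved per read at assignment time by the
  max-overlap rule.
- **Degenerate inputs.** An empty locus or subfamily set still yields a
  valid (zero-column) matrix and a well-formed TSV; an annotation that
  filters to nothing is a warning (the run can still count zero TEs),
  but a GTF without exon features is an error, because running without
  the non-exonic filter would silently change the method.
- **Determinism.** The quantifier contains no randomness; matrices are
  written with rows sorted by grid coordinates and columns sorted
  lexicographically, so identical inputs give byte-identical outputs.
  Only the simulator consumes seeds, and equal (spec, plan, seed)
  triples reproduce files byte for byte.
- **Problem sizes in the test-suite.** Property-style suites run on
  randomized instances of up to 100 reads × 20 loci against an
  independent per-base brute-force oracle (position-set arithmetic,
  sharing no interval code with the implementation), 100 instances per
  run; benchmark properties run on 20 simulated scenarios of 1000 reads
  each over the default mini-genome — sizes chosen to exercise every
  code path while a full check stays in the minutes range on one CPU.

## Known limitations

- No EM-style probabilistic reassignment of multi-mappers
  (TEtranscripts/Telescope-style); the method's answer to ambiguity is
  the MS partition, not redistribution.
- Subfamily pooling can over-count a multi-mapper that touches several
  subfamilies (once per subfamily); the run log reports the dispositions
  needed to audit this.
- Loci with intermediate mapping scores are invisible in both default
  outputs; widen the thresholds to claim them, at the documented cost.
- The benchmark's aligner stand-in searches planted loci only and
  allows substitutions but not indels.
- Barcode error correction, image registration and read alignment are
  out of scope; the package consumes what the upstream ST pipeline
  already produced.
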