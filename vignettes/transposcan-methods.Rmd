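---
title: "Methods: in silico transposon display and insertion-site analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in silico transposon display and insertion-site analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transposcan)
```

# The assay being modeled

Transposon display locates new insertions of an active DNA transposon (the
motivating case is a ~20.5 kb CACTA-family element in soybean) by a
ligation-mediated nested PCR:

1. Genomic DNA of each mutant is digested separately with blunt-cutting
   enzymes (default panel: DraI `TTT^AAA`, EcoRV `GAT^ATC`, PvuII
   `CAG^CTG`, StuI `AGG^CCT`).
2. An adaptor is ligated to the blunt fragment ends.
3. An outer PCR pairs an adaptor primer with an outer element-specific
   primer (R1), followed by a nested PCR with a nested adaptor primer and a
   nested element primer (R2) closer to the element terminus. Only the
   nested product is observed on the gel.
4. Bands present in every mutant come from residual element copies shared
   by the genetic background; bands unique to one mutant are sequenced.
5. A sequenced product is accepted only if it carries more than 100 bp of
   exact element-end sequence adjacent to the junction; the genomic flank
   beyond the junction is then mapped to the reference.

`transposcan` models each of these steps as an explicit, testable
operation, with the biology that the assay cannot see (primer chemistry,
amplification bias, gel resolution) deliberately out of scope.

## Product-length arithmetic

For an element copy whose primer-bearing terminus survives intact inside a
restriction fragment that also has an adaptor-ligated genomic end, the
nested product length is

```
product_length = dist(R2 site, element terminus) + flank_length + adaptor_length
```

`predict_display_products()` verifies the exact geometry: the fragment must
contain the full R1 and R2 sites (primer binding is exact-match,
full-length; truncated or fractured termini therefore yield no band), and
only products inside the amplifiable window (default 100–6,000 bp) are
kept.

```{r product}
el <- element_spec()
el
```

# Coordinate conventions

These conventions are fixed, documented, and covered by tests; several are
arbitrary choices that simply need to be made consistently.

**Adjacent-pair insertion sites.** An insertion is reported as a 1-based
pair (`left`, `right = left + 1`): the element sits between two adjacent
reference bases. All downstream classification refers to the junction by
`left`.

**Feature attribution at boundaries.** The inter-base junction between
`left` and `left + 1` is attributed to the feature containing base `left`,
so a junction exactly on an exon/intron boundary goes to the
lower-coordinate feature.

**Upstream distance.** For a plus-strand gene, a junction within the window
(default 2,000 bp) before the transcription start is `upstream` with
`distance = gene_start - left`; minus-strand genes mirror this. A junction
272 bp upstream of a gene at 39,611,506 therefore has `left = 39,611,234` —
this is the convention that makes the reported distances reproduce
published site tables digit-for-digit. Gene bodies take precedence over
neighboring genes' windows; among several window hits the nearest gene
wins, with ties broken toward the smaller `gene_id`.

**Target-site duplication (TSD).** On insertion the element duplicates
`tsd_length` target bases (default 3, a CACTA-family convention; it is a
config knob, not asserted biology). The mutant chromosome is
`ref[1..left+d] + element + ref[left+1..]`. Because the single-side display
assays only the element end carrying the R1/R2 primers, the recovered
flank abuts the *element-proximal copy* of the duplication: with the
default 3'-terminus primers, a `+`-orientation insertion is recovered at
`left` and a `-`-orientation insertion at `left + d`. The pipeline's truth
accounting normalizes for this, and callers comparing against known truth
should do the same.

**Mapper junction side.** `map_flank()` needs to know which end of the
query abuts the element (`junction_end`, default `"5p"`, which is what
`extract_and_validate_flank()` produces: flanks read away from the
element). Mapping a flank and its reverse complement with the flag flipped
yields the same coordinate pair on opposite strands.

**File formats.** GFF3 and the internal tables are 1-based inclusive; BED
output is 0-based half-open, converted only at I/O boundaries.

# Default parameters and rationale

| Parameter | Default | Rationale |
|---|---|---|
| enzyme panel | DraI, EcoRV, PvuII, StuI | the blunt-end four-cutter panel used by the motivating assay |
| `adaptor_length` | 25 bp | typical nested adaptor-primer tail contribution |
| `size_range` | 100–6,000 bp | practical long-range PCR window |
| `min_element_evidence` | 100 bp | published screening rule: >100 bp of element-end sequence |
| element length | 20,548 bp | the motivating CACTA element's size |
| R1 / R2 distance | 250 / 150 bp | nested geometry leaving >100 bp of element-end evidence in every accepted product |
| `tsd_length` | 3 bp | CACTA-family convention, configurable |
| mapper `k` | 21 | long enough to be near-unique in a 10^9 bp genome, short enough to seed 100 bp flanks with mismatches |
| `max_mismatches` | 0 | the display validates flanks exactly; mismatch tolerance exists for degraded inputs |
| classifier `window` | 2,000 bp | typical promoter-proximal window; the assay literature reports distances well inside it |
| hotspot `window` / `min_count` | 1 Mb / 3 | "regions under 1 Mb enriched in insertions" |
| genome defaults | 4 chr x 2 Mb, exon 0.116, intron 0.105, pericentromere 0.57 | desk-scale genome with the composition of a soybean-like annotation |

# The synthetic genome generator

`generate_genome()` builds a deterministic genome from a
`synthetic_genome_spec()`: non-overlapping genes on both strands with
multi-exon structure (mean 6 exons/gene), a configurable fraction (default
30%) carrying a second splice variant (internal-exon skip, which preserves
the span, or 3'-terminal truncation, which shortens it — both exercise
longest-variant selection), one contiguous central pericentromere block per
chromosome, and residual 5'-truncated element copies planted in the widest
intergenic gaps. The realized exon/intron fractions land within ±0.01 of
the targets (the final gene on each chromosome is sized to close the
remaining budget exactly):

```{r generator}
bundle <- generate_genome(synthetic_genome_spec(), element_spec())
genome_partition(bundle$genes, chromosome_lengths(bundle))
```

Realism limits: sequence content is i.i.d. with a GC knob — there are no
repeat families, paralogs, or base-level evolution; genes never overlap or
nest; pericentromeres are single blocks. Only composition and interval
structure matter to the downstream statistics, and those are matched.

# Partition arithmetic

`genome_partition()` implements the longest-splice-variant decomposition:
for each gene take the transcript with the greatest transcribed span
(ties to the lexicographically smallest `transcript_id`; "longest by summed
exon length" is available via `by = "exonic"`), split it into 5'UTR / CDS /
3'UTR / intron lengths, and sum over genes. The conservation identity
`full = utr5 + cds + utr3 + intron` is asserted throughout. Non-coding
transcripts count their whole exonic length as exon (keeping the identity)
and are flagged. By default bases are counted once *per gene* — overlapping
gene models (possible in real annotations) each contribute fully, matching
how the published totals were assembled; `count_mode = "deduplicated"`
measures union coverage instead.

# Statistics: two chi-squared modes

Display studies have reported insertion-randomness checks as a chi-squared
computed directly on *percentages* of the two genic classes with one degree
of freedom:

```{r chisq}
chisq_paper(c(16.2, 9.5), c(11.6, 10.5))
```

This percentage-scale form is reproduced faithfully (it is the only form
that yields the published 1.92 for these inputs), but it is
scale-dependent — multiplying all percentages by a constant changes the
statistic — and the "two classes, df = 1" framing is non-standard. It is
therefore paired with, and should be interpreted through, the standard
count-based multinomial test:

```{r chisq2}
chisq_counts(c(17, 10, 78), 105, c(0.116, 0.105, 0.779))
```

The two are different statistics and will not agree numerically; published
values computed on rounded percentages can likewise differ from
recomputations on the underlying counts (a printed 1.92-style figure and a
1.78-style figure can both arise from the same cohort depending on the
inputs used). Only the count-based mode is a calibrated test; the test
suite checks its type-I error at the cohort sizes of interest.

`detect_hotspots()` finds maximal sets of at least `min_count` insertions
whose footprint fits in `window` bp via a two-pointer sweep. Qualifying
windows that share a member site are merged into one region reporting the
tight span of its members; a merged chain can therefore exceed `window`
(the unmerged regions never do). The sweep is verified against exhaustive
window enumeration.

# Problem sizes and runtime

On one CPU: default genome generation ≈ 4 s; classifying 100,000 uniform
sites ≈ 2 s; a full 124-mutant end-to-end run (genome, per-mutant display
with the four-enzyme panel, band comparison, flank validation, mapping,
classification, statistics, all outputs) ≈ 1 min. All stages are
deterministic under a fixed seed, and `run_pipeline()` reruns are
byte-identical.

# Limitations

- Single-side display only: the element end opposite R1/R2 is not assayed,
  so orientation-dependent TSD reporting (above) is inherent.
- Exact-match primer and flank models; no chemistry-level simulation.
- The classifier assigns one category per site; overlapping genes are
  resolved by fixed tie-breaks rather than reported multiply.
- The hotspot sweep is a windowed count, not a spatial point-process test.
- The synthetic genome is compositionally faithful but sequence-naive (see
  generator limits above).
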