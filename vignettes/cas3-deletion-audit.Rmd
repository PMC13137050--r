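---
title: "Auditing CRISPR-Cas3 editing: guide design, off-target enumeration, and large-deletion calling"
author: "cas3audit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing CRISPR-Cas3 editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cas3audit)
library(data.table)
```

## The problem

Type I-E CRISPR-Cas3 differs fundamentally from Cas9. Cascade, the
multi-subunit surveillance complex, binds a 32-nt protospacer flanked by a
5'-AAG PAM, forms an R-loop, and recruits the Cas3 helicase-nuclease, which
then degrades DNA processively and largely unidirectionally. The editing
outcome is not a small indel at a fixed cut site but a spectrum of long
deletions — kilobases to tens of kilobases — extending mostly to one side
of the PAM. Auditing such an experiment therefore needs different machinery
than Cas9 amplicon analysis:

* guide (crRNA) selection must screen for sequence-composition and
  positional criteria and for genome-wide uniqueness of a 35-nt site;
* potential off-target (POT) interrogation must handle two distinct
  recognition failure modes (a PAM-anchored stretch of exact pairing, or a
  distributed mismatch budget over the long protospacer);
* on-target quantification must call structural variants — deletions with
  two breakpoints — from capture-sequencing evidence rather than count
  indels in a window;
* off-target quantification must separate true cleavage signal from
  library/alignment noise by subtracting a no-crRNA control.

`cas3audit` implements this workflow end to end, together with a fully
seeded synthetic-data generator so every stage can be validated against
known ground truth.

## Coordinate conventions

All intervals everywhere in the package are 0-based half-open
(`[start, end)`), on the forward strand of the reference. The only
conversions happen at the I/O boundary: `read_alignments()` shifts SAM's
1-based positions down by one, and BED is consumed natively. No other
function converts coordinates; this removes the usual class of off-by-one
drift between modules.

## crRNA screening

`scan_candidates()` implements the design screen. A candidate is a 3-nt
PAM (default `AAG`) plus a 32-nt protospacer such that:

* the PAM matches exactly on the candidate's strand (both genome strands
  are scanned);
* protospacer GC content lies in [0.30, 0.70], bounds inclusive — we read
  "between 30% and 70%" inclusively, and the bounds are configurable;
* the PAM-proximal end of the protospacer lies 100-500 bp downstream of
  the target exon's 3' end, measured in the gene's transcription
  direction. The anchor choice (exon 3' end to PAM-proximal protospacer
  boundary) is one of several defensible readings of "downstream of the
  exon"; it is the transcription-oriented one and is configurable.

`uniqueness_check()` then applies two genome-wide exclusion rules: a
candidate fails if any other locus matches the full PAM+protospacer with
at most 3 protospacer mismatches (PAM exact, either strand), or exactly
matches the PAM plus the PAM-proximal 15-nt seed. "No significant
matches" is operationalized as *zero* such hits — the strictest consistent
reading, since no score threshold is stated for the screen. The seed
clause carries no mismatch budget for the same reason. Whether the
3-mismatch budget should also cover PAM positions is genuinely ambiguous;
we fixed PAM-exact (the conservative choice for specificity) and count
mismatches over the spacer only.

## POT enumeration

For a Cas3 guide, `find_pot_sites_cas3()` reports every genomic window
(both strands) satisfying either of two rules:

* **consecutive**: a contiguous exact match of at least 16 nt to the
  35-nt PAM+protospacer that overlaps at least one PAM base. A run lying
  entirely inside the spacer does not qualify; requiring the full PAM is
  available via `consec_pam_bases = 3`. The upper figure in the "16-20 nt"
  phrasing is recorded but not enforced as a cap — a 25-nt run obviously
  still qualifies — so `consec_min` is the single active bound and the
  observed run length is reported.
* **mismatch-tolerant**: an exact PAM with at most 7 mismatches over the
  full 32-nt protospacer. The consecutive rule explicitly includes the
  PAM while this rule names the full target sequence, so we count the
  budget over the spacer only and require the PAM exact; both choices are
  configurable.

`N` in the genome never matches anything (conservative); a pattern `N`
(as in the Cas9 `NGG` PAM) is a wildcard over A/C/G/T but still never
matches a genomic `N`. Overlapping qualifying windows offset by fewer
than 10 bp are merged into one site, keeping the representative with the
fewest mismatches and then the longest PAM-anchored run, so one physical
locus is not double-counted. `find_pot_sites_cas9()` applies the Cas9
benchmark definition: `NGG` PAM 3' of a 20-nt guide, at most 3 guide
mismatches.

The scan itself is a vectorized running-window pass over each contig (35
vector operations per strand, whatever the contig length). Its
correctness is checked in the test suite against an independent
brute-force oracle built on `Biostrings::matchPattern`: for the
mismatch rule, all inexact full-site matches re-verified per hit; for the
consecutive rule, the observation that a qualifying run exists iff one of
the three PAM-anchored 16-mers of the pattern matches exactly at the
right offset. The two code paths agree site-for-site on seeded random
genomes with planted near-misses straddling both rule boundaries.

`build_capture_regions()` encodes the probe geometry: on-target regions
span 100 kbp on both sides of the PAM; POT regions span 9 kbp on the
PAM-upstream side and 1 kbp downstream, oriented by the site's strand.
The asymmetric window only makes sense anchored to the directionality of
Cas3 degradation, so upstream/downstream follow the site's strand.

## Deletion calling

Evidence extraction re-implements the minimal contracts of the standard
SV toolchain:

* `extract_split_reads()` emits one item per soft clip of at least
  `min_clip` nt (default 20) on a mapped primary record with
  `mapq >= 20`; the breakpoint is the reference coordinate of the
  clip boundary. The 20-nt floor treats shorter clips as alignment
  ambiguity (adapter stubs, low-complexity slippage) rather than
  breakpoint evidence.
* `extract_discordant_pairs()` flags pairs whose outer span exceeds the
  proper-pair insert mean + 3 SD (estimated from the data, or supplied),
  or whose orientation is not forward-reverse.

`bin_split_counts()` tiles the capture region with fixed 100-bp bins —
fine enough to resolve kilobase-scale deletions, coarse enough for stable
counts; the width is exposed in the configuration. `detect_cut_points()`
applies the ratio rule: a bin is a cut point when
`treated / max(control, 1)` **strictly exceeds** 5 (a ratio of exactly 5
does not qualify) and the treated count reaches `min_support` (default 3;
the ratio alone would fire on 1-versus-0 noise). The pseudo-denominator
handles zero-control bins with minimal assumptions.

`infer_deletion_patterns()` turns cut points into deletion calls: pairs
with one inner boundary within 150 bp of the cut point are clustered by
their far boundary (single linkage, 150 bp — about one read length of
breakpoint uncertainty). Each cluster becomes one pattern. Breakpoints
are estimated as the tightest bounds consistent with every member pair —
the maximum of left mate ends and minimum of right mate starts. Pair
boundaries can only *under-reach* a deletion breakpoint (a mate must stop
short of the junction), so averaging them biases the call outward by
roughly half the mate gap; the extremes are the least-biased pair-only
estimate. When split reads fall within the merge tolerance of such a
bound, the call snaps to their median breakpoint, which is exact up to
alignment jitter. This pair+split integration is what dedicated SV
callers converge on, and in the simulated libraries it keeps breakpoint
error well inside the 150-bp matching tolerance even for calls supported
by a handful of pairs.

`summarize_extents()` reports maxima relative to the PAM in
strand-oriented 5'/3' terms, and `annotate_gene_overlap()` scores each
neighboring gene: a pattern overlaps a gene when the deleted interval
intersects the gene body, with "partial" recorded when the gene is not
fully contained. Percentages are rounded half-up to one decimal — plain
`round()`'s half-even rule would disagree with most printed figures of
this kind.

## Off-target scoring

`score_pot_sites()` counts treated split reads inside each capture region
and subtracts the no-crRNA control count. Negative scores are retained
(they are informative diagnostics of noise asymmetry) but never flagged;
a region is flagged at a score of 5 or more — there is no published
numeric cutoff for "elevated", so the threshold is exposed in the
configuration. `adjusted_indel()` provides the Cas9 benchmark mode:
reads whose alignment overlaps a +/-20 bp window around the expected cut
count as edited when any insertion or deletion CIGAR operation overlaps
the window, and the control percentage is subtracted with clamping at
zero (the "adjusted" convention).

## The synthetic-data generator

`sim_config()` fixes the emulated study conditions; they are the
generator's defaults and are not tuned per test:

| parameter | default | meaning |
|---|---|---|
| `genome_len` | 400 kb | single contig, i.i.d. uniform ACGT |
| `n_cells` | 200 | deletion haplotypes |
| `editing_rate` | 0.6 | fraction of haplotypes carrying one deletion |
| `direction_bias` | 0.8 | probability the deletion extends 3' of the PAM |
| `del_mean_3p` / `del_max` | 20 kb / 100 kb | geometric 3' length, truncated |
| `del_mean_5p` | 2 kb | geometric length of the minor 5' direction |
| `bp_jitter` | 50 bp | anchored-breakpoint scatter around the cut |
| `read_len`, `insert_mean`, `insert_sd` | 150, 400, 60 | 2x150 paired-end model |
| `depth` | 200x | mean read coverage per capture region and library |
| `noise_clip_rate` | 0.2% | spurious 5-15 nt soft clips, both libraries |

The geometric length family was chosen for its heavy right tail, which
reaches the tens-of-kilobase maxima seen in real Cas3 data; no claim is
made that it is the true lesion-length law. Deletions are strictly
one-sided: one breakpoint is anchored within +/-50 bp of the cut and the
other is drawn from the direction's length distribution. Reads are
sampled in haplotype coordinates and mapped back to the reference, so
junction-crossing reads carry exact soft-clipped CIGARs and
junction-spanning fragments produce deletion-inflated template lengths —
with the realistic caveat that a crossing read whose longer segment lies
on its mate's side of the junction aligns there and contributes no
discordant evidence. The ground-truth table records, per haplotype, the
number of fragments that genuinely yield a discordant pair.

What the generator does *not* model: base-substitution sequencing error
(irrelevant to split/discordant evidence), PCR duplicates, capture-probe
efficiency bias, multi-contig rearrangements, or microhomology at
junctions. Passing tests therefore demonstrate correctness of the
evidence-to-call machinery under clean alignments, not robustness to
every artifact of real libraries.

## Problem sizes and what the validation shows

The validation suite runs the full pipeline at the default conditions
(400-kb genome, 200 haplotypes, 200x depth) across ten seeds, plus
scaled-down runs (60-260 kb, 30-50 haplotypes) for fast structural
checks. At the default conditions each deletion is crossed by only ~1
fragment on average — 200x of region coverage shared across 200
haplotypes — so deletions with at least 5 supporting discordant pairs,
the recovery criterion's population, are rare (a few across ten seeds).
Those are recovered with breakpoint error within the 150-bp tolerance; a
control-versus-control comparison yields zero cut points; planted
non-cleaved POT sites (copies of the guide at 2, 5 and 7 mismatches)
score exactly zero and are never flagged, while the on-target region is
always flagged.

## Worked example

```{r example, eval = FALSE}
cfg <- run_config(seed = 1)
rep <- run_pipeline(cfg)
rep$extents
rep$gene_overlap
rep$scores[, .(region_id, kind, treated_splits, control_splits, score, flagged)]
```

## Degenerate inputs and numerical choices

* Empty pattern sets make the overlap fraction undefined:
  `annotate_gene_overlap()` returns an explicit empty table rather than
  0/0.
* A sample with zero reads covering the indel window yields `NA`
  percentages, not zero.
* Candidate windows that run off the contig end are truncated with a
  warning; capture regions are clipped at contig edges with a warning;
  anchors outside the contig are errors.
* Ties in the POT merge rule break toward fewest mismatches, then longest
  PAM-anchored run, then leftmost coordinate (via stable ordering).
* All reported percentages use half-up rounding (`round_half_up()`), with
  a 1e-9 guard against binary representation of exact halves.

## Limitations

* The deletion caller targets intra-contig deletions only; inversions,
  translocations and insertions are out of scope.
* Cut-point resolution is bin-width limited; the reported cut point is
  the bin midpoint.
* The uniqueness screen and POT scan are exact-arithmetic scans; they do
  not model DNA/RNA bulges.
* Scoring uses the whole capture region per POT site; a sub-window score
  would sharpen contrast at very high depth but is not implemented.
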