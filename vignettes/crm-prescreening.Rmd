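---
title: "Prescreening and designing cell-type-specific cis-regulatory modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prescreening and designing cell-type-specific cis-regulatory modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmscan)
```

## The problem

Chromatin accessibility (ATAC-seq, DNase-seq) nominates candidate
cis-regulatory modules (CRMs), but most accessible regions do not drive
transcription in vivo: accessibility alone is a poor predictor of
activity. `crmscan` implements a prescreening statistic that markedly
enriches for active CRMs before any wet-lab testing: the density of
binding sites for the target cell type's *enriched transcription factors*
(e.g. Müller-glia-enriched TFs for a Müller glia screen). The package also
implements the complementary *stitching* strategy for cell types where a
TF panel cannot be assembled: concatenating the accessible regions
flanking a cell-type-enriched gene into one synthetic CRM, subject to the
~4.7 kb AAV packaging budget.

The full prescreen is a pipeline of five stages, each usable on its own:

1. **Marker/TF selection** (`find_markers`, `select_tfs`): cell-type-
   enriched genes from a clustered single-cell count matrix, subset to
   transcription factors.
2. **CRM nomination** (`nominate_crms`): accessibility peaks flanking a
   gene of interest, bounded by the neighbouring genes, excluding exonic
   peaks.
3. **Motif scanning** (`load_jaspar_pfm`, `scan_sequence`): PWM log-odds
   scanning of each candidate on both strands.
4. **Density and classification** (`tfbs_density`, `classify`): the
   merged-TFBS-per-100-bp statistic at two score thresholds, and the
   quadrant call.
5. **Stitching** (`union_stage_peaks`, `tissue_specific_filter`,
   `stitch`): the synthetic-CRM designer.

Every stage runs on synthetic inputs with planted ground truth
(`simulate_preset`), so the whole pipeline is testable without any
download.

## The density statistic

For a candidate of length $L$ bp and a panel of $m$ TF motifs, every
window on both strands is scored against each motif's log2-odds matrix

$$ W_{b,j} = \log_2 \frac{(c_{b,j} + p\,\pi_b) / (C_j + p)}{\pi_b}, $$

where $c_{b,j}$ are the position frequency matrix counts, $C_j$ the column
total, $p$ the pseudocount (default 1, distributed by the background
$\pi$, default uniform 0.25). A window is reported when its *relative*
score — the raw score rescaled to $[0,1]$ between the matrix's attainable
minimum and maximum — reaches 0.80, the JASPAR SCAN convention.

Hits are then thresholded on the **raw** log-odds score ("JASPAR score")
at two cuts, 10 and 11. Within each threshold set, hits whose starts lie
within 5 bp of one another (pooled across motifs and strands) are merged
into one "TFBS count"; the density is

$$ d_{>t} = \frac{\text{merged count at raw score} > t}{L} \times 100 . $$

A candidate is placed on the $(d_{>10}, d_{>11})$ plane and called
**likely active** (quadrant A2) when $d_{>10} > 1.7$ *and* $d_{>11} > 1$
(strict inequalities; points on a cut line are outside A2). The published
operating point also admits an *or* reading; `classifier_config(combine_rule
= "OR")` selects it, with `AND` the default because the validated active
CRMs all sat in A2.

Long tandem repeats (a unit of ≤ 6 bp repeated ≥ 3 consecutive times over
≥ 12 bp, e.g. `CTCCCT` runs or `ACACACACACACAC`) tile spurious motif
matches; hits falling fully inside such regions are excluded before
merging. Masking removes hits, never length — $L$ is always the full
candidate length. Detection is automatic (`detect_tandem_repeats`), and a
user-supplied mask (or `mask = NA` to disable) overrides it.

### Interpretation of the score thresholds

The published thresholds are described as "JASPAR score > 10 / > 11". The
JASPAR *relative* score is bounded by 1, so values above 10 can only be
the raw log-odds score column of the JASPAR scanner; `crmscan` therefore
applies the cuts to the raw score, and emits both columns so either
reading can be applied downstream. The cuts, the relative threshold, the
merge window and the density cuts are all `classifier_config` fields.

### Merge-rule convention

"Starts within 5 bp count once" does not say whether a chain of hits is
measured from the cluster's first hit or from the previous hit. The
default is anchor-based (distance to the cluster's first hit), which makes
the count independent of how ties are ordered; neighbour-based chaining is
available via `classifier_config(chain = "neighbor")`. The window is
inclusive: starts 0 and 5 merge.

## Peak nomination

Candidates for a gene of interest are accessibility peaks in the region
from the end of the nearest upstream gene body to the start of the nearest
downstream gene body — *including* the gene's own body, because validated
CRMs can sit in introns (intragenic, non-exonic peaks stay eligible).
A peak seeds at any local signal maximum with tip value ≥ 20 and extends
to the outermost contiguous positions with signal ≥ 20% of that tip
("reached 20%" is read closed on the ≥ side; the emitted interval is
half-open). Overlapping extents merge, keeping the higher tip; on a
plateau the tip position is the leftmost maximum. Any peak sharing ≥ 1 bp
with any exon of any gene is excluded. The boundary comparison carries a
1e-9 slack so that exact fractions of the tip are not flipped by binary
representation.

Coverage input is bedGraph or wiggle (fixedStep/variableStep), read
through `rtracklayer`; uncovered positions read as zero. BigWig sources
should be converted to bedGraph at the I/O boundary.

## Marker and TF selection

Cells with < 20% mitochondrial reads and > 900 detected genes are kept —
both bounds strict, so a cell at exactly 20% or exactly 900 genes is
removed. Counts are log-normalised per cell
($\ln(1 + c/\text{total} \times 10^4)$). For a target cluster versus all
other cells, genes expressed in ≥ 25% of either group are tested with a
two-sided Wilcoxon rank-sum on the log-normalised values; the fold change
is the ratio of mean expression on the linear depth-normalised scale
(`expm1` of the log-normalised values, the standard single-cell
convention — under which a 16-fold planted marker shows log2FC ≈ 4,
whereas means of log-scale values would compress it to ≈ 1.2). A gene
passes at log2FC > 2 and p < 0.05; no multiple-testing correction enters
the decision (a BH column is emitted for information). Passing markers
intersected with a TF list form the TF panel that drives the density scan.

The rank-sum p-value is exact (the Wilcoxon distribution) for tie-free
pooled samples up to 50; small tied samples are enumerated exhaustively
while $\binom{n}{n_a} \le 2 \times 10^5$; larger problems use the normal
approximation with tie and continuity corrections. Identical pooled
values give p = 1.

## Stitching designer

For a gene without a usable TF panel: peaks are called per developmental
stage (e.g. retina P1, P7, 8 weeks), unioned across stages (overlaps
merged, higher tip and concatenated provenance kept), filtered against a
second tissue (≥ 1 shared bp with any other-tissue peak rejects a
candidate; the threshold is configurable), exon-filtered, and the
survivors concatenated in ascending genomic start order on the forward
strand — a fixed convention recorded in the FASTA header, since the
published schematics do not state order or strand. No spacer is inserted
by default. The budget check is
`stitched + cargo + overhead ≤ 4700 bp`; overhead (ITRs, promoter, polyA)
defaults to 0 and should be supplied by the user.

## What the simulators emulate — and what they do not

`simulate_preset` generates every input the pipeline consumes, with truth
tables in the same 0-based half-open, forward-anchored coordinates the
analysis uses:

- **Sequences** (`plant_sequence`): i.i.d. background at a chosen GC
  content (default 0.40, roughly mammalian non-coding) with motif sites
  written at known positions/strands. Real genomes have repeats,
  CpG islands and conservation structure that this does not mimic.
- **Motifs** (`make_profile`): single-consensus PFMs with a sharpness
  knob (consensus fraction of N = 100 counts per column). Real JASPAR
  matrices have heterogeneous information content across columns.
- **Coverage** (`make_coverage`): analytic triangular / gaussian /
  plateau shapes on a zero baseline, optional gaussian noise. Truth
  boundaries are the analytic 20%-of-tip crossings, so noise-free
  recovery must be exact. Real ATAC tracks have autocorrelated,
  signal-dependent noise.
- **Expression** (`make_expression`): negative-binomial counts
  (dispersion $\alpha$, variance $\mu + \alpha\mu^2$; default mean 2,
  $\alpha = 0.5$), planted markers as mean multipliers, optional
  mitochondrial load injection. No batch effects, doublets or dropout
  beyond the NB zeros.

Passing tests on these generators demonstrates that the *statistics and
rules* are implemented exactly as specified, not that the thresholds
themselves transfer to any particular real dataset — the thresholds are
the published operating point, kept as defaults.

The `mg-demo` preset fixes the study-like conditions for the classifier
check: a panel of four sharp 10-bp motifs, 12 candidates with 18 planted
sites per 500 bp (merged density 3.6 per 100 bp, at least twice either
cut) and 12 motif-free decoys. At scan threshold 0.80 a background window
needs ≥ 8/10 consensus matches to be reported at all and ≥ 9/10 to pass
the raw-score cuts, so the decoy false-hit density is far below the cuts;
the tests and the acceptance script *measure* it rather than assume zero.

## Numerical and degenerate-input choices

- `N` bases score the column minimum, so ambiguity can only lose hits.
- Hit output order is fixed as (start, motif id, strand with `+` before
  `-`), independent of locale, for byte-reproducible output.
- Hits partially overlapping a repeat-mask interval are kept; only fully
  contained hits are dropped (conservative).
- An overlapping neighbour gene clips that side's flank to zero length
  with a warning; a missing neighbour uses the chromosome edge.
- Zero-length sequences, empty profile lists, all-cells-removed QC and
  degenerate clusters are explicit errors; empty hit lists, empty masks
  and empty peak sets are valid empty results.
- Reproducibility: `crm_prescreen` output files contain a `# key=value`
  header echoing every threshold, and a manifest with input MD5s and the
  package version; no timestamps, so reruns are byte-identical.

## Problem sizes

The bundled tests and the acceptance script use deliberately small
problems chosen to exercise every rule exactly: sequences of 20–500 bp,
panels of 1–4 motifs, 2-kb coverage tracks over 50 random loci, count
matrices of 300–800 genes × 120–400 cells, and 24-candidate prescreen
demos. All are regenerated from seeds at run time; nothing is downloaded
or stored.

## Known limitations

- TFBSs are weighted equally; weighting by affinity/activity is out of
  scope (and was explicitly deferred by the strategy this implements).
- No dinucleotide or higher-order background for motif scoring, and no
  p-value calibration of motif scores.
- Peak calling is the tip/boundary rule, not a statistical caller; read
  alignment and upstream peak calling are out of scope.
- Clustering of the expression matrix is an input (labels), not computed.
- The quadrant labels A1/A3/A4 outside the active quadrant A2 are a fixed
  but arbitrary convention (A1 high-y, A4 high-x, A3 neither).
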