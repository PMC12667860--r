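---
title: "Delimiting a minimal mRNA localization signal: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting a minimal mRNA localization signal: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locsig)
```

## The problem

Many mRNAs are trafficked to specific subcellular compartments by
*cis*-acting elements in their 3' untranslated regions. In
oligodendrocytes, *Mbp* mRNA is transported into cellular projections and
translated locally at the myelin sheath, a behavior conferred by its
~1.5-kb 3' UTR. `locsig` implements the computational side of a
three-assay strategy for finding and validating the minimal element
responsible:

1. a **compartment reporter assay**: a library of reporters carrying
   sheared fragments of the UTR is expressed in cells grown on a porous
   transwell, RNA is sequenced separately from the cell-body and
   projection compartments (plus the input plasmid pool), and every
   sub-sequence window of the UTR is scored for projection enrichment;
2. **in-cell DMS structure probing** (DMS-MaPseq), whose per-position
   mutation rates are normalized into reactivities that report
   single-strandedness and let a called element be checked for defined
   structure;
3. **single-molecule FISH imaging** of reporter constructs, scored per
   cell for RNA localization and for translational output (EGFP per RNA
   molecule).

The package takes aligned reads (BED), mutation/coverage count tables
(TSV) and segmented-cell records as inputs; alignment, spot detection and
segmentation are upstream tools' business. A seeded generator simulates
all three data types with known ground truth, so the whole pipeline is
testable end to end with no external data.

## Rolling-window enrichment

For a reference UTR of length $L$ the grid holds windows of $w = 250$ nt
every $s = 5$ nt: starts $0, s, 2s, \dots$ while the window still fits
(`make_windows`; 251 windows for $L = 1500$). Partial windows are never
emitted — the statistic is defined for fixed-size windows only.

Let $c^{(k)}_i$ be the number of reads of sample
$k \in \{\text{input}, \text{body}, \text{proj}\}$ that fall **entirely**
within window $i$ (containment is strict; reads are never clipped; a read
longer than $w$ counts nowhere). Compartment counts are normalized by the
input library,

$$ n^{(k)}_i = c^{(k)}_i / c^{(\text{input})}_i, $$

and the track is the scaled difference

$$ e_i = \frac{n^{(\text{proj})}_i - n^{(\text{body})}_i}
              {\max_j \left( n^{(\text{proj})}_j - n^{(\text{body})}_j \right)}, $$

so $\max_i e_i = 1$ whenever any window has a positive difference. Two
guards are ours: windows with input counts below `min_input` (default 10
reads) are masked rather than divided by a near-zero denominator, and a
track with no positive difference is scaled by the maximum absolute
difference with a warning instead of dividing by a non-positive maximum.
The sign convention (projection-minus-body) is explicit and flippable
(`sign = "body"`), since "enrichment" in a transwell experiment depends
on which membrane face one calls positive.

### Calling regions, and why there is a "core" refinement

`call_regions` selects windows with $e_i \ge f \cdot \max_j e_j$
(default $f = 0.5$; the cutoff is a fraction of the maximum because the
max-1 scaling makes the track scale-free) and by default merges
overlapping selected windows into maximal intervals. That union answers
"where is the enriched signal?", but it cannot delimit an element
*smaller* than one window: a union of 250-nt windows is at least 250 nt
long.

The assay's own logic supports a sharper statement. A window is enriched
only if enriched fragments fit entirely inside it, and a fragment is
enriched only if it carries the whole element — so every sufficient
window must contain the element, and the element must lie in the
**intersection** of the qualifying windows. `call_regions(refine =
"core")` returns, per merged block, the span common to all of the
block's qualifying windows. On default synthetic runs the union call is
~350-400 nt (IoU with a 127-nt element around 0.35-0.40) while the core
is ~150-180 nt and contains the element (IoU typically 0.7-0.85). The
core is what `run_discovery` reports as the candidate minimal signal; a
core is only defined while a block's qualifying starts span less than
one window, and wider blocks fall back to their union.

The same subtraction logic drives `minimal_signal`: nucleotides covered
by regions shown sufficient but by no insufficient region. On the
packaged annotation coordinates — sufficient reporter windows 520-770 and
525-775, insufficient 400-650 and 405-655 (1-based) — the difference is
656-775 (120 nt). This deliberately under-reaches the packaged 650-776
element annotation: the published 5' boundary also drew on the probed
secondary structure, which this window-only computation does not model.
The pipeline reports the window-derived interval and leaves
structure-boundary integration to the analyst.

## DMS reactivity normalization

Raw rates are mutations/coverage wherever coverage reaches
`coverage_floor` (default 500 reads — below that, rate estimates at
typical DMS mutation frequencies of 0.5-5% are noise-dominated; the
floor is configurable). G and U (T in DNA-alphabet references) are always
masked: DMS adducts at those bases give poor signal-to-noise in live-cell
probing.

Normalization is per base (A and C separately) in a sliding 50-nt window
centered on each position and *shifted*, not shrunk, at the sequence
ends, so every factor rests on a full-width window. Within a window the
valid same-base rates are boxplot-normalized in the Low-Weeks
convention: values above $Q_3 + 1.5\,\mathrm{IQR}$ (type-7,
linear-interpolation quantiles) are discarded as outliers and the
normalization factor is the mean of the top 10% (at least one value) of
the remainder; the position's reactivity is its raw rate over that
factor. The published description names the boxplot scheme but not the
quantile rule or outlier handling; we adopt this convention as the
standard one behind the cited tooling and document it as our choice.
Windows offering fewer than 10 valid same-base rates leave their
positions invalid rather than normalizing on a sliver of data.
Reactivities are **not capped**; the output metadata records this
(`params$capped = FALSE`), since some downstream folding engines expect
capped inputs.

Two properties pin the implementation down and are tested against an
explicit-loop oracle: scale invariance (multiplying all rates by $c > 0$
leaves reactivities unchanged) and locality (a position's reactivity
depends only on rates within its window).

`structure_agreement` validates the stage on synthetic data: the
rank-based concordance $P(\text{reactivity}_{\text{unpaired}} >
\text{reactivity}_{\text{paired}})$ (ties half-weighted) between valid
positions of the two classes of a known dot-bracket structure. At the
default generator settings (rates 0.005 paired / 0.05 unpaired, 5000x
coverage) concordance is ~0.97.

## smFISH localization and translation scoring

Per cell, with $n_{\text{out}}/n_{\text{in}}$ spots outside/inside the
body mask and pixel areas $A_{\text{cell}} \ge A_{\text{body}}$:

$$ \text{raw} = n_{\text{out}} / n_{\text{in}}, \qquad
   \text{adjusted} = \text{raw} \Big/
   \frac{A_{\text{cell}} - A_{\text{body}}}{A_{\text{body}}}, $$

and all adjusted scores are divided by the **median** adjusted score of
the negative-control condition (a reporter with no 3' UTR), making the
control median exactly 1. "Projection area" is taken as cell-minus-body
area — the segmentation-derived quantity available without a separate
projection mask. Cells with no body spots or no projection area are
excluded with a logged reason, not imputed: a continuity correction
would silently bias small cells. A spot is "inside" iff its pixel
carries the body label; the label decides boundary cases.

Translation output is EGFP intensity over spot count (EGFP per RNA
molecule); whether the upstream pipeline supplies integrated or mean
intensity is its choice — the score is a per-cell scalar ratio either
way. Condition summaries use medians throughout, and fold changes
(control over condition, so suppression scores above 1) carry
case-resampling bootstrap percentile intervals (default 1000 replicates,
resampling cells independently within control and condition). Medians
and percentile intervals are the right match for skewed per-cell ratios
and were preferred over means and normal-theory intervals.

## The synthetic generator

`synthetic_truth` fixes the study conditions; its defaults are the
desk-scale geometry of the assay being emulated and are not tuned
per-analysis:

| parameter | default | what it emulates |
|---|---|---|
| `utr_length` | 1500 nt | the ~1.5-kb UTR |
| `element` | 1-based 650-776 (127 nt) | the known localization signal |
| `fragment_size_range` | 200-400 nt | the sheared cloning insert size |
| `n_fragments` | 5000 | distinct library fragments |
| `enrichment_factor` | 8 | projection sampling weight of element-carrying fragments |
| `depths` | 100k/100k/100k | reads per sample |
| `mu_paired`, `mu_unpaired` | 0.005 / 0.05 | DMS rates (10x contrast) |
| `coverage` | 5000x | DMS read depth |
| `p_outside` | 0.10 control / 0.40 element / 0.15 element-deleted | spot placement |
| `translation_scale` | 20 / 4 / 8 | EGFP per RNA (5x and 2.5x suppression) |

Reads are multinomial over fragments at each sample's depth; only
fragments containing the **entire** element get the projection weight
(partial overlap confers nothing), which reproduces the sharp
sufficiency boundary the window comparison exploits. The physical
library behind the emulated assay had ~270 clones; we default to 5000
fragments because the clone-sampling process is not specified
computationally and a denser library separates fragment-placement noise
from the statistic under test while staying desk-scale. DMS counts are
binomial per position under a seeded random hairpin structure (~50%
paired). Cells are concentric-disc body/cell masks with log-normal
areas (body ~200 px, projection/body ratio ~2), Poisson spot counts
(mean 40), Bernoulli spot placement, and log-normal EGFP noise (sdlog
0.3). A single root seed derives fixed per-generator child seeds, so
adding a generator never perturbs another's stream.

What the generator does **not** model — sequencing error, PCR
duplicates, alignment artifacts, replicate structure, 3-D cell geometry,
segmentation error — bounds what green tests mean: they demonstrate the
statistics recover known truth under the assumed noise model, not that
the assays themselves are unbiased on real data.

## Numerical and degenerate-input choices

- Coordinates are 0-based half-open internally (BED-compatible);
  human-facing reports are 1-based inclusive, converted only at the
  boundary by an exact inverse pair of helpers.
- Reads and windows are treated as sense-strand; antisense alignments
  are assumed filtered upstream (reporter inserts are directional).
- BED columns beyond the name are ignored, tolerating converter
  dialects; malformed coordinates fail with the line number.
- `simulate_dms_counts` requires positive coverage (the truth object
  enforces all depths and coverage positive), and the fold-change
  summary requires at least 5 cells per condition.
- All-masked enrichment tracks and control-free cell sets are errors,
  not silent empties; an all-zero difference track is returned unscaled.

## Problem sizes

The shipped tests run the full default assay scale (100k reads/sample,
5000 fragments, 5000x coverage, 50 cells/condition) for the 20-seed
recovery suites and a reduced scale (20k reads, 1200 fragments, 12
cells) where only mechanics are under test; the whole suite completes in
under a minute on one core.

## Known limitations

- The core refinement assumes a single dominant element per qualifying
  block; two elements closer than one window width merge into one call.
- Input normalization presumes the input library covers every window;
  sparse custom libraries will mask heavily at the default `min_input`.
- The reactivity stage stops at normalized reactivities; reactivity-
  guided folding belongs to dedicated structure-prediction tools.
- Bootstrap intervals are percentile, not BCa; with n = 50 cells per
  condition and median statistics they are adequate but slightly
  narrow in the tails.
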