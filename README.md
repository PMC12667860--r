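# locsig

Discovery and validation of minimal mRNA localization signals from
compartment reporter assays, in-cell RNA structure probing, and
single-molecule FISH imaging.

## The problem

Localized mRNAs — such as *Mbp* mRNA, which is transported into
oligodendrocyte projections and translated locally at the myelin sheath —
carry *cis*-acting elements in their 3' UTRs. Delimiting the minimal
element requires combining orthogonal assays: a massively parallel
reporter assay that scores every UTR sub-sequence for compartment
enrichment, structure probing to check the element folds, and per-cell
imaging to confirm localization and measure translational output.
`locsig` implements the quantification for all three, plus a seeded
synthetic-data generator with known ground truth so the entire pipeline
runs and is tested without any external data.

## The statistics

**Rolling-window enrichment.** Windows of 250 nt every 5 nt tile the
reference UTR. For window *i* and sample *k* (input plasmid pool,
cell-body RNA, projection RNA), *c⁽ᵏ⁾ᵢ* counts reads falling *entirely*
inside the window. Compartments are normalized by the input,
*n⁽ᵏ⁾ᵢ = c⁽ᵏ⁾ᵢ / c⁽ⁱⁿᵖᵘᵗ⁾ᵢ*, and the track is the per-window difference
scaled to a maximum of 1:

    eᵢ = (n⁽ᵖʳᵒʲ⁾ᵢ − n⁽ᵇᵒᵈʸ⁾ᵢ) / maxⱼ (n⁽ᵖʳᵒʲ⁾ⱼ − n⁽ᵇᵒᵈʸ⁾ⱼ)

Candidate regions are windows above a fraction of the maximum, merged
(`call_regions`); the `refine = "core"` mode intersects the qualifying
windows to delimit elements smaller than one window, and
`minimal_signal` subtracts insufficient regions from sufficient ones.

**DMS reactivity.** Per-position mutation rates (mutations/coverage,
coverage floor 500) are boxplot-normalized per base (A and C; G/U
masked) in a sliding 50-nt window: outliers above Q3 + 1.5·IQR removed,
factor = mean of the top 10% of the rest, reactivity = rate/factor,
uncapped. `structure_agreement` reports the paired-vs-unpaired
rank concordance against a known structure.

**smFISH scoring.** Per cell: raw = spots outside / spots inside the
body; adjusted = raw / ((cell − body area)/body area); normalized so the
negative-control median is exactly 1. Translation output is EGFP
intensity per RNA spot; condition summaries are medians with
control/condition fold changes and case-resampling bootstrap percentile
CIs.

## Worked example

```r
library(locsig)
res <- run_discovery(default_config(seed = 7))
print(res)
```

```
<locsig_run>
<slap_track> 251 windows of 250 nt every 5 nt on utr (1500 nt)
  sign: projection-positive; masked windows: 0 of 251
  peak window: 586-835 (1-based), enrichment 1.000
  called regions: 1 (union), 1 (core)
  candidate minimal signal (1-based):
    636-800 (165 nt)
  reactivity/structure concordance: 0.977
Translation output by condition (control: no_utr)
  condition n_cells median_signal fold_change  ci_lo ci_hi
     no_utr      50        19.960       1.000 0.8571 1.168
        mls      50         4.045       4.935 4.1380 5.696
 utr_no_mls      50         8.351       2.390 2.1460 3.047
```

The simulated experiment embeds a 127-nt element at 650-776 (1-based)
with an 8-fold projection enrichment factor. The peak 250-nt window
(586-835) overlaps it; the core-refined candidate region (636-800,
165 nt) contains it and delimits it well below window resolution. The
reactivity/structure concordance of 0.977 means a random unpaired
position out-scores a random paired one 97.7% of the time. The imaging
stage recovers the generative translation suppression: the
element-carrying reporter's output is ~4.9-fold below the no-UTR control
(truth: 5), the element-deleted UTR ~2.4-fold (truth: 2.5), with
bootstrap CIs covering both.

On published window coordinates, the interval logic reproduces the
worked comparison directly:

```r
minimal_signal(mls_annotation("sufficient"), mls_annotation("insufficient"))
#   ref_id start end name first last length
#  Mbp_3utr  655 775 <NA>   656  775    120
```

A thin CLI wraps the same functions
(`Rscript inst/cli/locsig.R enrich --input ... --body ... --projection
... --ref-fasta ...`; subcommands `simulate`, `enrich`, `reactivity`,
`fishscore`, `run`, `report`).

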