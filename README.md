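# ggaaswitch

Quantifying the GGAA microsatellite **enhancer-class switch** in Ewing
sarcoma: how loss of the cohesin subunit STAG2 redistributes the EWS-FLI1
fusion transcription factor from short (monomeric, 1x GGAA) toward long
(multimeric, ≥5x/≥10x GGAA) repeat enhancers, and how the resulting
repeat-length–specific gene signatures stratify patient survival.

The package is aimed at computational genomicists who have standard
epigenomic inputs — a genome FASTA, peak intervals (BED) with per-peak
signal counts, replicate chromatin-loop calls (bedPE-style), gene/TSS
models, differential-expression tables, expression matrices and survival
tables — and want a tested, reproducible implementation of the full
analysis, plus a synthetic-data generator with planted ground truth that
exercises every stage without any downloads.

## What it computes

* **Repeat scanning** — every maximal tandem run of the exact `GGAA`
  string (optionally `TTCC` as minus-strand blocks); a block with *k*
  consecutive units is a "*k* x GGAA" element, and peaks are classified by
  their largest overlapping run into `0x / 1-4x / 5-9x / >=10x`.
* **Differential binding by class** — per-peak counts normalized to 16 M
  reads, log2 fold-changes `log2((mean_T + 1)/(mean_C + 1))`, peaks
  partitioned into lost/retained/gained and cross-tabulated by repeat
  class.
* **Consensus loops and enhancer→gene maps** — loops kept only when both
  replicates support them within a matching tolerance; genes are assigned
  to an enhancer peak when a consensus loop connects the peak's anchor to
  the gene's promoter (1.5 kb upstream of the TSS) on the other anchor.
* **Repeat-class gene signatures** —
  `10x promoter`: promoter peaks with `max_run >= 10` and `Fold > 0.5`;
  `1x promoter`: promoter peaks with `max_run == 1` and `Fold < -1`,
  intersected with genes down-regulated upon FLI1 knockdown
  (`logFC < 0`, adj. p < 0.05); `10x / 1x enhancer`: the same predicates
  applied through consensus loops.  A prognostic refinement intersects
  the combined 10x signature with genes carrying a positive univariate
  Cox coefficient for overall survival, and a STAG2-inactivation activity
  signature collects genes concordantly differential across ≥2
  STAG2-knockdown model systems.  (All folds are log2.)
* **Scoring and survival** — per-sample single-sample GSEA (ssGSEA,
  exponent α = 0.25), top/bottom-quartile signature-high/low strata
  (matching the ~25% prevalence of STAG2 alterations), Kaplan–Meier
  curves, median survival and log-rank comparison of high vs low.

## Worked example

A single command simulates a complete study (genome with planted repeats,
two-condition peak counts, replicate loops, expression, survival), runs the
full pipeline and compares everything against the planted truth:

```r
library(ggaaswitch)
run_demo(seed = 1)
```

```
Synthetic enhancer-class-switch demonstration (seed 1)
  signature Jaccard vs planted: 10x_promoter=1.00, 1x_promoter=0.92, 10x_enhancer=1.00, 1x_enhancer=1.00
  mean log2FC by repeat class: >=10x=+0.96, 0x=-0.00, 1-4x=-0.72, 5-9x=+0.48
  ssGSEA shift (latent-high - latent-low): 10x_promoter=+0.421, 10x_enhancer=+0.355, 1x_promoter=-0.404, 1x_enhancer=-0.390
  median survival high=10.1 low=85.1 months; log-rank p=4.2e-15
  all recovery checks passed
```

Reading the output: the four derived signatures recover the planted gene
sets (Jaccard ≥ 0.9); mean binding fold-change rises monotonically with
repeat class (short repeats lose, long repeats gain — the class switch);
samples with a high latent STAG2-loss factor score higher on the 10x
signatures and lower on the 1x signatures; and the prognostic-score-high
quartile has far shorter survival than the score-low quartile.

The underlying stages are ordinary functions — e.g.

```r
st   <- simulate_study(seed = 1)
bl   <- scan_fasta(st$fasta)                  # maximal GGAA runs
prof <- profile_intervals(st$peaks, bl)       # per-peak repeat profile
res  <- run_full(st)                          # everything downstream
res$stratification$contingency                # status x repeat-class table
```

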