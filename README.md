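# xbias

Analysis of the chromosomal distribution of sex-biased gene expression in
*Drosophila melanogaster* and its relationship with dosage compensation.

## The problem

Genes expressed differently between males and females (sex-biased genes) are
not placed randomly in the genome. In *D. melanogaster*, whole-fly and
gonad comparisons show a *paucity* of male-biased genes (MBG) on the X
chromosome ("demasculinization"), while the brain shows the opposite — a
strong *excess* of X-linked MBG. One proposed explanation involves the
dosage compensation complex (DCC/MSL), which roughly doubles transcription
of the single male X: genes close to DCC binding sites can be
*overcompensated* (upregulated by more than 2-fold in males, creating weak
male bias without any sex-specific regulation), while genes that need
strong male-specific upregulation are hindered near DCC sites and tend to
sit far from them.

`xbias` implements the full analysis chain needed to test these ideas on
any per-tissue male/female expression comparison, plus a ground-truth
simulator that encodes the overcompensation mechanism so every stage is
testable without external downloads. It is aimed at researchers analysing
sex-biased expression who have per-gene differential-expression output from
any upstream tool (DESeq2, edgeR, limma, microarray pipelines) and want the
chromosomal-distribution and DCC-proximity statistics.

## What it computes

For each data set, with gene classes `MBG` / `FBG` / `UBG` assigned by
significance (BH–FDR or nominal-p dialect) and the sign of
log2(male/female):

- **X-linkage enrichment** — observed X-linked count per class, expectation
  `E[X] = n_class · n_X / n_total`, the O/E ratio, and a Fisher exact test
  of the class-vs-rest 2×2 table.
- **DCC proximity** — the minimum endpoint distance between each X-linked
  gene's transcriptional unit and the nearest binding site (zero on
  overlap), per DCC component (MLE, MSL-1/2/3, MOF, and HAS derived by
  MLE∩MSL-2 colocalization); Spearman's ρ between log2(M/F) and distance;
  per-class median distances with Wilcoxon rank-sum tests.
- **Bias magnitude** — fold-change bins (≤2, 2–4, 4–6, >6-fold) and the
  per-bin distance profile.
- **Tissue specificity** — the τ index,
  τ = Σᵢ (1 − xᵢ/x_max) / (N − 1) ∈ [0, 1], with probe collapsing and
  tissue exclusion/averaging; housekeeping (τ < 0.4) and specific
  (τ > 0.7) flags.
- **Dosage summaries** — RPKM, X:A median male expression ratios under
  expression/housekeeping filters, per-component expression (mean ± SEM),
  mean gene age (classes 0–6), hypergeometric gene-set overlaps, and
  remove-and-recompute enrichment.

## Worked example

Simulate a brain-like data set (overcompensation near DCC sites, no
sex-specific regulation), classify genes and run the pipeline:

```r
library(xbias)

sim <- simulate_dataset(brain_like_config(seed = 42))
de  <- de_table_from_counts(sim$counts, sim$meta)
report <- run_dataset(dataset_config(
  "brain-like", de, sim$genes, sites = list(MLE = sim$sites),
  threshold = threshold_config("NOMINAL_P", alpha = 0.05)))
report
#> <xbias_report> data set: brain-like
#>   expressed genes: 2000
#>   class counts:
#>  call count_autosome count_x pct_x
#>   MBG             31      35    53
#>   FBG             38       7    16
#>   UBG           1611     278    15
#>   proximity (per component):
#>  component   n        rho        rho_p median_mbg median_fbg median_ubg
#>        MLE 320 -0.4582051 5.143648e-18       1935      15370      10823
#>  wilcoxon_p_mbg_vs_ubg
#>           1.901669e-10
```

Only 16% of the simulated genes are X-linked, yet 53% of the detected MBG
are on the X (O/E = 3.3, Fisher p = 1.5e-12 via `glance(report)`), and the
male/female ratio falls with distance from the nearest DCC site
(ρ = −0.46): the pipeline recovers the enrichment-plus-proximity signature
that overcompensation produces, and `sim$truth` exposes the per-gene
ground truth behind it. `gonad_like_config()` generates the opposite
regime (strong sex-regulated genes far from sites), which yields ρ > 0 and
an X paucity of MBG.

Published per-tissue class counts for 14 male/female comparisons ship with
the package (`dmel_sexbias_counts()`), ready for `x_enrichment()`.

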