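# lpsclass

Integrated RNA-seq + ATAC-seq analysis of macrophage responses to
lipopolysaccharide (LPS) under BET bromodomain inhibition.

When bone marrow-derived macrophages (BMDMs) are stimulated with LPS, a BET
inhibitor such as (+)-JQ1 reshapes the transcriptional response: some genes
stay fully inducible, others are attenuated or pushed below their
unstimulated baseline, and the chromatin near the attenuated genes loses its
LPS-induced accessibility gains at distal (enhancer-like) elements carrying
AP-1 and IRF motifs. `lpsclass` packages the full analytical chain used to
make statements of that kind, with a seeded synthetic-data generator so every
stage can be validated against planted ground truth:

* a minimal **negative-binomial differential engine**: median-of-ratios size
  factors, per-feature method-of-moments dispersion
  (`Var = μ + αμ²`), Wald contrasts and likelihood-ratio tests with
  small-sample-calibrated references, BH FDR, a shifted-log VST proxy and
  top-variance PCA — applied identically to gene and peak counts;
* the **two-cluster / ten-class response classification**: from the three
  pairwise contrasts A = LPS vs unstim, B = LPS+JQ1 vs unstim,
  C = LPS+JQ1 vs LPS, each LRT-eligible gene (FDR < 0.05, baseMean ≥ 10) is
  placed in Cluster 1 (relatively higher with JQ1, `C.log2FC > 0`) or
  Cluster 2, then into classes I–X by an explicit, configurable decision
  table over significance and log₂FC of A and B;
* **chromatin integration**: strand-aware promoter annotation
  (−1000/+100 bp around the TSS), distal peak-to-gene linkage within
  ±25 kb, DAR calling (FDR < 0.05, |log₂FC| bins 0.5/1), hypergeometric
  DAR-per-class enrichment, 2×2 chi-square, paired Wilcoxon and Spearman
  helpers;
* **motif analysis**: JASPAR/MEME parsing, log-odds PWM scanning of central
  500 bp DAR windows on both strands, sequence-level hypergeometric motif
  enrichment against sampled non-DAR background, and Ncor-based motif
  similarity clustering (thresholds: width ≥ 5, r ≥ 0.7, Ncor ≥ 0.4);
* a **synthetic-data generator** producing NB counts with planted response
  classes, ATAC peaks with planted DARs near genes of a chosen class, and
  peak sequences with planted AP-1 consensus instances.

## Worked example

```r
library(lpsclass)

report <- run_pipeline(list(sim = sim_config(seed = 1)))
report
#> <lps_report> v0.1.0, config ec9c00676a82d8f918fdaeb88c3c90ff
#> genes: 2000 (1043 eligible); peaks: 7000 (681 DARs, 4000 links)
#> truth recovery: class 98%, cluster 100%

glance(report$summary)
#> # A tibble: 1 x 5
#>   n_total n_eligible n_unassigned cluster1 cluster2
#> 1    2000       1043            0      384      659

report$dar_enrichment |> dplyr::filter(class == "VI")
#> # A tibble: 1 x 8
#>   class     k     K     n     N  fold         p      padj
#> 1 VI      336   677   658  4000  3.02 1.22e-115 1.22e-114
```

The 2,000 simulated genes carry planted response classes in the printed
per-class proportions for half the transcriptome; 1,043 pass the LRT
eligibility gate, every eligible gene receives a class (no unassigned), 98%
of the planted classes and 100% of the planted clusters are recovered, and
the distal peaks near class VI genes — where the generator concentrates
differential accessibility — are strongly enriched for DARs
(336 of 658 class-linked peaks vs 677 of 4,000 overall, fold 3.0).

The report also carries the three pairwise contrasts and the LRT
(`report$contrasts`), per-peak DAR flags, ±25 kb peak–gene links, and the
motif enrichment of central DAR windows (the planted AP-1 motif ranks first;
unrelated library motifs stay at padj > 0.1). Individual stages are plain
functions over data frames — `size_factors()`, `wald_contrast()`,
`assign_classes()`, `annotate_peaks()`, `motif_enrichment()`, … — and
compose with the pipe; results are tibbles with `tidy()`/`glance()`/
`autoplot()` methods.

## Vignette

`vignettes/lpsclass-methods.Rmd` describes the statistical model, the
decision table, the small-sample calibration choices, what the generator
does and does not emulate, and known limitations.
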