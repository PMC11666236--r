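# perturbEHT

Analysis toolkit for inducible CRISPR-activation (CRISPRa) perturbation
single-cell RNA-seq during the endothelial-to-haematopoietic transition
(EHT), for researchers steering human iPSC differentiation toward blood
progenitors. It covers the full computational arc of such a study:

- **Candidate TF discovery** across an in vivo / in vitro dataset pair:
  Wilcoxon rank-sum markers of arterial haemogenic endothelium (aHEC)
  with BH adjustment, filtered to transcription factors detected in
  > 50% of aHEC cells and < 25% of in vitro-derived endothelium.
- **Guide-capture cell assignment**: per-cell guide detection at a UMI
  threshold, with library-specific keep rules (control cells keep iff
  exactly one guide; high-MOI activation cells iff more than one).
- **Preprocessing**: 10x-style MatrixMarket I/O, QC gates (1000–7500
  genes, 1–15% mitochondrial), per-cell normalisation + log1p,
  PCA/kNN/Louvain clustering, and marker-panel cluster annotation
  (arterial GJA4/DLL4, venous NRP2/APLNR, haemogenic RUNX1/CD44).
- **Perturbation statistics**: target activation as carrier-restricted
  log2(+DOX/−DOX) means; cluster-composition tests (chi-square with
  exact fallback) with a directional expansion flag; per-target Fisher
  guide-enrichment within a cluster; rank-sum differential expression;
  hypergeometric gene-set over-representation on user-supplied GMT sets.
- **Seahorse ATP partitioning** from OCR/ECAR traces:
  `mito_atp = (OCR_basal − OCR_oligo) × 2 × 2.75`,
  `per = ECAR_basal × 2.6 × 2.28 × 1.1`,
  `glyco_atp = per − (OCR_basal − OCR_rot) × 0.5`, with totals, the
  Mito/Glyco ratio, and strict invalid-well handling.
- **A ground-truthed synthetic-data generator** emulating the whole
  design — four perturbation libraries (iSAM_NT / iSAM_AGM, ± DOX), a
  49-guide pool over nine targets with one planted null, arterial
  expansion on induction (1.63× control line, 3.33× activation line), an
  IGFBP2-like effector driven by RUNX1T1-class guides, reference panels
  with planted detection fractions, and Seahorse traces — so every
  stage can be validated against planted truth.

See `vignettes/perturbEHT-methods.Rmd` for the models, parameter
defaults and design decisions.

## Worked example

```r
library(perturbEHT)

# simulate the default study design and run the full pipeline
sim <- simulate_perturbation_experiment(sim_config(seed = 1))
res <- run_perturbation_pipeline(sim)

round(res$activation$log2_ratio[, "AGM"], 2)
#> RUNX1T1   NR4A1   GATA2   SMAD7  ZNF124    SOX6  ZNF33A   NFAT5   TFDP2
#>    0.99    1.09    0.97    1.05    0.17    0.88    1.13    0.99    1.04

res$composition$table
#>    cluster            p        p_adj fold_change flagged
#> 1 arterial 6.688992e-61 2.006697e-60   1.6774345    TRUE
#> 2      EHT 6.129983e-04 6.129983e-04   0.9214263   FALSE
#> 3   venous 1.402412e-17 2.103618e-17   0.8374044   FALSE

subset(res$enrichment, flagged, c(unit, odds_ratio, p_adj))
#>      unit odds_ratio        p_adj
#> 4 RUNX1T1   3.303943 5.030523e-17

head(res$de, 2)[, c("gene", "lfc", "p_adj")]
#>      gene       lfc        p_adj
#> 18 IGFBP2 1.3774252 3.913946e-15
#> 17  TFDP2 0.9974555 2.127693e-04
```

Reading the output: the eight responsive targets come back around
log2 ≈ 1 (the planted 2-fold activation) while the planted null
(ZNF124) stays near 0; only the arterial cluster is flagged as expanded
in the induced activation library versus the induced control; only
RUNX1T1-class guides are enriched among arterial cells; and the planted
effector (IGFBP2) is the top-ranked upregulated gene in the arterial
contrast.

The ATP module reproduces the hand-computable partitioning: phase means
(100, 40, 20) with basal ECAR 30 give `ocr_atp = 60`,
`mito_atp = 330`, `per = 195.624`, `glyco_atp = 155.624`,
`total_atp = 485.624`, ratio ≈ 2.12 pmol ATP/min.

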