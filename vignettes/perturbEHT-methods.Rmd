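---
title: "Models and methods behind perturbEHT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind perturbEHT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

perturbEHT analyses inducible CRISPR-activation (CRISPRa) perturbation
scRNA-seq of human pluripotent stem cells differentiating through the
endothelial-to-haematopoietic transition (EHT), together with the Seahorse
XF ATP-rate partitioning used to characterise the metabolic state of the
resulting cells. This vignette is the package's own account of the models
it implements, the tunable parameters that matter, and the design
decisions taken where the underlying procedures are conventionally left
open.

## The experimental design being modelled

Two iPSC lines carrying a doxycycline-inducible SAM activator are
profiled at day 10 of differentiation: a control line with a single
non-targeting guide (`iSAM_NT`) and an activation line transduced at
MOI 10 with a 49-guide pool covering nine transcription-factor targets
(5–7 promoter-proximal guides each; `iSAM_AGM`), each with and without
DOX. Guide identity is read out per cell through a capture sequence in
the guide scaffold, alongside the transcriptome. The nine targets
themselves come from a cross-dataset comparison: markers of in vivo
arterial haemogenic endothelium (aHEC, versus arterial and venous
endothelium from the same embryos) that are transcription factors,
detected in more than 50% of aHEC cells and in less than 25% of in
vitro-derived endothelial cells.

## Candidate discovery

`find_markers()` uses a two-sided Wilcoxon rank-sum test per gene with
Benjamini–Hochberg adjustment — the standard default for scRNA-seq
marker detection — computing the exact (permutation) null distribution
for small tie-free groups and the tie-corrected normal approximation
otherwise. Effect sizes are log2 fold-changes of group means on the
de-logged normalised scale, stabilised by a pseudocount of
`1/target_sum`.

`select_candidates()` applies four gates: BH-adjusted marker
significance (`alpha = 0.05`), membership in a user-supplied
transcription-factor list (an input file rather than a live ontology
query, for reproducibility), and the two detection-fraction gates.
"Detected" means a raw count above zero. Both fraction inequalities are
strict (`> 0.50`, `< 0.25`), the literal reading of "more than" and
"less than"; the boundary behaviour is unit-tested. Fractions are
computed within each dataset separately on raw detection — detection
fractions are integration-free, so no cross-dataset anchoring is needed
for the gates; only the marker ranking depends on normalisation. This is
a deliberate simplification of a merged-and-normalised analysis and is
the package's contract-level reading of that step.

## Guide assignment

`detect_guides()` calls a guide present in a cell when its capture count
reaches `min_umi`. The default is 1 (detection = any count), because the
upstream chemistry reports detection rather than abundance; the
simulated capture model (below) separates true from ambient counts
cleanly at `min_umi = 3`, which is what `run_perturbation_pipeline()`
uses and what a threshold sweep on the generator recommends. Cells
present in the expression matrix but missing from the capture matrix are
treated as zero-guide cells and reported as such.

`filter_cells_by_guides()` implements the library-specific keep rules:
control (NT) cells are kept iff exactly one guide is detected; activation
(AGM) cells iff more than one, reflecting the high-MOI design. Multi-
target cells remain assigned to all their targets — no winner-takes-all —
since the analysis downstream treats carriage as a set property.

## Preprocessing

QC keeps cells with 1000–7500 detected genes and 1–15% mitochondrial
counts by default, both bounds inclusive (the conventional reading of a
printed range); mitochondrial genes are symbols matching `^MT-`
(GRCh38 convention), configurable. Normalisation scales each cell to
10,000 counts and applies `log1p`.

Clustering is PCA (top 200 highly variable genes by trend-corrected
variance — the residual of log-variance against a lowess trend on
log-mean, so genuinely structured genes outrank merely deep ones — 10
components) followed by a k-nearest-neighbour graph (k = 15) and Louvain
community detection; the resolution is exposed and weakly increases the
cluster count. Cells are processed in a canonical (sorted-barcode)
order internally, which makes the partition invariant to the column
order of the input. No claim is made of reproducing any particular
cluster count on real data — algorithm, resolution, PC count and HVG
selection are all config-exposed choices.

`annotate_clusters()` scores each cluster by the mean z-scored
expression of each marker panel — arterial (GJA4, DLL4), venous (NRP2,
APLNR), haemogenic/EHT (RUNX1, CD44) — and assigns the best panel, with
exact ties resolved by panel priority order (arterial first) and
repeated labels suffixed (`EHT_1`, `EHT_2`).

## Perturbation statistics

**Activation.** `activation_matrix()` averages de-logged normalised
expression of each target per library, restricting activation-library
means to carrier cells of that target (non-carriers dilute the signal;
a flag restores library-level means). Each +DOX entry is the log2 ratio
to its matched −DOX entry within the same line, with pseudocount
`1/target_sum`; a target with zero eligible cells is flagged missing,
never zero.

**Composition.** Each cluster is tested for association between
membership and library (chi-square on the 2×L table, exact when any
expected count is ≤ 5 — the boundary is inclusive so that fully sparse
tables always go exact), BH-adjusted across clusters. Because population
fractions are compositional, a genuine expansion of one cluster
necessarily depresses every other cluster's proportion, and at a few
thousand cells those complementary shifts are also statistically
significant. The `flagged` column therefore additionally requires the
cluster to be *expanded* (fold ≥ 1.25 by default) in a focal library
pair (induced activation versus induced control, matching the
directional claim being tested); the full p-value and fold columns are
always reported so a pure significance reading remains available.

**Enrichment.** `guide_enrichment()` tests each target (guides pooled by
default; per-guide mode for diagnostics) with a Fisher exact test on
carrying-the-target × cluster-membership, BH across targets, sample odds
ratios with Haldane correction when a cell is zero. Flagging requires
enrichment (OR > 1), not depletion.

**Differential expression.** The same rank-sum machinery as marker
detection, over two disjoint cell sets, ordered by adjusted p then
effect; `gene_set_overrepresentation()` is a hypergeometric test of an
input list against user-supplied GMT sets within an explicit universe
(no live pathway-database access).

## ATP-rate partitioning

`compute_atp_rates()` implements the printed arithmetic exactly: with
per-well phase means (three reads averaged per phase),

- `ocr_atp = ocr_basal − ocr_oligo`
- `mito_atp = ocr_atp × 2 × 2.75` (oxygen consumption rate × P/O)
- `mito_per = (ocr_basal − ocr_rot) × 0.5` (CO₂ contribution)
- `per = ecar_basal × 2.6 × 2.28 × 1.1` (buffer factor × volume × Kvol)
- `glyco_atp = per − mito_per`, `total_atp = glyco_atp + mito_atp`,
  `ratio = mito_atp / glyco_atp`

Units are pmol ATP/min. Note that `mito_per` as printed uses total
mitochondrial OCR (basal − rotenone), not ATP-linked OCR; some published
conventions differ, and the package implements the printed formula
without attempting to resolve that discrepancy. The ECAR entering the
proton efflux rate is the basal-phase mean (the Agilent-consistent
reading; configurable). Wells violating `basal ≥ oligo ≥ rot` are
flagged invalid and excluded with a reason — silent clamping would hide
assay failures. No cell-number normalisation is applied by default
(densities are assumed comparable across wells); a per-well divisor can
be added trivially upstream.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study
conditions under which the pipeline's recovery claims are made.

*Expression.* Counts are negative binomial per gene (shared dispersion
2), with background means log-normal around 0.3 and marker programs as
population-specific mean overrides on that shared baseline — the
simplest structure that makes clustering and annotation well-posed.
Three populations (arterial 10%, venous 60%, EHT 30%) carry the marker
structure above, plus pan-endothelial PECAM1/CDH5 everywhere, lowered in
EHT. Thirteen `MT-` genes at mean 4 give mitochondrial fractions around
5%, inside the QC gates.

*Perturbation.* DOX induction multiplies the arterial base fraction by
1.63 (control line) or 3.33 (activation line), renormalised across
populations — the reported quantity is a fold-expansion of a fraction,
not absolute counts. Eight targets are activated 2-fold in carrier cells
of the induced activation library; ZNF124 is the planted null at fold 1.
The IGFBP2-like effector is induced 3-fold in arterial cells carrying
RUNX1T1-class guides, and those guides are sampled with double weight in
arterial cells of the induced library, planting the guide-enrichment
signal.

*Guides.* Activation-line cells draw a zero-truncated Poisson(10) number
of guides — the infection was at MOI 10, and the realised guides-per-cell
distribution is not an inferred quantity, so this is a configuration
choice, not a claim. True guides get NB(mean 50, size 4) capture counts;
ambient background hits each cell × guide entry with probability 0.01 at
1 + Poisson(0.3) counts. This makes the detection-threshold decision
testable: at `min_umi = 1` ambient noise produces false detections, at
`min_umi = 3` assignments match planted truth in ≥ 95% of cells, and with
ambient noise off and `min_umi = 1` the match is exact.

*Reference panels.* The in vivo panel (aEC 35%, vEC 35%, aHEC 30%) and
in vitro panel (IVD_Endo 70%, IVD_HPC 30%) plant the nine candidate TFs
at detection probability 0.7 in aHEC and 0.1 in vitro (0.2 in the other
in vivo populations), with NB means solved from the detection
probability. Two non-TF decoys share the planted profile so the TF gate
is exercised; ten extra TFs sit at uniform background detection so the
marker and fraction gates are exercised.

*Seahorse.* Per condition, three wells × three reads per phase with
additive Gaussian noise; the effector-treated condition lowers ECAR
(reduced glycolysis) with preserved respiration, so the glycolytic ATP
rate drops and the Mito/Glyco ratio rises. Zero-noise traces pass the
configured means straight through to the arithmetic.

*Determinism.* Every generator seeds the R RNG from `config$seed`;
identical configurations give bit-identical outputs. Two-timepoint
designs (day-10/day-13 analogues, ± effector treatment) are composed by
running the generator once per condition and concatenating the outputs
under a condition label; no separate machinery is needed.

*What the generator does not model* — and hence what passing tests do
not show about real data: no read-level simulation, no doublets, no
ambient-RNA transcriptome contamination, no batch effects, no
cross-dataset batch structure in the reference panels, and marker
programs are additive mean shifts rather than correlated modules. Results
on real data depend on upstream choices (alignment, cell calling) that
are out of scope here.

## Problem sizes and calibration

The recovery properties are stated under the default study conditions:
four libraries × 2,000 cells × 2,000 genes for the perturbation design,
2,000 cells per reference panel, evaluated over 20 seeds. Null
calibration of the composition and enrichment tests uses 100 seeds of an
effect-free configuration at 500 cells/library and a 600-gene panel —
the type-I error of those tests does not depend on the effect-free
sample size, and the smaller draws keep the calibration loop quick.
These sizes are the package's own validation choices.

## Known limitations

- The marker test, significance cutoffs, and the composition/enrichment
  test choices are explicit stand-ins for unnamed conventions in the
  workflow being modelled; all are exposed as parameters.
- The rank-sum normal approximation is conservative for heavily tied
  sparse genes at very small n; the exact path covers small tie-free
  groups only.
- The direction-gated composition flag answers "which clusters
  expanded?", not "which clusters changed?"; use the reported p-values
  for the latter.
- Guide assignment trusts the capture matrix after thresholding; no
  barcode-collision or index-hopping correction is attempted.
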