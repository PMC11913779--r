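# ICIwindow

Biomarker discovery for window-of-opportunity immune-checkpoint-inhibitor
(ICI) trials in gastro-esophageal cancer.

Window trials give a rare view of what ICI does to a tumor on its own:
patients receive a four-week ICI-only window ("ICI-4W") before
immunochemotherapy, with tumor biopsies profiled before (PreTx) and at the
end of the window. This package implements, as tested and reusable
components, the three biomarker axes such a trial supports — for
computational biologists and trial statisticians who want to run or stress
the same analyses on their own or simulated cohorts:

* **On-treatment T/NK signature.** Median-of-ratios normalization,
  empirical-Bayes moderated *paired* differential expression
  (posterior variance $(d_0 s_0^2 + d s^2)/(d_0+d)$, BH FDR < 0.1),
  a top-70 gene signature, per-patient upregulation scores
  ("scaled, without centering"), reactive/quiescent stratification,
  noise-robust compact subsets, and preranked GSEA (weighted
  Kolmogorov–Smirnov ES, gene-permutation null, NES by same-sign null
  pools) against moderated-LFC or outcome-correlation rankings.
* **Tumor composition.** Cell-type reference profiles from labeled single
  cells (3000 most-variable genes, confounder gene classes excluded),
  non-negative least-squares deconvolution on the linear scale, RNA-to-cell
  fraction conversion via per-type RNA content, an 80-sample pseudobulk
  ground-truth benchmark (per-sample Spearman ρ and NRMSE = RMSE/range on
  both fraction scales, pluggable method registry), tumor monocyte content
  (TMC) extraction, Ward (`ward.D`) compartment clustering, and spike-in
  validation of the TMC readout.
* **Genomics and survival.** 2-of-3 caller consensus filtering; TMB =
  nonsynonymous coding mutations per 35.6 Mb averaged over biopsies; MSI at
  score ≥ 3.5; amplification (> 2× ploidy) / deletion (loss > half
  baseline) calls; irRECIST-style response and 12-month clinical-benefit
  classification; Kaplan–Meier, log-rank, Efron-corrected Cox on scaled
  log10(TMC) and TMB, cell-type survival screens with BH correction, median
  splits and TMB×TMC quadrant analysis.

A synthetic-cohort generator (`simConfig()`, `simulateSingleCellReference()`,
`simulatePseudobulkPanel()`, `simulateCohort()`, `simulateSpikeIn()`)
produces every input with known ground truth — negative-binomial single
cells with marker structure, bulk mixtures with known RNA/cell fractions,
responder-specific signature upregulation, and proportional-hazards
survival in z(log10 TMC) and z(TMB) — so every stage is testable end to
end. See `vignettes/biomarker-workflow.Rmd` for the models, defaults and
design decisions.

## Worked example

```r
library(ICIwindow)
cfg <- simConfig(seed = 11)   # defaults documented in the vignette
out <- runPipeline(cfg)
out$signature
head(out$tmc, 3)
out$cox
```

```
GeneSignature 'INCITE-like': 70 genes (66 up, 4 down)
  top: G0208, G0169, G0166, G0155, G0163
      sample        tmc   log10Tmc floored
1 P001_PreTx 0.06267657 -1.2028948   FALSE
2 P002_PreTx 0.05330165 -1.2732593   FALSE
3 P003_PreTx 0.25355586 -0.5959263   FALSE
  term   beta    se    hr    lo    hi  pvalue
1  tmc -0.812 0.284 0.444 0.254 0.774 0.00424
2  tmb -1.019 0.351 0.361 0.181 0.719 0.00373
```

The 70-gene signature is dominated by the simulated T/NK markers (genes
G0141–G0210 carry the true treatment effect), the deconvolved TMC tracks
each patient's generative monocyte content, and the multivariable Cox fit
recovers protective per-SD hazard ratios for both TMC and TMB on this
35-patient cohort. (At n = 35 a median-split log-rank is underpowered
compared with the continuous Cox fit — here `out$logrankOS` gives p ≈ 0.5
— which is why the parameter-recovery checks below use 200-patient
cohorts.)

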