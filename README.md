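# temiR

Translation efficiency and the magnitude of miRNA-mediated repression.

MicroRNAs silence their targets through mRNA decay and translational
repression, but the *depth* of translational repression varies enormously
between targets. temiR is an R package for the analysis that explains much
of that variation: messages that are translated efficiently before the
miRNA arrives are the ones most strongly repressed at the translational
level, while miRNA-driven mRNA decay is insensitive to translation
efficiency. The package is aimed at people analysing paired ribosome
profiling (RPF) and RNA-seq libraries from miRNA perturbation experiments,
and at people who want a fully specified synthetic benchmark for such
analyses.

## What it computes

For a mock and a miRNA-transfected condition with RPF and RNA-seq counts:

- **rpkM** per library, `1e9 * count / (length * library_total)`, and
  **translation efficiency** `TE = rpkM_RPF / rpkM_RNA` in the mock
  condition (RPF over CDS length, RNA over transcript length).
- **log2 fold changes** of RPF and RNA (miRNA over mock), with strict
  count filters and no pseudocounts.
- **Seed-site classification** of 3'UTRs for a mature miRNA: 8mer,
  7mer-m8, 7mer-a1 and 6mer sites, each occurrence reported once at its
  highest class.
- **TE stratification**: median-half or quartile TE bins of predicted
  targets, per-bin fold-change medians, empirical CDFs, and all pairwise
  two-sample Kolmogorov–Smirnov tests.
- **tAI**: tRNA adaptation index weights from a tRNA gene-copy table
  (standard wobble s-values), per-gene tAI, genome-wide distributions, and
  synonymous CDS redesign toward a target tAI.
- **A TE-augmented model** of RPF fold change (least squares on
  `fc_rna`, `fc_rna^2`, optionally `log TE` and its interaction) compared
  with and without TE by seeded 5-fold cross-validation.
- **A synthetic study generator**: transcriptomes with planted seed
  sites, lognormal abundance and TE, and negative-binomial mock/miRNA
  count tables in which decay scales with site count and translational
  repression additionally scales with TE rank — the ground-truth testbed
  for everything above.

## Worked example

```r
library(temiR)

study <- simulateStudy(simParams(nGenes = 5000, seed = 1))
records <- repressionRecords(study$tables$rpf_mock, study$tables$rpf_mir,
                             study$tables$rna_mock, study$tables$rna_mir)
utrs <- setNames(as.character(study$transcriptome@utr3),
                 geneIds(study$transcriptome))
annotation <- classifyTargets(utrs, study$mirna)
teTruth <- setNames(study$truth$te, study$truth$gene_id)

strat <- stratifiedComparison(records, annotation, assay = "RPF",
                              binning = "median", te = teTruth)
strat$bins
#>   label   n  median_fc
#> 1   Low 976 -0.1573329
#> 2  High 976 -0.5508723
strat$ks
#>   bin1 bin2         D p
#> 1  Low High 0.2110656 0
```

High-TE targets lose ~0.55 log2 units of ribosome occupancy versus ~0.16
for low-TE targets (KS p < 1e-15): translational repression scales with
how well the message was translated. The same call with `assay = "RNA"`
shows medians of −0.15 and −0.18 with KS p ≈ 0.36 — the decay channel is
TE-blind. Adding TE to the fold-change model raises the cross-validated
Pearson r from 0.11 to 0.17 on the same folds:

```r
recModel <- records
recModel$te <- unname(teTruth[recModel$gene_id])
compareFcModels(recModel, seed = 1)$delta_r_cv
#> [1] 0.06212125
```

Binning uses the simulator's true TE here; the methods vignette
(`vignettes/te-and-mirna-repression.Rmd`) explains why a TE estimate taken
from the same mock libraries as the fold changes is not a calibrated
stratification variable, along with the generative model, filter
conventions, and tAI conventions.

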