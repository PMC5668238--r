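---
title: "Translation efficiency and the magnitude of miRNA-mediated repression: methods"
author: "temiR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translation efficiency and the magnitude of miRNA-mediated repression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(temiR)
```

# The question and the quantities

MicroRNAs repress their targets through two channels: mRNA decay and
translational repression. A recurring observation in ribosome-profiling
experiments is that the *magnitude* of translational repression varies
widely between targets, and that much of this variation tracks how well
the message was being translated before the miRNA arrived. temiR
implements the quantitative machinery needed to ask that question of
paired ribosome-protected-fragment (RPF) and RNA-seq libraries from a
mock and a miRNA-transfected condition:

* **rpkM** — reads per kilobase of feature per million mapped reads,
  $10^9 \, c / (L \, N)$ for count $c$, feature length $L$ (nt) and
  library total $N$. Each library is normalised against its own total.
* **Translation efficiency (TE)** — the mock-condition ratio
  $\mathrm{TE} = \mathrm{rpkM}_{\mathrm{RPF}} / \mathrm{rpkM}_{\mathrm{RNA}}$,
  a per-gene proxy for how efficiently the message is translated. RPF
  rpkM uses the CDS length, RNA rpkM the mature transcript length (a
  single shared length can be supplied instead).
* **Fold change** — $\log_2$ of the miRNA-to-mock rpkM ratio, computed
  separately for RPF (translational output) and RNA (message level).
* **Seed sites** — canonical target classes on the 3'UTR sense strand:
  6mer (match to miRNA positions 2–7), 7mer-a1 (6mer plus an A opposite
  position 1), 7mer-m8 (match to positions 2–8), 8mer (7mer-m8 plus the
  A), with the affinity hierarchy 8mer > 7mer-m8 > 7mer-a1 > 6mer.
* **tAI** — the tRNA adaptation index: per-codon adaptiveness from tRNA
  gene copy numbers with wobble penalties, gene score the geometric mean
  over sense codons.

The analysis proper stratifies the fold change of predicted targets by
TE (median halves or quartiles), compares the strata with two-sample
Kolmogorov–Smirnov tests, and asks — via a small regression family —
whether TE improves prediction of the RPF fold change beyond what the
RNA fold change already explains.

# Count filtering and zero handling

Genes must reach a minimum raw count (default 10, `minCount`) in every
library entering a derived quantity; failing genes are excluded, never
imputed. No pseudocounts are used anywhere: a pseudocount shrinks large
negative fold changes and would bias exactly the TE-bin medians the
analysis reports. A zero rpkM among a gene's required values likewise
excludes the gene, so no infinities propagate.

# The synthetic study

`simulateStudy()` generates the full experiment the pipeline consumes,
and is the basis of every statistical test in the package. Per gene
$g$:

* abundance $a_g \sim \mathrm{Lognormal}(\mu_a, \sigma_a)$ with
  defaults $\mu_a = 3$, $\sigma_a = 1.5$ (log scale), the span typical
  of bulk RNA-seq;
* true efficiency $\mathrm{TE}_g \sim \mathrm{Lognormal}(0, 0.5)$,
  roughly the interquartile spread seen in HeLa ribosome profiling;
* expected mock counts
  $\mathbb{E}[\mathrm{RNA}] \propto a_g L_{\mathrm{tx}}$ and
  $\mathbb{E}[\mathrm{RPF}] \propto a_g \mathrm{TE}_g L_{\mathrm{CDS}}$,
  scaled so each library sums to its declared depth (default $10^7$);
* for targets, the miRNA condition applies
  $\Delta_{\mathrm{RNA}} = -\delta \cdot (\#\text{sites})$ and
  $\Delta_{\mathrm{RPF}} = \Delta_{\mathrm{RNA}} -
  \beta \cdot \mathrm{rank01}(\mathrm{TE}_g) \cdot \sum_i w_{\mathrm{site},i}$
  in log2 units, with site weights $1, 0.75, 0.5, 0.25$ for
  8mer, 7mer-m8, 7mer-a1, 6mer;
* counts are negative binomial with variance $m + \phi m^2$ and a
  single dispersion $\phi$ (default 0.1) across genes — the simplest
  model consistent with bulk count data.

Defaults are 5000 genes, 40% targets, $\delta = 0.25$ per site and
$\beta = 1$. No published effect-size scale exists for this generative
model; $\delta$ and $\beta$ are calibration choices fixed once, sized
so that the decay and translational channels are of the same order and
the TE gradient spans about one log2 unit across the TE range. The
TE coupling uses the rank of TE scaled to $[0,1]$ rather than raw TE,
so $\beta$ has a bounded, distribution-free meaning; only a monotone
relationship is asserted biologically. Most targets carry one site
(site count $1 + \mathrm{Poisson}(0.25)$), and the per-type mix
(0.15 / 0.35 / 0.30 / 0.20 for 8mer / 7mer-m8 / 7mer-a1 / 6mer) follows
the usual preponderance of 7mers among predicted sites.

Sequences are random DNA at a requested GC fraction; CDS are built from
sense codons with an ATG start and single stop. Before planting,
*every* 3'UTR is re-sampled until it contains no chance seed match, so
truth labels are exact; planted sites travel with guard bases that pin
their detected class, and each plant is verified by re-detection.
Each output table draws from its own RNG stream derived from the master
seed.

What the generator does **not** emulate: positional ribosome profiles
and read-level artifacts (no FASTQ or alignment), replicate structure,
gene-specific dispersion, 3'-supplementary pairing, co-targeting by
other miRNAs, and sequence-composition biases. Passing tests therefore
demonstrate correctness of the statistical machinery under a known
truth, not robustness to every property of real libraries.

# A calibration subtlety: estimated TE shares noise with the fold change

TE is estimated from the same mock libraries that enter the fold
changes, so the sampling noise of the mock RPF count appears in both
$\widehat{\mathrm{TE}}$ (positively) and the measured RPF fold change
(negatively). Stratifying or modelling on $\widehat{\mathrm{TE}}$
therefore produces a spurious association with repression even when
none was simulated — a regression-to-the-mean coupling. At the default
dispersion the effect is large: under a null simulation
($\beta = \delta = 0$), the cross-validated model gain from adding
estimated TE is around +0.4 in Pearson r, and TE-bin KS tests reject
far above their nominal level.

The package's calibration and power analyses therefore bin and model on
a TE measure *independent* of the fold-change noise — in simulations,
the generator's true TE. For real data the equivalent is estimating TE
from libraries (or replicates) disjoint from those used for the fold
change; with a single mock library per assay, TE-stratified repression
analyses should be interpreted with this coupling in mind. The
diagnostic is easy to run here because the simulator provides both
versions of TE.

# Statistical choices

* **KS tests** use the exact sup-difference statistic and the
  asymptotic Kolmogorov p-value with effective size
  $n_x n_y / (n_x + n_y)$; intended bin sizes are in the hundreds. A
  seeded permutation p-value is available for small samples
  (`method = "permutation"`).
* **Quantile bins** are rank-based; ties share the bin of their mean
  rank and an exact-median value goes to the low bin (deterministic and
  immaterial at genomic n). All-identical input yields a single bin
  with a warning.
* **Bin medians** are exact sample medians (mean of the middle pair for
  even n).
* **The model family** replaces free-form symbolic regression with a
  fixed least-squares family: predictors
  $\{fc_{\mathrm{RNA}}, fc_{\mathrm{RNA}}^2\}$, plus
  $\{\log \mathrm{TE}, fc_{\mathrm{RNA}} \cdot \log \mathrm{TE}\}$ when
  TE is included. The reported comparison is the 5-fold cross-validated
  Pearson r between measured and predicted RPF fold change, both arms
  on identical seeded folds. In-sample r is monotone in predictor-set
  inclusion by construction; the CV contrast is the honest comparison.

# tAI conventions

Weights follow the standard wobble constraint set
($s_{G:U} = 0.41$, $s_{I:C} = 0.28$, $s_{I:A} = 0.9999$,
$s_{U:G} = 0.68$). Eukaryote mode is the default: the bacterial
lysidine rule for ATA is disabled and ATG/TGG take only their
Watson–Crick decoder. Every sense codon including the initiator enters
the geometric mean (`dropFirstCodon` flips this, since conventions
differ between implementations). Codons with zero raw adaptiveness
receive the geometric mean of the nonzero weights — prominent for
sparse toy tables, where it changes results materially.

CDS redesign toward a target tAI is steepest-feasible greedy on
synonymous swaps (ties to the lowest codon index, seeded shuffle among
exact ties), with restarts from the all-maximal, all-minimal and seeded
random assignments if the first pass stalls outside tolerance. The
attainable range is reported, unattainable targets error, and the
encoded protein is asserted unchanged.

# Problem sizes and determinism

The bundled statistical checks run the simulator at 5000 genes for the
headline stratification (with 100 count-level replicates reusing one
transcriptome), 2000 genes for the 200-replicate null calibration and
the 100-replicate model-direction runs, and a few hundred genes for
unit fixtures — sizes at which every quantity of interest is stable yet
the whole suite completes in about a minute. All randomness flows from
explicit seeds; identical parameters give byte-identical fixtures.

# Known limitations

* The composition effect of within-library normalisation is real and
  reproduced: with 40% of genes repressed, per-library scaling shifts
  all fold changes upward by a common constant (~0.1 log2 units at the
  defaults). Bin contrasts are unaffected; absolute medians are not
  comparable across target fractions.
* Conservation of sites is consumed from external annotation
  (TargetScan-style tables), never computed.
* MFE values are consumed precomputed; only the per-nucleotide
  normalisation (MFE density) is implemented, with a pluggable
  normaliser for regression-residual variants.
* Real-data reproduction of published medians depends on unstated
  upstream filter conventions of the original count processing; the
  package exposes `minCount` and the length conventions but does not
  guess beyond them.
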