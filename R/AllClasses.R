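#' @import methods
#' @importFrom stats cor ks.test median quantile rbinom rlnorm rnbinom
#'   rpois runif coef lm predict complete.cases sd fitted setNames
#' @importFrom utils read.delim write.table head combn packageVersion
#' @importFrom graphics hist
NULL

SITE_TYPES <- c("8mer", "7mer-m8", "7mer-a1", "6mer")

# canonical hierarchy weights used by the simulator's repression model;
# only the ordering 8mer > 7mer-m8 > 7mer-a1 > 6mer is biologically fixed
SITE_WEIGHTS <- c("8mer" = 1, "7mer-m8" = 0.75, "7mer-a1" = 0.5, "6mer" = 0.25)

#' Simulation parameters for the synthetic ribosome-profiling experiment
#'
#' Container for all parameters of the generative model: a transcriptome of
#' \code{nGenes} genes with lognormal abundance and translation efficiency
#' (TE), a fraction of genes carrying planted miRNA seed sites, and paired
#' mock / miRNA-transfection RPF and RNA-seq libraries drawn from a
#' negative-binomial model in which mRNA decay scales with site count and
#' translational repression additionally scales with the TE rank of the gene.
#'
#' @slot nGenes number of genes.
#' @slot targetFraction fraction of genes receiving at least one seed site.
#' @slot siteTypeMix named probabilities over site types
#'   (\code{8mer}, \code{7mer-m8}, \code{7mer-a1}, \code{6mer}); must sum to 1.
#' @slot muAbundance,sigmaAbundance meanlog/sdlog of the lognormal gene
#'   abundance \eqn{a_g}.
#' @slot sigmaTe sdlog of the lognormal true translation efficiency
#'   \eqn{TE_g} (meanlog 0).
#' @slot deltaDecay per-site mean RNA log2 decrease \eqn{\delta} in the
#'   miRNA condition.
#' @slot betaTe coupling \eqn{\beta} of translational repression to the
#'   within-transcriptome TE rank (rank01 in [0,1]).
#' @slot dispersion negative-binomial dispersion \eqn{\phi > 0}
#'   (variance \eqn{m + \phi m^2}).
#' @slot depthRpf,depthRna expected library sizes of each RPF / RNA table.
#' @slot seed master RNG seed; every output table derives its own stream.
#' @slot lengthParams list with integer ranges \code{utr5}, \code{cds},
#'   \code{utr3} (nt); CDS lengths are snapped to multiples of 3.
#' @slot gc GC fraction of simulated sequences.
#' @export
setClass("SimParams", representation(
  nGenes = "integer",
  targetFraction = "numeric",
  siteTypeMix = "numeric",
  muAbundance = "numeric",
  sigmaAbundance = "numeric",
  sigmaTe = "numeric",
  deltaDecay = "numeric",
  betaTe = "numeric",
  dispersion = "numeric",
  depthRpf = "numeric",
  depthRna = "numeric",
  seed = "integer",
  lengthParams = "list",
  gc = "numeric"
))

setValidity("SimParams", function(object) {
  msg <- character()
  if (object@nGenes < 1) msg <- c(msg, "nGenes must be >= 1")
  if (object@targetFraction < 0 || object@targetFraction > 1)
    msg <- c(msg, "targetFraction must be in [0,1]")
  mix <- object@siteTypeMix
  if (!setequal(names(mix), SITE_TYPES))
    msg <- c(msg, "siteTypeMix must be named over the four site types")
  else if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
    msg <- c(msg, "siteTypeMix probabilities must be >= 0 and sum to 1")
  for (p in c("sigmaAbundance", "sigmaTe", "dispersion", "depthRpf",
              "depthRna")) {
    if (slot(object, p) <= 0) msg <- c(msg, paste(p, "must be > 0"))
  }
  if (object@deltaDecay < 0) msg <- c(msg, "deltaDecay must be >= 0")
  if (object@gc <= 0 || object@gc >= 1) msg <- c(msg, "gc must be in (0,1)")
  lp <- object@lengthParams
  if (!all(c("utr5", "cds", "utr3") %in% names(lp)))
    msg <- c(msg, "lengthParams needs ranges utr5, cds, utr3")
  else {
    for (r in c("utr5", "cds", "utr3")) {
      rng <- lp[[r]]
      if (length(rng) != 2 || any(rng < 1) || rng[1] > rng[2])
        msg <- c(msg, paste("invalid length range for", r))
    }
    if (length(lp$cds) == 2 && any(lp$cds %% 3 != 0))
      msg <- c(msg, "cds length range must be multiples of 3")
    if (length(lp$cds) == 2 && lp$cds[1] < 9)
      msg <- c(msg, "cds must be at least 9 nt (start + one codon + stop)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct simulation parameters
#'
#' Defaults encode the study conditions used throughout the package:
#' 5000 genes, 40\% targets, decay effect \eqn{\delta = 0.25} per site,
#' TE coupling \eqn{\beta = 1}, NB dispersion \eqn{\phi = 0.1}, and
#' 1e7-read libraries.
#'
#' @param nGenes,targetFraction,siteTypeMix,muAbundance,sigmaAbundance
#'   see \linkS4class{SimParams}.
#' @param sigmaTe,deltaDecay,betaTe,dispersion,depthRpf,depthRna,seed
#'   see \linkS4class{SimParams}.
#' @param lengthParams,gc see \linkS4class{SimParams}.
#' @return A \linkS4class{SimParams} object.
#' @examples
#' sp <- simParams(nGenes = 100, seed = 7)
#' sp
#' @export
simParams <- function(nGenes = 5000L,
                      targetFraction = 0.4,
                      siteTypeMix = c("8mer" = 0.15, "7mer-m8" = 0.35,
                                      "7mer-a1" = 0.3, "6mer" = 0.2),
                      muAbundance = 3,
                      sigmaAbundance = 1.5,
                      sigmaTe = 0.5,
                      deltaDecay = 0.25,
                      betaTe = 1,
                      dispersion = 0.1,
                      depthRpf = 1e7,
                      depthRna = 1e7,
                      seed = 1L,
                      lengthParams = list(utr5 = c(50L, 300L),
                                          cds = c(300L, 2400L),
                                          utr3 = c(100L, 1500L)),
                      gc = 0.5) {
  new("SimParams",
      nGenes = as.integer(nGenes), targetFraction = targetFraction,
      siteTypeMix = siteTypeMix[SITE_TYPES],
      muAbundance = muAbundance, sigmaAbundance = sigmaAbundance,
      sigmaTe = sigmaTe, deltaDecay = deltaDecay, betaTe = betaTe,
      dispersion = dispersion, depthRpf = depthRpf, depthRna = depthRna,
      seed = as.integer(seed), lengthParams = lengthParams, gc = gc)
}

setMethod("show", "SimParams", function(object) {
  cat("SimParams:", object@nGenes, "genes,",
      sprintf("%.0f%% targets", 100 * object@targetFraction), "\n")
  cat(sprintf("  delta = %.3g, beta = %.3g, phi = %.3g, seed = %d\n",
              object@deltaDecay, object@betaTe, object@dispersion,
              object@seed))
})

#' Mature microRNA
#'
#' Holds a mature miRNA sequence, 5' to 3'. The seed is positions 2-8
#' (1-based from the 5' end); U and T are treated as equivalent and the
#' sequence is stored in DNA alphabet.
#'
#' @slot name miRNA name.
#' @slot seq mature sequence (DNA alphabet, length >= 8).
#' @export
setClass("MiRNA", representation(name = "character", seq = "character"))

setValidity("MiRNA", function(object) {
  s <- object@seq
  if (nchar(s) < 8) return("mature sequence must be at least 8 nt")
  if (grepl("[^ACGT]", s)) return("sequence alphabet must be A,C,G,U/T")
  TRUE
})

#' @param name miRNA name.
#' @param seq mature sequence 5'->3', RNA or DNA alphabet.
#' @return A \linkS4class{MiRNA} object.
#' @examples
#' mir155 <- miRNA("hsa-miR-155-5p", "UUAAUGCUAAUCGUGAUAGGGGU")
#' @rdname MiRNA-class
#' @export
miRNA <- function(name, seq) {
  new("MiRNA", name = name, seq = asDna(seq))
}

setMethod("show", "MiRNA", function(object) {
  cat("MiRNA", object@name, ":", object@seq, "\n")
  cat("  seed (2-8):", substr(object@seq, 2, 8), "\n")
})

#' Per-gene counts and rpkM for one assay/condition
#'
#' One sequencing library: raw counts and feature lengths per gene, with
#' rpkM normalised against the table's own library total
#' (\eqn{10^9 \cdot count / (length \cdot total)}).
#'
#' @slot assay \code{"RPF"} or \code{"RNA"}.
#' @slot condition \code{"mock"} or \code{"mir"}.
#' @slot genes data.frame with columns \code{gene_id}, \code{count},
#'   \code{length}, \code{rpkm}.
#' @export
setClass("ExpressionTable", representation(
  assay = "character", condition = "character", genes = "data.frame"))

setValidity("ExpressionTable", function(object) {
  msg <- character()
  if (!object@assay %in% c("RPF", "RNA"))
    msg <- c(msg, "assay must be RPF or RNA")
  if (!object@condition %in% c("mock", "mir"))
    msg <- c(msg, "condition must be mock or mir")
  g <- object@genes
  need <- c("gene_id", "count", "length", "rpkm")
  if (!all(need %in% names(g)))
    msg <- c(msg, paste("genes must have columns",
                        paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(g$gene_id)) msg <- c(msg, "duplicate gene_id")
    if (any(g$count < 0)) msg <- c(msg, "negative count")
    if (any(g$length <= 0)) msg <- c(msg, "non-positive feature length")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ExpressionTable", function(object) {
  cat(sprintf("ExpressionTable %s/%s: %d genes, %.3g reads\n",
              object@assay, object@condition, nrow(object@genes),
              sum(object@genes$count)))
})

#' @describeIn ExpressionTable-class library total (sum of raw counts).
#' @param x an \code{ExpressionTable}.
#' @export
libraryTotal <- function(x) sum(x@genes$count)

#' @describeIn ExpressionTable-class the per-gene table as a data.frame.
#' @export
geneTable <- function(x) x@genes

#' @describeIn ExpressionTable-class assay label.
#' @export
assayType <- function(x) x@assay

#' @describeIn ExpressionTable-class condition label.
#' @export
conditionType <- function(x) x@condition

#' tRNA adaptation index weights
#'
#' Per-codon absolute (W) and relative (w) adaptiveness computed from a
#' tRNA gene-copy table with wobble-pairing selective constraints
#' (s-values). \code{max(w) == 1}; zero weights are replaced by the
#' geometric mean of the nonzero weights before use.
#'
#' @slot W named numeric, absolute adaptiveness per sense codon.
#' @slot w named numeric, relative adaptiveness in (0,1] per sense codon
#'   (zeros already substituted).
#' @slot sValues the wobble s-values used.
#' @export
setClass("TaiWeights", representation(
  W = "numeric", w = "numeric", sValues = "numeric"))

setValidity("TaiWeights", function(object) {
  if (abs(max(object@w) - 1) > 1e-12) return("max(w) must be 1")
  if (any(object@w <= 0)) return("w must be > 0 after zero substitution")
  TRUE
})

setMethod("show", "TaiWeights", function(object) {
  cat(sprintf("TaiWeights over %d sense codons; mean w = %.3f\n",
              length(object@w), mean(object@w)))
})

#' @describeIn TaiWeights-class relative adaptiveness vector w.
#' @param x a \code{TaiWeights} object.
#' @export
relAdaptiveness <- function(x) x@w

#' Simulated transcriptome
#'
#' Gene set with 5'UTR, CDS and 3'UTR sequences (DNA alphabet). CDS
#' sequences start with ATG, end with a stop codon and contain no
#' internal stops.
#'
#' @slot geneIds character vector of gene ids.
#' @slot utr5,cds,utr3 \code{DNAStringSet} per region, parallel to
#'   \code{geneIds}.
#' @export
setClass("Transcriptome", representation(
  geneIds = "character", utr5 = "ANY", cds = "ANY", utr3 = "ANY"))

setValidity("Transcriptome", function(object) {
  n <- length(object@geneIds)
  if (length(object@utr5) != n || length(object@cds) != n ||
      length(object@utr3) != n)
    return("regions must be parallel to geneIds")
  TRUE
})

setMethod("show", "Transcriptome", function(object) {
  cat(sprintf(
    "Transcriptome: %d genes (median CDS %d nt, median 3'UTR %d nt)\n",
    length(object@geneIds),
    as.integer(median(Biostrings::width(object@cds))),
    as.integer(median(Biostrings::width(object@utr3)))))
})

#' @describeIn Transcriptome-class gene identifiers.
#' @param x a \code{Transcriptome}.
#' @export
geneIds <- function(x) x@geneIds

#' @describeIn Transcriptome-class per-gene region lengths (nt) and the
#'   mature transcript length (their sum), as a data.frame.
#' @export
regionLengths <- function(x) {
  data.frame(gene_id = x@geneIds,
             len_utr5 = Biostrings::width(x@utr5),
             len_cds = Biostrings::width(x@cds),
             len_utr3 = Biostrings::width(x@utr3),
             len_transcript = Biostrings::width(x@utr5) +
               Biostrings::width(x@cds) + Biostrings::width(x@utr3),
             stringsAsFactors = FALSE)
}
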