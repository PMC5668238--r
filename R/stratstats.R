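# TE binning, empirical CDFs, two-sample Kolmogorov-Smirnov tests and
# per-bin medians: the machinery of the stratified fold-change analysis.

#' Rank-based equal-count bins
#'
#' Assigns each value to one of k quantile bins (label 1 = lowest).
#' Bins are rank-based, so sizes differ by at most one for distinct
#' values; ties share the bin of their mean rank, and a value exactly at
#' the median boundary goes to the low bin. If all values are identical
#' a single-bin assignment is returned with a warning.
#'
#' @param values numeric vector, length >= k.
#' @param k number of bins (>= 2); 2 = median split, 4 = quartiles.
#' @param labels optional bin labels, low to high.
#' @return factor of length(values), levels ordered low to high.
#' @examples
#' quantileBins(c(1, 2, 3, 4), 2)  # low, low, high, high
#' @export
quantileBins <- function(values, k,
                         labels = if (k == 2) c("Low", "High")
                                  else if (k == 4)
                                    c("Low", "Med.Low", "Med.High", "High")
                                  else paste0("Q", seq_len(k))) {
  if (k < 2) stopf("k must be >= 2")
  n <- length(values)
  if (n < k) stopf("need at least k = %d values, got %d", k, n)
  if (length(unique(values)) == 1) {
    warnf("all values identical; returning a single bin")
    return(factor(rep(labels[1], n), levels = labels))
  }
  r <- rank(values, ties.method = "average")
  bin <- pmin(k, floor((r - 1) * k / n) + 1L)
  factor(labels[bin], levels = labels)
}

# asymptotic Kolmogorov tail: P(sqrt(n_eff) D > t)
kolmogorovP <- function(t) {
  if (t < 1e-8) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(1, max(0, p))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum over thresholds of the absolute difference of the
#' two empirical CDFs; the p-value comes from the asymptotic Kolmogorov
#' distribution with effective sample size
#' \eqn{n_x n_y / (n_x + n_y)}. A permutation p-value is available for
#' small samples.
#'
#' @param x,y non-empty numeric samples.
#' @param method \code{"asymptotic"} (default) or \code{"permutation"}.
#' @param nPerm permutations when \code{method = "permutation"}.
#' @param seed RNG seed for the permutation method.
#' @return list with \code{D}, \code{p}, \code{n_x}, \code{n_y}.
#' @examples
#' ksTwoSample(c(1, 3), c(2, 4))$D  # 0.5
#' @export
ksTwoSample <- function(x, y, method = c("asymptotic", "permutation"),
                        nPerm = 2000, seed = 1L) {
  method <- match.arg(method)
  if (!length(x) || !length(y)) stopf("empty sample")
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  D <- unname(kt$statistic)
  if (method == "asymptotic") {
    p <- unname(kt$p.value)
  } else {
    pooled <- c(x, y)
    nx <- length(x)
    dObs <- D
    hits <- withSeed(seed, {
      sum(vapply(seq_len(nPerm), function(i) {
        idx <- sample.int(length(pooled), nx)
        dd <- suppressWarnings(
          stats::ks.test(pooled[idx], pooled[-idx], exact = FALSE))
        unname(dd$statistic) >= dObs - 1e-12
      }, NA))
    })
    p <- (hits + 1) / (nPerm + 1)
  }
  list(D = D, p = p, n_x = length(x), n_y = length(y))
}

#' Per-bin sample medians
#'
#' @param values numeric vector.
#' @param bins factor parallel to \code{values}; every level must be
#'   non-empty.
#' @return named numeric vector of exact sample medians per bin.
#' @export
binMedians <- function(values, bins) {
  if (length(values) != length(bins)) stopf("values/bins length mismatch")
  tab <- table(bins)
  if (any(tab == 0)) stopf("empty bin: %s",
                           paste(names(tab)[tab == 0], collapse = ", "))
  vapply(split(values, bins), median, 0)
}

#' Pearson and Spearman correlation of a paired sample
#'
#' @param x,y paired numeric vectors, n >= 3, non-constant.
#' @return list with \code{pearson_r}, \code{spearman_rs}, \code{n}.
#' @export
correlations <- function(x, y) {
  if (length(x) != length(y)) stopf("x/y length mismatch")
  if (length(x) < 3) stopf("need n >= 3")
  if (sd(x) == 0 || sd(y) == 0) stopf("zero variance input")
  list(pearson_r = cor(x, y),
       spearman_rs = cor(x, y, method = "spearman"),
       n = length(x))
}

applySiteFilter <- function(annotation, siteFilter) {
  if (is.null(siteFilter)) {
    annotation$best_type != "none"
  } else if (is.function(siteFilter)) {
    siteFilter(annotation)
  } else if (is.character(siteFilter)) {
    annotation$best_type %in% siteFilter
  } else stopf("siteFilter must be NULL, a function or site types")
}

#' TE-stratified fold-change comparison
#'
#' The cumulative-distribution analysis of miRNA-target repression:
#' restrict to predicted targets passing \code{siteFilter}, bin them by
#' TE (median halves or quartiles), and report per-bin medians,
#' ECDF supports and all pairwise KS tests. The pooled "All targets"
#' group and the non-target background are carried alongside the bins.
#'
#' @param records data.frame from \code{\link{repressionRecords}}
#'   (columns \code{gene_id}, \code{fc_rpf}, \code{fc_rna}, \code{te}).
#' @param annotation data.frame from \code{\link{classifyTargets}} or
#'   \code{\link{readTargetScanSummary}}.
#' @param assay \code{"RPF"} or \code{"RNA"}: which fold change to
#'   analyse.
#' @param binning \code{"median"} (2 bins) or \code{"quartile"} (4).
#' @param siteFilter NULL (all genes with a site), a character vector of
#'   \code{best_type} values, or a predicate over annotation rows (used
#'   e.g. to bin by conserved-site counts).
#' @param te optional named TE vector overriding \code{records$te} for
#'   the binning (e.g. an independently estimated or ground-truth TE).
#' @return list with \code{assay}, \code{binning}, \code{bins}
#'   (data.frame \code{label}, \code{n}, \code{median_fc}),
#'   \code{ks} (data.frame \code{bin1}, \code{bin2}, \code{D},
#'   \code{p}), \code{ecdf} (named list of sorted fold changes per bin,
#'   plus \code{"All targets"} and \code{"Background"}), and
#'   \code{medianAll}.
#' @export
stratifiedComparison <- function(records, annotation,
                                 assay = c("RPF", "RNA"),
                                 binning = c("median", "quartile"),
                                 siteFilter = NULL, te = NULL) {
  assay <- match.arg(assay)
  binning <- match.arg(binning)
  fcCol <- if (assay == "RPF") "fc_rpf" else "fc_rna"
  idx <- match(records$gene_id, annotation$gene_id)
  ann <- annotation[idx, , drop = FALSE]
  known <- !is.na(idx)
  isTarget <- known & applySiteFilter(ann, siteFilter)
  if (!any(isTarget)) stopf("no genes pass the site filter")

  teVals <- if (is.null(te)) records$te else unname(te[records$gene_id])
  tgt <- records[isTarget, , drop = FALSE]
  tgtTe <- teVals[isTarget]
  if (anyNA(tgtTe)) stopf("TE missing for %d target gene(s)", sum(is.na(tgtTe)))
  fc <- tgt[[fcCol]]
  k <- if (binning == "median") 2L else 4L
  bins <- quantileBins(tgtTe, k)

  med <- binMedians(fc, bins)
  binsDf <- data.frame(label = levels(bins),
                       n = as.integer(table(bins)[levels(bins)]),
                       median_fc = unname(med[levels(bins)]),
                       stringsAsFactors = FALSE)
  prs <- utils::combn(levels(bins), 2)
  ksDf <- do.call(rbind, lapply(seq_len(ncol(prs)), function(j) {
    a <- fc[bins == prs[1, j]]
    b <- fc[bins == prs[2, j]]
    kk <- ksTwoSample(a, b)
    data.frame(bin1 = prs[1, j], bin2 = prs[2, j], D = kk$D, p = kk$p,
               stringsAsFactors = FALSE)
  }))
  ecdfs <- c(lapply(split(fc, bins), sort),
             list("All targets" = sort(fc),
                  "Background" = sort(records[[fcCol]][known &
                    ann$best_type == "none"])))
  list(assay = assay, binning = binning, bins = binsDf, ks = ksDf,
       ecdf = ecdfs, medianAll = median(fc))
}
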