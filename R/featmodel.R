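# Per-gene sequence features and the TE-augmented fold-change model.
#
# The model family predicts RPF log2 fold change from RNA log2 fold
# change (and its square), optionally augmented with log TE and an
# fc_rna x log TE interaction, by least squares; the reported comparison
# is the 5-fold cross-validated Pearson correlation between measured and
# predicted RPF fold change with and without the TE terms, on identical
# folds.

#' Per-gene sequence features
#'
#' Lengths and 3'UTR GC content from sequence; minimum-free-energy (MFE)
#' values are consumed from an external table and normalised per
#' nucleotide (MFE density, kcal/mol per nt); tAI is computed when
#' weights are given; mRNA half-life is a passthrough join. Missing
#' joins leave fields NA, never zero-filled.
#'
#' @param sequences list with named character vectors (or
#'   \code{DNAStringSet}s) \code{utr5}, \code{cds}, \code{utr3}, as from
#'   \code{\link{readFixtureSequences}}.
#' @param mfeTable optional data.frame \code{gene_id}, \code{mfe_5utr},
#'   \code{mfe_3utr} (kcal/mol).
#' @param halfLifeTable optional data.frame \code{gene_id},
#'   \code{half_life} (hours).
#' @param weights optional \linkS4class{TaiWeights} for per-gene tAI.
#' @param mfeNormalizer function(mfe, length) -> normalised MFE;
#'   default is the density \code{mfe / length}.
#' @return data.frame, one row per gene present in \code{sequences$cds}.
#' @export
computeFeatures <- function(sequences, mfeTable = NULL,
                            halfLifeTable = NULL, weights = NULL,
                            mfeNormalizer = function(mfe, len) mfe / len) {
  u5 <- asCharNamed(sequences$utr5)
  cds <- asCharNamed(sequences$cds)
  u3 <- asCharNamed(sequences$utr3)
  ids <- names(cds)
  gcOf <- function(s) {
    if (is.na(s) || !nchar(s)) return(NA_real_)
    v <- strsplit(asDna(s), "")[[1]]
    mean(v %in% c("G", "C"))
  }
  out <- data.frame(
    gene_id = ids,
    len_5utr = unname(nchar(u5[ids])),
    len_cds = unname(nchar(cds)),
    len_3utr = unname(nchar(u3[ids])),
    stringsAsFactors = FALSE)
  out$len_transcript <- out$len_5utr + out$len_cds + out$len_3utr
  out$gc_3utr <- vapply(u3[ids], gcOf, 0, USE.NAMES = FALSE)
  out$mfe_5utr <- NA_real_
  out$mfe_3utr <- NA_real_
  out$norm_mfe_5utr <- NA_real_
  out$norm_mfe_3utr <- NA_real_
  if (!is.null(mfeTable)) {
    if (anyDuplicated(mfeTable$gene_id)) stopf("duplicate keys in MFE table")
    m <- match(ids, mfeTable$gene_id)
    if ("mfe_5utr" %in% names(mfeTable)) {
      out$mfe_5utr <- mfeTable$mfe_5utr[m]
      out$norm_mfe_5utr <- mfeNormalizer(out$mfe_5utr, out$len_5utr)
    }
    if ("mfe_3utr" %in% names(mfeTable)) {
      out$mfe_3utr <- mfeTable$mfe_3utr[m]
      out$norm_mfe_3utr <- mfeNormalizer(out$mfe_3utr, out$len_3utr)
    }
  }
  out$tai <- NA_real_
  if (!is.null(weights)) {
    out$tai <- vapply(cds, function(s) {
      tryCatch(tai(s, weights), error = function(e) NA_real_)
    }, 0, USE.NAMES = FALSE)
  }
  out$half_life <- NA_real_
  if (!is.null(halfLifeTable)) {
    if (anyDuplicated(halfLifeTable$gene_id))
      stopf("duplicate keys in half-life table")
    out$half_life <- halfLifeTable$half_life[match(ids,
                                                   halfLifeTable$gene_id)]
  }
  rownames(out) <- NULL
  out
}

modelFrame <- function(records, includeTe) {
  df <- data.frame(y = records$fc_rpf, x = records$fc_rna,
                   x2 = records$fc_rna^2)
  if (includeTe) {
    df$lte <- log(records$te)
    df$xlte <- records$fc_rna * log(records$te)
  }
  df
}

#' Fit the fold-change prediction model
#'
#' Least-squares fit of RPF log2 fold change on RNA log2 fold change
#' and its square, optionally with log TE and its interaction with the
#' RNA fold change. Reports the in-sample and seeded 5-fold
#' cross-validated Pearson correlation between measured and predicted
#' values.
#'
#' @param records data.frame with \code{fc_rpf}, \code{fc_rna},
#'   \code{te} (complete, n >= 20).
#' @param includeTe add the TE terms?
#' @param folds number of CV folds (default 5).
#' @param seed seed for the fold assignment.
#' @return list with \code{coefficients}, \code{r_insample},
#'   \code{r_cv}, \code{n}, \code{cv_scheme}, \code{includeTe}.
#' @export
fitFcModel <- function(records, includeTe = TRUE, folds = 5, seed = 1L) {
  rec <- records[complete.cases(records[, c("fc_rpf", "fc_rna", "te")]), ]
  n <- nrow(rec)
  if (n < 20) stopf("need at least 20 complete records, got %d", n)
  if (any(rec$te <= 0)) stopf("te must be > 0")
  df <- modelFrame(rec, includeTe)
  if (any(vapply(df[-1], sd, 0) == 0)) stopf("degenerate design")
  fit <- lm(y ~ ., data = df)
  rIn <- cor(df$y, fitted(fit))
  foldId <- withSeed(seed, sample(rep_len(seq_len(folds), n)))
  pred <- numeric(n)
  for (f in seq_len(folds)) {
    hold <- foldId == f
    m <- lm(y ~ ., data = df[!hold, , drop = FALSE])
    pred[hold] <- predict(m, newdata = df[hold, , drop = FALSE])
  }
  list(coefficients = coef(fit), r_insample = rIn,
       r_cv = cor(df$y, pred), n = n,
       cv_scheme = sprintf("%d-fold, seed %d", folds, seed),
       includeTe = includeTe)
}

#' Compare the fold-change model with and without TE
#'
#' Both models are evaluated on identical seeded folds; the contrast of
#' cross-validated Pearson correlations is the package's analogue of
#' asking whether TE carries information about translational repression
#' beyond the mRNA-level change.
#'
#' @inheritParams fitFcModel
#' @return list with \code{with_te}, \code{without_te} (both as from
#'   \code{\link{fitFcModel}}) and \code{delta_r_cv}
#'   (with minus without).
#' @export
compareFcModels <- function(records, folds = 5, seed = 1L) {
  w <- fitFcModel(records, includeTe = TRUE, folds = folds, seed = seed)
  wo <- fitFcModel(records, includeTe = FALSE, folds = folds, seed = seed)
  list(with_te = w, without_te = wo, delta_r_cv = w$r_cv - wo$r_cv)
}
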