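# rpkM normalisation, translation efficiency and fold changes.
#
# TE = rpkM_RPF / rpkM_RNA in the mock condition; fold change is the
# log2 ratio of rpkM, miRNA-transfected over mock, computed separately
# for RPF and RNA. Genes failing the raw-count filter are excluded
# outright (no pseudocounts), so no infinite values propagate.

#' Reads per kilobase of feature per million mapped reads
#'
#' @param count raw read count (non-negative).
#' @param featureLength feature length in nt (> 0).
#' @param libraryTotal total mapped reads of the library (> 0).
#' @return \eqn{10^9 \cdot count / (length \cdot total)}; vectorised.
#' @examples
#' rpkm(10, 1000, 1e6)  # 10
#' @export
rpkm <- function(count, featureLength, libraryTotal) {
  if (any(featureLength <= 0)) stopf("feature length must be > 0")
  if (any(libraryTotal <= 0)) stopf("library total must be > 0")
  if (any(count < 0)) stopf("negative count")
  1e9 * as.numeric(count) / (as.numeric(featureLength) *
                               as.numeric(libraryTotal))
}

#' Build an ExpressionTable from a per-gene data.frame
#'
#' Computes rpkM against the table's own library total.
#'
#' @param df data.frame with \code{gene_id}, \code{count}, \code{length}.
#' @param assay \code{"RPF"} or \code{"RNA"}.
#' @param condition \code{"mock"} or \code{"mir"}.
#' @return An \linkS4class{ExpressionTable}.
#' @export
expressionTable <- function(df, assay, condition) {
  need <- c("gene_id", "count", "length")
  if (!all(need %in% names(df)))
    stopf("need columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stopf("duplicate gene_id: %s",
          paste(head(unique(df$gene_id[duplicated(df$gene_id)]), 3),
                collapse = ", "))
  if (any(df$count < 0)) stopf("negative count")
  total <- sum(df$count)
  g <- data.frame(gene_id = as.character(df$gene_id),
                  count = df$count, length = df$length,
                  rpkm = if (total > 0) rpkm(df$count, df$length, total)
                         else rep(0, nrow(df)),
                  stringsAsFactors = FALSE)
  new("ExpressionTable", assay = assay, condition = condition, genes = g)
}

#' Read one expression library from a counts TSV
#'
#' The TSV is the long format written by \code{\link{writeFixture}}
#' (columns \code{gene_id assay condition count length}); the requested
#' (assay, condition) slice is extracted and rpkM computed from that
#' slice's own library total. Malformed rows are rejected with their row
#' numbers.
#'
#' @param path TSV path.
#' @param assay \code{"RPF"} or \code{"RNA"}.
#' @param condition \code{"mock"} or \code{"mir"}.
#' @return An \linkS4class{ExpressionTable}.
#' @export
readExpressionTable <- function(path, assay, condition) {
  tb <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "assay", "condition", "count", "length")
  if (!all(need %in% names(tb)))
    stopf("%s: need columns %s", path, paste(need, collapse = ", "))
  bad <- which(!is.finite(tb$count) | tb$count < 0 |
                 tb$count != round(tb$count) | tb$length <= 0)
  if (length(bad))
    stopf("%s: malformed rows: %s", path,
          paste(head(bad, 10), collapse = ", "))
  sl <- tb[tb$assay == assay & tb$condition == condition, , drop = FALSE]
  if (!nrow(sl)) stopf("%s: no rows for %s/%s", path, assay, condition)
  expressionTable(sl[, c("gene_id", "count", "length")], assay, condition)
}

passingGenes <- function(table, minCount) {
  g <- geneTable(table)
  g$gene_id[g$count >= minCount]
}

rpkmVec <- function(table) {
  g <- geneTable(table)
  setNames(g$rpkm, g$gene_id)
}

#' Mock-condition translation efficiency per gene
#'
#' TE = rpkM(RPF) / rpkM(RNA) from the two mock libraries. Genes failing
#' the raw-count filter in either library, or with a zero rpkM, are
#' omitted from the result (never set to 0 or Inf).
#'
#' @param mockRpf,mockRna mock-condition \linkS4class{ExpressionTable}s
#'   of the matching assay.
#' @param minCount minimum raw count required in each library
#'   (default 10).
#' @return named numeric vector of TE values.
#' @export
translationEfficiency <- function(mockRpf, mockRna, minCount = 10) {
  if (assayType(mockRpf) != "RPF" || assayType(mockRna) != "RNA")
    stopf("expected an RPF and an RNA table, in that order")
  common <- intersect(geneTable(mockRpf)$gene_id,
                      geneTable(mockRna)$gene_id)
  if (!length(common)) stopf("empty gene intersection")
  keep <- intersect(intersect(passingGenes(mockRpf, minCount),
                              passingGenes(mockRna, minCount)), common)
  rpf <- rpkmVec(mockRpf)[keep]
  rna <- rpkmVec(mockRna)[keep]
  ok <- rpf > 0 & rna > 0
  (rpf / rna)[ok]
}

#' Per-gene log2 fold change between conditions
#'
#' \eqn{fc = \log_2(rpkM_{mir} / rpkM_{mock})}, each rpkM normalised by
#' its own library total; genes must pass the raw-count filter in both
#' conditions.
#'
#' @param mirTable,mockTable \linkS4class{ExpressionTable}s of the same
#'   assay, miRNA-transfected and mock.
#' @param minCount minimum raw count required in each library.
#' @return named numeric vector of log2 fold changes.
#' @export
foldChange <- function(mirTable, mockTable, minCount = 10) {
  if (assayType(mirTable) != assayType(mockTable))
    stopf("assay mismatch: %s vs %s", assayType(mirTable),
          assayType(mockTable))
  common <- intersect(geneTable(mirTable)$gene_id,
                      geneTable(mockTable)$gene_id)
  if (!length(common)) stopf("empty gene intersection")
  keep <- intersect(intersect(passingGenes(mirTable, minCount),
                              passingGenes(mockTable, minCount)), common)
  a <- rpkmVec(mirTable)[keep]
  b <- rpkmVec(mockTable)[keep]
  ok <- a > 0 & b > 0
  log2(a / b)[ok]
}

#' Assemble per-gene repression records
#'
#' Joins RPF and RNA fold changes with mock TE for the genes passing the
#' raw-count filter in all four libraries — the input of the
#' stratification and modelling steps.
#'
#' @param rpfMock,rpfMir,rnaMock,rnaMir the four
#'   \linkS4class{ExpressionTable}s.
#' @param minCount minimum raw count in each of the four libraries.
#' @return data.frame with \code{gene_id}, \code{fc_rpf}, \code{fc_rna},
#'   \code{te}.
#' @export
repressionRecords <- function(rpfMock, rpfMir, rnaMock, rnaMir,
                              minCount = 10) {
  te <- translationEfficiency(rpfMock, rnaMock, minCount)
  fcRpf <- foldChange(rpfMir, rpfMock, minCount)
  fcRna <- foldChange(rnaMir, rnaMock, minCount)
  ids <- intersect(intersect(names(te), names(fcRpf)), names(fcRna))
  data.frame(gene_id = ids, fc_rpf = unname(fcRpf[ids]),
             fc_rna = unname(fcRna[ids]), te = unname(te[ids]),
             stringsAsFactors = FALSE)
}
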