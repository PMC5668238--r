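# Seed-match site detection and per-gene target classification.
#
# Site definitions on the target sense strand, 5'->3' (t1 denotes the
# target position opposite miRNA position 1):
#   6mer    : exact reverse-complement match to miRNA positions 2-7
#   7mer-a1 : 6mer followed immediately (3' on target) by A
#   7mer-m8 : exact reverse-complement match to miRNA positions 2-8
#   8mer    : 7mer-m8 followed by A
# Each occurrence of the 6mer core is reported once with the highest
# applicable type; U and T are interchangeable throughout.

#' Find canonical miRNA seed-match sites in a 3'UTR
#'
#' Scans the sense strand of a 3'UTR for matches to the miRNA seed
#' (positions 2-8 from the 5' end) and classifies each occurrence as
#' 8mer, 7mer-m8, 7mer-a1 or 6mer. A longer type subsumes the shorter
#' ones at the same locus (no double counting). Coordinates are 0-based
#' half-open on the UTR sense strand.
#'
#' @param utrSeq 3'UTR sequence (character or \code{DNAString}-coercible),
#'   sense strand 5'->3'.
#' @param mirna a \linkS4class{MiRNA}.
#' @return data.frame with columns \code{start}, \code{end},
#'   \code{site_type}; zero rows when the UTR has no site.
#' @examples
#' let7 <- miRNA("let-7", "UGAGGUAGUAGGUUGUAUAGUU")
#' findSeedSites("AAACTACCTCAAAA", let7)   # one 8mer
#' @export
findSeedSites <- function(utrSeq, mirna) {
  stopifnot(is(mirna, "MiRNA"))
  utr <- asDna(utrSeq)
  if (nchar(utr) == 0) stopf("empty UTR sequence")
  seed27 <- substr(mirna@seq, 2, 7)
  m8 <- substr(mirna@seq, 8, 8)
  core <- revcompChr(seed27)        # target-strand match to positions 2-7
  m8c <- complementBase(m8)         # target base pairing miRNA position 8

  hits <- gregexpr(core, utr, fixed = TRUE)[[1]]
  if (hits[1] == -1L) {
    return(data.frame(start = integer(), end = integer(),
                      site_type = character(), stringsAsFactors = FALSE))
  }
  n <- nchar(utr)
  out <- lapply(as.integer(hits), function(i) {
    # i is 1-based start of the 6mer core
    hasM8 <- i > 1 && substr(utr, i - 1, i - 1) == m8c
    hasA1 <- i + 6 <= n && substr(utr, i + 6, i + 6) == "A"
    if (hasM8 && hasA1) {
      c(i - 2L, i + 6L, "8mer")
    } else if (hasM8) {
      c(i - 2L, i + 5L, "7mer-m8")
    } else if (hasA1) {
      c(i - 1L, i + 6L, "7mer-a1")
    } else {
      c(i - 1L, i + 5L, "6mer")
    }
  })
  data.frame(start = as.integer(vapply(out, `[`, "", 1)),
             end = as.integer(vapply(out, `[`, "", 2)),
             site_type = vapply(out, `[`, "", 3),
             stringsAsFactors = FALSE)
}

#' Classify genes by their seed-match site content
#'
#' Applies \code{\link{findSeedSites}} to every 3'UTR and summarises
#' per-gene site counts and the best (highest-affinity) site type under
#' the hierarchy 8mer > 7mer-m8 > 7mer-a1 > 6mer. Genes without any site
#' get \code{best_type = "none"} and form the non-target background set.
#' Conservation counts are never computed; they are passed through from
#' an external annotation table when provided.
#'
#' @param geneUtrs named character vector or \code{DNAStringSet} of
#'   3'UTR sequences, one per gene.
#' @param mirna a \linkS4class{MiRNA}.
#' @param annotation optional data.frame with \code{gene_id},
#'   \code{conserved_sites}, \code{poorly_conserved_sites}; ids absent
#'   from the UTR set raise a warning, not an error.
#' @return data.frame with one row per gene: counts per site type
#'   (\code{n_8mer}, \code{n_7mer_m8}, \code{n_7mer_a1}, \code{n_6mer}),
#'   \code{n_sites}, \code{best_type}, and conservation columns (NA when
#'   no annotation given).
#' @export
classifyTargets <- function(geneUtrs, mirna, annotation = NULL) {
  utrs <- asCharNamed(geneUtrs)
  ids <- names(utrs)
  if (is.null(ids) && length(utrs) > 0)
    stopf("geneUtrs must be named by gene id")
  counts <- matrix(0L, nrow = length(utrs), ncol = 4,
                   dimnames = list(ids, SITE_TYPES))
  for (i in seq_along(utrs)) {
    s <- findSeedSites(utrs[[i]], mirna)
    if (nrow(s)) {
      tb <- table(factor(s$site_type, levels = SITE_TYPES))
      counts[i, ] <- as.integer(tb)
    }
  }
  best <- apply(counts, 1, function(r) {
    hit <- which(r > 0)
    if (length(hit)) SITE_TYPES[min(hit)] else "none"
  })
  out <- data.frame(
    gene_id = ids %||% character(),
    n_8mer = counts[, "8mer"], n_7mer_m8 = counts[, "7mer-m8"],
    n_7mer_a1 = counts[, "7mer-a1"], n_6mer = counts[, "6mer"],
    n_sites = as.integer(rowSums(counts)),
    best_type = if (length(utrs)) unname(best) else character(),
    conserved_sites = rep(NA_integer_, length(utrs)),
    poorly_conserved_sites = rep(NA_integer_, length(utrs)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(annotation)) {
    extra <- setdiff(annotation$gene_id, out$gene_id)
    if (length(extra))
      warnf("%d annotation gene ids not in the UTR set", length(extra))
    idx <- match(out$gene_id, annotation$gene_id)
    if ("conserved_sites" %in% names(annotation))
      out$conserved_sites <- annotation$conserved_sites[idx]
    if ("poorly_conserved_sites" %in% names(annotation))
      out$poorly_conserved_sites <- annotation$poorly_conserved_sites[idx]
  }
  out
}

#' Read a TargetScan-style per-gene site summary
#'
#' Reads a TSV of predicted targets (gene id/symbol plus per-type site
#' counts and, optionally, conserved / poorly conserved counts) so that
#' real-data runs can bypass sequence scanning and use an external
#' prediction universe directly.
#'
#' @param path TSV with columns \code{gene_id}, optional \code{n_8mer},
#'   \code{n_7mer_m8}, \code{n_7mer_a1}, \code{n_6mer},
#'   \code{conserved_sites}, \code{poorly_conserved_sites}.
#' @return data.frame in the layout of \code{\link{classifyTargets}}.
#' @export
readTargetScanSummary <- function(path) {
  tb <- read.delim(path, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(tb)) stopf("missing gene_id column in %s", path)
  if (anyDuplicated(tb$gene_id)) stopf("duplicate gene_id in %s", path)
  for (cc in c("n_8mer", "n_7mer_m8", "n_7mer_a1", "n_6mer"))
    if (!cc %in% names(tb)) tb[[cc]] <- 0L
  cmat <- as.matrix(tb[, c("n_8mer", "n_7mer_m8", "n_7mer_a1", "n_6mer")])
  tb$n_sites <- as.integer(rowSums(cmat))
  tb$best_type <- apply(cmat, 1, function(r) {
    hit <- which(r > 0)
    if (length(hit)) SITE_TYPES[min(hit)] else "none"
  })
  for (cc in c("conserved_sites", "poorly_conserved_sites"))
    if (!cc %in% names(tb)) tb[[cc]] <- NA_integer_
  tb[, c("gene_id", "n_8mer", "n_7mer_m8", "n_7mer_a1", "n_6mer",
         "n_sites", "best_type", "conserved_sites",
         "poorly_conserved_sites")]
}
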