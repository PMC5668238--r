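# tRNA adaptation index (tAI) and synonymous CDS redesign.
#
# W_c for a codon sums tGCN over the anticodons able to read it, each
# discounted by the selective constraint s of its wobble pairing:
#   codon NNU : (1-s_WC) tGCN(A34) + (1-s_GU) tGCN(G34)
#   codon NNC :          tGCN(G34) + (1-s_IC) tGCN(A34)   (A34 read as I)
#   codon NNA :          tGCN(U34) + (1-s_IA) tGCN(A34)
#   codon NNG :          tGCN(C34) + (1-s_UG) tGCN(U34)
# with anticodon positions 35/36 Watson-Crick matched to codon positions
# 2/1. w = W / max(W); zero w are replaced by the geometric mean of the
# nonzero w. tAI of a CDS is the geometric mean of w over its sense
# codons. Eukaryote mode: ATG and TGG take only their Watson-Crick
# contribution; the bacterial lysidine rule for ATA is disabled.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Standard wobble selective constraints (s-values)
#'
#' @return named numeric: \code{WC} = 0, \code{GU} = 0.41,
#'   \code{IC} = 0.28, \code{IA} = 0.9999, \code{UG} = 0.68,
#'   \code{lysidine} = 0.89 (bacterial; unused in eukaryote mode).
#' @export
sValues <- function() {
  c(WC = 0, GU = 0.41, IC = 0.28, IA = 0.9999, UG = 0.68,
    lysidine = 0.89)
}

#' Read a tRNA gene-copy table
#'
#' @param path TSV with columns \code{anticodon} (DNA, 5'->3') and
#'   \code{tgcn} (non-negative gene copy number); anticodons absent from
#'   the table have copy number 0.
#' @return named integer vector over anticodons.
#' @export
readTrnaTable <- function(path) {
  tb <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("anticodon", "tgcn") %in% names(tb)))
    stopf("%s: need columns anticodon, tgcn", path)
  ac <- asDna(tb$anticodon)
  if (any(nchar(ac) != 3) || any(grepl("[^ACGT]", ac)))
    stopf("%s: invalid anticodon triplet", path)
  if (any(tb$tgcn < 0)) stopf("%s: negative tGCN", path)
  setNames(as.numeric(tb$tgcn), ac)
}

allCodons <- function() {
  as.vector(outer(as.vector(outer(DNA_BASES_CHR, DNA_BASES_CHR, paste0)),
                  DNA_BASES_CHR, paste0))
}

#' Compute tAI adaptiveness weights from a tRNA table
#'
#' @param trna named numeric vector of tRNA gene copy numbers per
#'   anticodon (DNA alphabet), e.g. from \code{\link{readTrnaTable}}.
#' @param s wobble constraints, see \code{\link{sValues}}.
#' @param lysidine if TRUE apply the bacterial lysidine rule for codon
#'   ATA (read by a modified CAT anticodon); default FALSE (eukaryote).
#' @return A \linkS4class{TaiWeights} object.
#' @examples
#' w <- taiWeights(c(GAA = 2, AAA = 1))
#' relAdaptiveness(w)[c("TTT", "TTC")]
#' @export
taiWeights <- function(trna, s = sValues(), lysidine = FALSE) {
  names(trna) <- asDna(names(trna))
  tg <- function(ac) if (ac %in% names(trna)) trna[[ac]] else 0
  if (all(vapply(names(trna), tg, 0) == 0) || length(trna) == 0 ||
      sum(trna) == 0)
    stopf("tRNA table has no nonzero gene copy number")
  codons <- setdiff(allCodons(), STOP_CODONS)
  W <- setNames(numeric(length(codons)), codons)
  for (cd in codons) {
    b <- strsplit(cd, "")[[1]]
    stemAc <- paste0(complementBase(b[2]), complementBase(b[1]))
    ac34 <- function(wob) paste0(wob, stemAc)
    if (cd == "ATG" || cd == "TGG") {
      # single decoder, Watson-Crick only (eukaryote convention)
      W[cd] <- tg(ac34(complementBase(b[3])))
    } else if (cd == "ATA" && lysidine) {
      W[cd] <- tg("TAT") + (1 - s[["lysidine"]]) * tg("CAT")
    } else {
      W[cd] <- switch(b[3],
        "T" = (1 - s[["WC"]]) * tg(ac34("A")) + (1 - s[["GU"]]) * tg(ac34("G")),
        "C" = tg(ac34("G")) + (1 - s[["IC"]]) * tg(ac34("A")),
        "A" = tg(ac34("T")) + (1 - s[["IA"]]) * tg(ac34("A")),
        "G" = tg(ac34("C")) + (1 - s[["UG"]]) * tg(ac34("T")))
    }
  }
  w <- W / max(W)
  nz <- w[w > 0]
  w[w == 0] <- geomMean(nz)
  new("TaiWeights", W = W, w = w,
      sValues = s[c("WC", "GU", "IC", "IA", "UG", "lysidine")])
}

cdsCodons <- function(cds, where = "CDS") {
  s <- asDna(cds)
  if (nchar(s) %% 3 != 0)
    stopf("%s length %d is not a multiple of 3", where, nchar(s))
  substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
}

# split into sense codons, dropping one trailing stop; error on internal
# stops with their codon index
senseCdsCodons <- function(cds) {
  codons <- cdsCodons(cds)
  if (codons[length(codons)] %in% STOP_CODONS)
    codons <- codons[-length(codons)]
  bad <- which(codons %in% STOP_CODONS)
  if (length(bad))
    stopf("internal stop codon at codon index %d", bad[1])
  codons
}

#' tRNA adaptation index of a coding sequence
#'
#' Geometric mean of the relative adaptiveness w over all sense codons;
#' a single trailing stop codon is dropped.
#'
#' @param cds coding sequence (DNA/RNA character), length a multiple
#'   of 3, no internal stop codons.
#' @param weights a \linkS4class{TaiWeights}.
#' @param dropFirstCodon if TRUE the initiator codon is excluded from
#'   the geometric mean; default FALSE (all sense codons counted).
#' @return tAI in (0, 1].
#' @export
tai <- function(cds, weights, dropFirstCodon = FALSE) {
  codons <- senseCdsCodons(cds)
  if (dropFirstCodon) codons <- codons[-1]
  if (!length(codons)) stopf("no codons left to score")
  geomMean(weights@w[codons])
}

#' Genome-wide tAI distribution
#'
#' @param cdsSet named character vector or \code{DNAStringSet} of CDS.
#' @param weights a \linkS4class{TaiWeights}.
#' @param breaks histogram breaks on [0,1] (default width 0.02).
#' @return list with \code{perGene} (named tAI vector over valid CDS),
#'   \code{invalid} (named character vector of per-gene validation
#'   errors, reported rather than silently dropped), \code{quantiles}
#'   and \code{histogram} (data.frame \code{mid}, \code{count},
#'   \code{frequency}).
#' @export
genomeTaiDistribution <- function(cdsSet, weights,
                                  breaks = seq(0, 1, by = 0.02)) {
  seqs <- asCharNamed(cdsSet)
  if (!length(seqs)) stopf("empty CDS set")
  vals <- setNames(rep(NA_real_, length(seqs)), names(seqs))
  errs <- character()
  for (i in seq_along(seqs)) {
    r <- tryCatch(tai(seqs[[i]], weights), error = function(e) e)
    if (inherits(r, "error")) {
      errs[names(seqs)[i] %||% as.character(i)] <- conditionMessage(r)
    } else vals[i] <- r
  }
  ok <- vals[!is.na(vals)]
  h <- hist(ok, breaks = breaks, plot = FALSE)
  list(perGene = ok, invalid = errs,
       quantiles = quantile(ok, c(0, 0.25, 0.5, 0.75, 1)),
       histogram = data.frame(mid = h$mids, count = h$counts,
                              frequency = h$counts / length(ok)))
}

synonymsByAa <- function() {
  gc <- Biostrings::GENETIC_CODE
  sense <- gc[!names(gc) %in% STOP_CODONS]
  split(names(sense), unname(sense))
}

#' Redesign a CDS toward a target tAI with synonymous swaps
#'
#' Steepest-feasible greedy search: repeatedly apply the single
#' synonymous codon swap that moves the tAI furthest toward the target,
#' ties broken by lowest codon index (seeded shuffle only among exact
#' ties). If the greedy path stalls outside tolerance, restarts from the
#' all-maximal, all-minimal and seeded random synonym assignments are
#' tried and the best result kept. The encoded protein is unchanged.
#'
#' @param cds coding sequence; a trailing stop codon is preserved
#'   untouched.
#' @param weights a \linkS4class{TaiWeights}.
#' @param targetTai desired tAI, within the attainable synonymous range.
#' @param tolerance acceptable |tai - target| (default 0.005).
#' @param seed RNG seed for tie-breaking and restarts.
#' @return list with \code{cds} (redesigned sequence), \code{tai},
#'   \code{converged} (TRUE iff within tolerance), and
#'   \code{attainableRange}.
#' @export
redesignCDS <- function(cds, weights, targetTai, tolerance = 0.005,
                        seed = 1L) {
  s <- asDna(cds)
  codons <- cdsCodons(s)
  stopCd <- if (codons[length(codons)] %in% STOP_CODONS)
    codons[length(codons)] else NULL
  sense <- senseCdsCodons(s)
  n <- length(sense)
  lw <- log(weights@w)
  syn <- synonymsByAa()
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[sense])
  synList <- syn[aa]                       # per-position synonym sets

  lwMax <- vapply(synList, function(cs) max(lw[cs]), 0)
  lwMin <- vapply(synList, function(cs) min(lw[cs]), 0)
  rng <- c(exp(mean(lwMin)), exp(mean(lwMax)))
  if (targetTai < rng[1] - 1e-12 || targetTai > rng[2] + 1e-12)
    stopf("target tAI %.4f unattainable; attainable range [%.4f, %.4f]",
          targetTai, rng[1], rng[2])

  distOf <- function(S) abs(exp(S / n) - targetTai)
  greedy <- function(cur) {
    S <- sum(lw[cur])
    repeat {
      d0 <- distOf(S)
      if (d0 <= 1e-15) break
      bestD <- d0; bestPos <- NA_integer_; bestCd <- NA_character_
      for (i in seq_len(n)) {
        cands <- setdiff(synList[[i]], cur[i])
        if (!length(cands)) next
        dNew <- distOf(S - lw[cur[i]] + lw[cands])
        j <- which(dNew < bestD - 1e-15)
        if (length(j)) {
          jj <- j[which.min(dNew[j])]
          exact <- j[abs(dNew[j] - dNew[jj]) < 1e-15]
          if (length(exact) > 1) jj <- sample(exact, 1)
          bestD <- dNew[jj]; bestPos <- i; bestCd <- cands[jj]
        }
      }
      if (is.na(bestPos)) break
      S <- S - lw[cur[bestPos]] + lw[bestCd]
      cur[bestPos] <- bestCd
    }
    list(codons = cur, dist = distOf(S))
  }

  withSeed(seed, {
    best <- greedy(sense)
    if (best$dist > tolerance) {
      starts <- list(
        vapply(synList, function(cs) cs[which.max(lw[cs])], ""),
        vapply(synList, function(cs) cs[which.min(lw[cs])], ""))
      for (r in 1:20) {
        starts[[length(starts) + 1]] <-
          vapply(synList, function(cs) sample(cs, 1), "")
      }
      for (st in starts) {
        if (best$dist <= tolerance) break
        cand <- greedy(st)
        if (cand$dist < best$dist) best <- cand
      }
    }
    outSeq <- paste0(paste(best$codons, collapse = ""), stopCd %||% "")
    list(cds = outSeq, tai = geomMean(weights@w[best$codons]),
         converged = best$dist <= tolerance, attainableRange = rng)
  })
}
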