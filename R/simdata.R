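# Synthetic ribosome-profiling study generator.
#
# Generative model, per gene g:
#   abundance      a_g  ~ Lognormal(muAbundance, sigmaAbundance)
#   translation    TE_g ~ Lognormal(0, sigmaTe)
#   mock RNA mean  ~ a_g * L_transcript ; mock RPF mean ~ a_g * TE_g * L_cds
#   miRNA-condition effects for targets:
#     RNA log2 fc  = -delta * (number of planted sites)
#     RPF log2 fc  = RNA log2 fc - beta * rank01(TE_g) * sum(site weights)
#   counts ~ NB(mean scaled to the declared library depth, dispersion phi)
# Site weights follow the affinity hierarchy 8mer=1 > 7mer-m8=0.75 >
# 7mer-a1=0.5 > 6mer=0.25. rank01 is the TE rank over all genes scaled to
# [0,1], so beta has a bounded, distribution-free interpretation.

randomDnaVec <- function(nBases, gc) {
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sample(DNA_BASES_CHR, nBases, replace = TRUE, prob = prob)
}

randomUtrs <- function(lengths, gc) {
  bases <- randomDnaVec(sum(lengths), gc)
  idx <- rep.int(seq_along(lengths), lengths)
  vapply(split(bases, idx), paste, "", collapse = "")
}

senseCodons <- function() {
  codons <- as.vector(outer(
    as.vector(outer(DNA_BASES_CHR, DNA_BASES_CHR, paste0)),
    DNA_BASES_CHR, paste0))
  setdiff(codons, c("TAA", "TAG", "TGA"))
}

randomCds <- function(lengths, gc) {
  # interior codons drawn from the 61 sense codons, weighted by the
  # per-base composition implied by gc; ATG start, uniform stop at the end
  codons <- senseCodons()
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  wts <- vapply(codons, function(cd) {
    prod(p[strsplit(cd, "")[[1]]])
  }, 0)
  nInterior <- lengths / 3 - 2L   # minus start and stop
  draw <- sample(codons, sum(nInterior), replace = TRUE, prob = wts)
  idx <- rep.int(seq_along(lengths), nInterior)
  stops <- sample(c("TAA", "TAG", "TGA"), length(lengths), replace = TRUE)
  inner <- character(length(lengths))
  inner[unique(idx)] <- vapply(split(draw, idx), paste, "", collapse = "")
  paste0("ATG", inner, stops)
}

#' Generate a synthetic transcriptome
#'
#' Draws per-gene 5'UTR, CDS and 3'UTR lengths uniformly from the ranges
#' in \code{params@lengthParams} (CDS snapped to multiples of 3) and fills
#' them with random DNA at the requested GC fraction. Every CDS begins
#' with ATG, ends with a single stop codon and translates without
#' internal stops.
#'
#' @param params a \linkS4class{SimParams}.
#' @return A \linkS4class{Transcriptome}.
#' @export
makeTranscriptome <- function(params) {
  validObject(params)
  lp <- params@lengthParams
  n <- params@nGenes
  # sample() with a length-one x would sample from 1:x
  drawFrom <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]
  withSeed(childSeed(params@seed, 11L), {
    l5 <- drawFrom(lp$utr5[1]:lp$utr5[2], n)
    lc <- drawFrom(seq(lp$cds[1], lp$cds[2], by = 3L), n)
    l3 <- drawFrom(lp$utr3[1]:lp$utr3[2], n)
    ids <- sprintf("g%04d", seq_len(n))
    u5 <- randomUtrs(l5, params@gc)
    cds <- randomCds(lc, params@gc)
    u3 <- randomUtrs(l3, params@gc)
    new("Transcriptome", geneIds = ids,
        utr5 = Biostrings::DNAStringSet(setNames(u5, ids)),
        cds = Biostrings::DNAStringSet(setNames(cds, ids)),
        utr3 = Biostrings::DNAStringSet(setNames(u3, ids)))
  })
}

# window strings planted into a 3'UTR; each is 8 nt so flanking guard
# bases travel with the site and fix its detected type
siteWindow <- function(type, core, m8c) {
  guardY <- setdiff(DNA_BASES_CHR, m8c)[1]     # blocks m8 pairing
  switch(type,
    "8mer"    = paste0(m8c, core, "A"),
    "7mer-m8" = paste0(m8c, core, "C"),
    "7mer-a1" = paste0(guardY, core, "A"),
    "6mer"    = paste0(guardY, core, "C"))
}

# 0-based half-open site coordinates inside an 8-nt window at 1-based p
siteCoords <- function(type, p) {
  switch(type,
    "8mer"    = c(p - 1L, p + 7L),
    "7mer-m8" = c(p - 1L, p + 6L),
    "7mer-a1" = c(p, p + 7L),
    "6mer"    = c(p, p + 6L))
}

plantIntoUtr <- function(utr, types, core, m8c, mirna) {
  L <- nchar(utr)
  k <- length(types)
  for (attempt in 1:25) {
    starts <- sort(sample.int(L - 7L, k))
    if (k > 1 && any(diff(starts) < 8L)) next
    seqOut <- utr
    coords <- matrix(0L, nrow = k, ncol = 2)
    for (j in seq_len(k)) {
      win <- siteWindow(types[j], core, m8c)
      substr(seqOut, starts[j], starts[j] + 7L) <- win
      coords[j, ] <- siteCoords(types[j], starts[j])
    }
    found <- findSeedSites(seqOut, mirna)
    ok <- nrow(found) == k &&
      all(found$start[order(found$start)] == coords[, 1]) &&
      all(found$end[order(found$start)] == coords[, 2]) &&
      all(found$site_type[order(found$start)] == types)
    if (ok) {
      return(list(seq = seqOut, start = coords[, 1], end = coords[, 2]))
    }
  }
  NULL
}

#' Plant miRNA seed sites into a transcriptome
#'
#' First scrubs every 3'UTR of chance seed matches (UTRs containing the
#' 6mer core are re-sampled until none remain, so truth labels are
#' exact), then plants sites of randomly drawn types into a
#' \code{targetFraction} of genes. Planted sites are guaranteed to be
#' re-detected by \code{\link{findSeedSites}} at their planted
#' coordinates with their planted type.
#'
#' @param transcriptome a \linkS4class{Transcriptome}.
#' @param mirna a \linkS4class{MiRNA}.
#' @param params a \linkS4class{SimParams}; uses \code{targetFraction},
#'   \code{siteTypeMix} and the seed.
#' @return list with elements \code{transcriptome} (sites planted,
#'   non-target UTRs scrubbed), \code{sites} (data.frame
#'   \code{gene_id,start,end,site_type}, 0-based half-open), and
#'   \code{nSkipped} (genes whose UTR could not host a site).
#' @export
plantSites <- function(transcriptome, mirna, params) {
  validObject(params)
  seed27 <- substr(mirna@seq, 2, 7)
  core <- revcompChr(seed27)
  m8c <- complementBase(substr(mirna@seq, 8, 8))
  utrs <- as.character(transcriptome@utr3)
  ids <- transcriptome@geneIds
  n <- length(ids)

  withSeed(childSeed(params@seed, 12L), {
    # scrub chance matches everywhere
    for (i in seq_len(n)) {
      while (grepl(core, utrs[[i]], fixed = TRUE)) {
        utrs[[i]] <- paste(randomDnaVec(nchar(utrs[[i]]), params@gc),
                           collapse = "")
      }
    }
    nTarget <- round(params@targetFraction * n)
    targetIdx <- if (nTarget > 0) sort(sample.int(n, nTarget)) else integer()
    siteRows <- vector("list", length(targetIdx))
    nSkipped <- 0L
    for (j in seq_along(targetIdx)) {
      i <- targetIdx[j]
      L <- nchar(utrs[[i]])
      if (L < 8L) {
        nSkipped <- nSkipped + 1L
        next
      }
      k <- min(1L + rpois(1, 0.25), max(1L, L %/% 9L))
      types <- sample(SITE_TYPES, k, replace = TRUE,
                      prob = params@siteTypeMix[SITE_TYPES])
      res <- NULL
      for (tries in 1:5) {
        res <- plantIntoUtr(utrs[[i]], types, core, m8c, mirna)
        if (!is.null(res)) break
        utrs[[i]] <- paste(randomDnaVec(L, params@gc), collapse = "")
      }
      if (is.null(res)) {
        nSkipped <- nSkipped + 1L
        next
      }
      utrs[[i]] <- res$seq
      siteRows[[j]] <- data.frame(gene_id = ids[i], start = res$start,
                                  end = res$end, site_type = types,
                                  stringsAsFactors = FALSE)
    }
    if (nSkipped > 0) warnf("%d gene(s) skipped: UTR too short", nSkipped)
    sites <- do.call(rbind, c(siteRows, list(
      data.frame(gene_id = character(), start = integer(), end = integer(),
                 site_type = character(), stringsAsFactors = FALSE))))
    tx <- new("Transcriptome", geneIds = ids, utr5 = transcriptome@utr5,
              cds = transcriptome@cds,
              utr3 = Biostrings::DNAStringSet(setNames(utrs, ids)))
    list(transcriptome = tx, sites = sites, nSkipped = nSkipped)
  })
}

nbDraw <- function(mu, phi) {
  rnbinom(length(mu), mu = mu, size = 1 / phi)
}

#' Simulate paired mock/miRNA RPF and RNA-seq libraries
#'
#' Draws gene abundances and true TE, applies the repression model to
#' targets (RNA decay proportional to site count; translational
#' repression additionally proportional to the TE rank and summed site
#' weights), scales expected counts to the declared library depths and
#' draws negative-binomial counts with dispersion \code{phi}
#' (variance \eqn{m + \phi m^2}). RPF tables carry the CDS length, RNA
#' tables the mature transcript length.
#'
#' @param transcriptome a \linkS4class{Transcriptome} (typically after
#'   \code{\link{plantSites}}).
#' @param sites data.frame of planted sites as returned by
#'   \code{\link{plantSites}}.
#' @param params a \linkS4class{SimParams}.
#' @return list with \code{tables} (named list of four
#'   \linkS4class{ExpressionTable}s: \code{rpf_mock}, \code{rpf_mir},
#'   \code{rna_mock}, \code{rna_mir}) and \code{truth} (per-gene
#'   data.frame with \code{a}, \code{te}, \code{rank01},
#'   \code{is_target}, \code{n_sites}, \code{sum_site_weight},
#'   \code{rna_log2fc_true}, \code{rpf_log2fc_true}).
#' @export
simulateExperiment <- function(transcriptome, sites, params) {
  validObject(params)
  if (params@dispersion <= 0) stopf("dispersion must be > 0")
  ids <- transcriptome@geneIds
  n <- length(ids)
  lens <- regionLengths(transcriptome)

  nSites <- integer(n)
  sumW <- numeric(n)
  if (nrow(sites)) {
    tb <- tapply(rep(1L, nrow(sites)), sites$gene_id, sum)
    nSites[match(names(tb), ids)] <- as.integer(tb)
    wv <- tapply(SITE_WEIGHTS[sites$site_type], sites$gene_id, sum)
    sumW[match(names(wv), ids)] <- as.numeric(wv)
  }

  gen <- withSeed(childSeed(params@seed, 21L), {
    list(a = rlnorm(n, params@muAbundance, params@sigmaAbundance),
         te = rlnorm(n, 0, params@sigmaTe))
  })
  rank01 <- if (n > 1) (rank(gen$te, ties.method = "average") - 1) / (n - 1)
            else rep(0, n)

  rnaFc <- -params@deltaDecay * nSites
  rpfFc <- rnaFc - params@betaTe * rank01 * sumW

  muOf <- function(base, fc, depth) {
    e <- base * 2^fc
    depth * e / sum(e)
  }
  rnaBase <- gen$a * lens$len_transcript
  rpfBase <- gen$a * gen$te * lens$len_cds
  phi <- params@dispersion

  counts <- list(
    rpf_mock = withSeed(childSeed(params@seed, 22L),
                        nbDraw(muOf(rpfBase, 0, params@depthRpf), phi)),
    rpf_mir = withSeed(childSeed(params@seed, 23L),
                       nbDraw(muOf(rpfBase, rpfFc, params@depthRpf), phi)),
    rna_mock = withSeed(childSeed(params@seed, 24L),
                        nbDraw(muOf(rnaBase, 0, params@depthRna), phi)),
    rna_mir = withSeed(childSeed(params@seed, 25L),
                       nbDraw(muOf(rnaBase, rnaFc, params@depthRna), phi)))

  mkTable <- function(cnt, assay, condition, len) {
    expressionTable(data.frame(gene_id = ids, count = cnt, length = len,
                               stringsAsFactors = FALSE),
                    assay = assay, condition = condition)
  }
  tables <- list(
    rpf_mock = mkTable(counts$rpf_mock, "RPF", "mock", lens$len_cds),
    rpf_mir = mkTable(counts$rpf_mir, "RPF", "mir", lens$len_cds),
    rna_mock = mkTable(counts$rna_mock, "RNA", "mock", lens$len_transcript),
    rna_mir = mkTable(counts$rna_mir, "RNA", "mir", lens$len_transcript))

  truth <- data.frame(
    gene_id = ids, a = gen$a, te = gen$te, rank01 = rank01,
    is_target = nSites > 0, n_sites = nSites, sum_site_weight = sumW,
    rna_log2fc_true = rnaFc, rpf_log2fc_true = rpfFc,
    stringsAsFactors = FALSE)
  list(tables = tables, truth = truth)
}

#' Run the full synthetic study
#'
#' Convenience wrapper: transcriptome generation, site planting and
#' count simulation under one \linkS4class{SimParams}.
#'
#' @param params a \linkS4class{SimParams}.
#' @param mirna a \linkS4class{MiRNA}; defaults to hsa-miR-155-5p,
#'   matching the transfection the pipeline emulates.
#' @return list with \code{params}, \code{mirna}, \code{transcriptome},
#'   \code{sites}, \code{tables}, \code{truth}.
#' @examples
#' study <- simulateStudy(simParams(nGenes = 50, seed = 3))
#' head(study$truth)
#' @export
simulateStudy <- function(params = simParams(),
                          mirna = miRNA("hsa-miR-155-5p",
                                        "UUAAUGCUAAUCGUGAUAGGGGU")) {
  tx <- makeTranscriptome(params)
  planted <- plantSites(tx, mirna, params)
  ex <- simulateExperiment(planted$transcriptome, planted$sites, params)
  list(params = params, mirna = mirna,
       transcriptome = planted$transcriptome, sites = planted$sites,
       tables = ex$tables, truth = ex$truth)
}

#' Write a simulated study to plain-text fixture files
#'
#' Emits \code{sequences.fa} (one record per gene region, ids
#' \code{<gene>|utr5} / \code{|cds} / \code{|utr3}), \code{counts.tsv}
#' (long table \code{gene_id assay condition count length} covering all
#' four libraries), \code{sites.tsv} and \code{truth.tsv}. The files
#' round-trip through \code{\link{readExpressionTable}} and
#' \code{\link{readFixtureSequences}}.
#'
#' @param study result of \code{\link{simulateStudy}} (or a list with
#'   the same elements).
#' @param dir output directory, created if needed.
#' @return invisibly, the named vector of file paths.
#' @export
writeFixture <- function(study, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stopf("cannot create directory %s", dir)
  tx <- study$transcriptome
  ids <- tx@geneIds
  seqs <- c(setNames(as.character(tx@utr5), paste0(ids, "|utr5")),
            setNames(as.character(tx@cds), paste0(ids, "|cds")),
            setNames(as.character(tx@utr3), paste0(ids, "|utr3")))
  paths <- c(sequences = file.path(dir, "sequences.fa"),
             counts = file.path(dir, "counts.tsv"),
             sites = file.path(dir, "sites.tsv"),
             truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs),
                              paths["sequences"])
  long <- do.call(rbind, lapply(study$tables, function(tb) {
    g <- geneTable(tb)
    data.frame(gene_id = g$gene_id, assay = assayType(tb),
               condition = conditionType(tb), count = g$count,
               length = g$length, stringsAsFactors = FALSE)
  }))
  write.table(long, paths["counts"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(study$sites, paths["sites"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(study$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Read fixture sequences back into per-region sets
#'
#' @param path FASTA written by \code{\link{writeFixture}} with ids of
#'   the form \code{<gene>|<region>}.
#' @return list of named character vectors \code{utr5}, \code{cds},
#'   \code{utr3}.
#' @export
readFixtureSequences <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- names(ss)
  gene <- sub("\\|.*$", "", ids)
  region <- sub("^.*\\|", "", ids)
  out <- lapply(c(utr5 = "utr5", cds = "cds", utr3 = "utr3"), function(r) {
    keep <- region == r
    setNames(as.character(ss[keep]), gene[keep])
  })
  out
}
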