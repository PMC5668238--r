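toyW <- function() taiWeights(c(GAA = 2, AAA = 1))

test_that("tAI weights match the hand-computed wobble sums", {
  w <- toyW()
  W <- w@W
  # codon TTC: GAA anticodon Watson-Crick (2) + AAA read as inosine (0.72)
  expect_equal(unname(W["TTC"]), 2 + 0.72 * 1)
  # codon TTT: AAA Watson-Crick (1) + GAA via G:U wobble (0.59 * 2)
  expect_equal(unname(W["TTT"]), 1 + 0.59 * 2)
  expect_equal(unname(relAdaptiveness(w)["TTT"]), 2.18 / 2.72,
               tolerance = 1e-9)
  expect_equal(unname(relAdaptiveness(w)["TTC"]), 1)
  # codon TTA: AAA as inosine against A, nearly disallowed
  expect_equal(unname(W["TTA"]), (1 - 0.9999) * 1)
  expect_error(taiWeights(c(GAA = 0)), "nonzero")
})

test_that("single-anticodon table puts its Watson-Crick codon on top", {
  w <- taiWeights(c(AAA = 1))
  expect_equal(unname(relAdaptiveness(w)["TTT"]), 1)
  expect_equal(which.max(w@W), c(TTT = which(names(w@W) == "TTT")))
})

test_that("weights are invariant to uniform tGCN scaling", {
  tab <- c(GAA = 2, AAA = 1, TAT = 3, CAT = 1, CCA = 2)
  expect_equal(relAdaptiveness(taiWeights(tab)),
               relAdaptiveness(taiWeights(2 * tab)))
})

test_that("zero weights are replaced by the geometric mean of nonzero w", {
  w <- toyW()
  nz <- w@w[w@W > 0]
  z <- w@w[w@W == 0]
  expect_true(all(z > 0))
  expect_equal(unname(z[1]), exp(mean(log(nz))))
})

test_that("tai is the geometric mean of codon weights", {
  w <- toyW()
  expect_equal(tai("TTCTTCTTC", w), 1)          # all w = 1
  expect_equal(tai("TTCTTC", w), 1)
  expect_equal(tai("TTCTTTTAA", w),             # stop dropped
               sqrt(1 * 2.18 / 2.72))
  # hand-built weights: two codons at w = 0.5 give tai 0.5
  ww <- new("TaiWeights", W = c(AAA = 2, AAC = 1),
            w = c(AAA = 1, AAC = 0.5), sValues = sValues())
  expect_equal(tai("AACAAC", ww), 0.5)
  expect_error(tai("TTCT", w), "multiple of 3")
  expect_error(tai("TTCTAATTC", w), "codon index 2")
})

test_that("tai is permutation-invariant and monotone in weights", {
  w <- toyW()
  set.seed(3)
  codons <- sample(c("TTT", "TTC", "TTA", "TTG"), 30, replace = TRUE)
  t1 <- tai(paste(codons, collapse = ""), w)
  t2 <- tai(paste(sample(codons), collapse = ""), w)
  expect_equal(t1, t2)
  # raise the weight of a used codon -> tai cannot decrease
  wUpVec <- w@w
  wUpVec[["TTT"]] <- min(1, wUpVec[["TTT"]] * 1.1)
  wUp <- new("TaiWeights", W = w@W, w = wUpVec, sValues = sValues())
  expect_gte(tai("TTTTTATTC", wUp), tai("TTTTTATTC", w))
})

test_that("genome tAI distributions report quantiles and invalid genes", {
  w <- toyW()
  one <- genomeTaiDistribution(c(gA = "TTCTTC"), w)
  expect_equal(sum(one$histogram$frequency), 1)
  expect_equal(unname(one$quantiles["50%"]), 1)

  st <- smallStudy()
  cds <- setNames(as.character(st$transcriptome@cds),
                  geneIds(st$transcriptome))[1:50]
  d <- genomeTaiDistribution(cds, w)
  expect_true(all(d$perGene > 0 & d$perGene <= 1))
  # permuting codons within each gene leaves the distribution unchanged
  shuf <- vapply(cds, function(s) {
    body <- substr(s, 1, nchar(s) - 3)
    cods <- substring(body, seq(1, nchar(body), 3), seq(3, nchar(body), 3))
    paste0(paste(sample(cods), collapse = ""),
           substr(s, nchar(s) - 2, nchar(s)))
  }, "")
  expect_equal(sort(unname(genomeTaiDistribution(shuf, w)$perGene)),
               sort(unname(d$perGene)))
  bad <- genomeTaiDistribution(c(ok = "TTCTTC", bad = "TTCT"), w)
  expect_named(bad$invalid, "bad")
})

test_that("redesign returns the input at its own tAI and hits endpoints", {
  w <- toyW()
  cds <- "ATGTTTTTCAAACCCTAA"
  t0 <- tai(cds, w)
  same <- redesignCDS(cds, w, t0, tolerance = 1e-9)
  expect_identical(same$cds, cds)
  rng <- same$attainableRange
  top <- redesignCDS(cds, w, rng[2], 0.005)
  expect_equal(top$tai, top$attainableRange[2])
  # every codon at its maximal-w synonym
  lw <- log(w@w)
  cods <- substring(top$cds, seq(1, 15, 3), seq(3, 15, 3))
  gc <- Biostrings::GENETIC_CODE
  syn <- split(names(gc)[!names(gc) %in% c("TAA","TAG","TGA")],
               unname(gc[!names(gc) %in% c("TAA","TAG","TGA")]))
  for (cd in cods) {
    expect_equal(lw[[cd]], max(lw[syn[[gc[[cd]]]]]))
  }
  expect_error(redesignCDS(cds, w, 2), "unattainable")
})

test_that("redesign preserves the protein and reaches mid-range targets", {
  st <- smallStudy()
  w <- taiWeights(c(GAA = 2, AAA = 1, TAT = 3, CAT = 1, CCA = 2,
                    AGC = 2, GGC = 1, TGC = 4, CGC = 1))
  gcode <- Biostrings::GENETIC_CODE
  protein <- function(s) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    paste(gcode[cods], collapse = "")
  }
  cdsAll <- as.character(st$transcriptome@cds)
  for (seed in 1:50) {
    cds <- substr(cdsAll[seed], 1, 300)      # 100 codons, no stop kept
    rng <- redesignCDS(cds, w, tai(cds, w), 1)$attainableRange
    target <- mean(rng)
    out <- redesignCDS(cds, w, target, tolerance = 0.005, seed = seed)
    expect_true(out$converged)
    expect_lt(abs(out$tai - target), 0.005)
    expect_identical(protein(out$cds), protein(cds))
  }
})

test_that("redesign matches exhaustive enumeration on tiny CDS", {
  w <- toyW()
  lw <- log(w@w)
  gcode <- Biostrings::GENETIC_CODE
  sense <- names(gcode)[!names(gcode) %in% c("TAA", "TAG", "TGA")]
  syn <- split(sense, unname(gcode[sense]))
  set.seed(11)
  for (rep in 1:25) {
    nC <- sample(2:5, 1)
    cods <- sample(sense, nC, replace = TRUE)
    cds <- paste(cods, collapse = "")
    synSets <- lapply(syn[unname(gcode[cods])], function(x)
      x[seq_len(min(3, length(x)))])
    combos <- expand.grid(synSets, stringsAsFactors = FALSE)
    allTai <- apply(combos, 1, function(r) exp(mean(lw[unlist(r)])))
    target <- runif(1, min(allTai), max(allTai))
    # enumeration restricted to <=3 synonyms; the implementation may use
    # the full synonym sets, so its best distance can only be smaller
    bestDist <- min(abs(allTai - target))
    out <- redesignCDS(cds, w, target, tolerance = 0.005, seed = rep)
    expect_lte(abs(out$tai - target), max(0.005, bestDist + 1e-9))
    expect_identical(paste(gcode[substring(out$cds,
                                           seq(1, nchar(out$cds), 3),
                                           seq(3, nchar(out$cds), 3))],
                           collapse = ""),
                     paste(gcode[cods], collapse = ""))
  }
})

test_that("tRNA tables load from TSV", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "trna.tsv")
  writeLines(c("anticodon\ttgcn", "GAA\t2", "aaa\t1"), path)
  tb <- readTrnaTable(path)
  expect_equal(tb, c(GAA = 2, AAA = 1))
  writeLines(c("anticodon\ttgcn", "GAAA\t2"), path)
  expect_error(readTrnaTable(path), "triplet")
})
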