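test_that("transcriptome generation is deterministic and respects ranges", {
  p <- simParams(nGenes = 10, seed = 1)
  tx1 <- makeTranscriptome(p)
  tx2 <- makeTranscriptome(p)
  expect_identical(as.character(tx1@cds), as.character(tx2@cds))
  expect_identical(as.character(tx1@utr3), as.character(tx2@utr3))

  pDeg <- simParams(nGenes = 20, seed = 2,
                    lengthParams = list(utr5 = c(50L, 60L),
                                        cds = c(300L, 300L),
                                        utr3 = c(100L, 120L)))
  txd <- makeTranscriptome(pDeg)
  expect_true(all(Biostrings::width(txd@cds) == 300))
  lens <- regionLengths(txd)
  expect_true(all(lens$len_utr5 >= 50 & lens$len_utr5 <= 60))
  expect_equal(lens$len_transcript,
               lens$len_utr5 + lens$len_cds + lens$len_utr3)
})

test_that("CDS sequences translate without internal stops", {
  tx <- makeTranscriptome(simParams(nGenes = 40, seed = 5))
  for (s in as.character(tx@cds)) {
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_identical(codons[1], "ATG")
    expect_true(codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
    expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("pooled GC fraction matches the requested composition", {
  tx <- makeTranscriptome(simParams(nGenes = 2000, seed = 7, gc = 0.5))
  seqs <- paste(c(as.character(tx@utr5), as.character(tx@cds),
                  as.character(tx@utr3)), collapse = "")
  bases <- strsplit(seqs, "")[[1]]
  gc <- mean(bases %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 0.02)
})

test_that("invalid parameters are rejected", {
  expect_error(simParams(dispersion = 0), "dispersion")
  expect_error(simParams(siteTypeMix = c("8mer" = 0.5, "7mer-m8" = 0.2,
                                         "7mer-a1" = 0.2, "6mer" = 0.2)),
               "sum to 1")
  expect_error(simParams(lengthParams = list(utr5 = c(300L, 50L),
                                             cds = c(300L, 300L),
                                             utr3 = c(100L, 100L))),
               "length range")
})

test_that("site planting hits the declared fraction and round-trips", {
  st <- smallStudy()
  truthTargets <- unique(st$sites$gene_id)
  expect_equal(length(truthTargets),
               round(0.4 * length(geneIds(st$transcriptome))))
  # planted sites are re-detected exactly where they were planted
  utrs <- utr3Named(st)
  for (g in sample(truthTargets, 25)) {
    found <- findSeedSites(utrs[[g]], st$mirna)
    planted <- st$sites[st$sites$gene_id == g, ]
    expect_equal(sort(found$start), sort(planted$start))
    expect_setequal(found$site_type, planted$site_type)
  }
  # non-target UTRs were scrubbed of chance matches
  nonTargets <- setdiff(names(utrs), truthTargets)
  for (g in sample(nonTargets, 25)) {
    expect_equal(nrow(findSeedSites(utrs[[g]], st$mirna)), 0)
  }
})

test_that("degenerate planting mixes behave", {
  p0 <- simParams(nGenes = 60, targetFraction = 0, seed = 3)
  tx <- makeTranscriptome(p0)
  pl <- plantSites(tx, testMirna(), p0)
  expect_equal(nrow(pl$sites), 0)
  ann <- classifyTargets(setNames(as.character(pl$transcriptome@utr3),
                                  geneIds(pl$transcriptome)), testMirna())
  expect_true(all(ann$best_type == "none"))

  p8 <- simParams(nGenes = 60, targetFraction = 0.5, seed = 3,
                  siteTypeMix = c("8mer" = 1, "7mer-m8" = 0,
                                  "7mer-a1" = 0, "6mer" = 0))
  pl8 <- plantSites(makeTranscriptome(p8), testMirna(), p8)
  expect_true(all(pl8$sites$site_type == "8mer"))
  expect_equal(length(unique(pl8$sites$gene_id)), 30)
})

test_that("truth records the applied effect model exactly", {
  st <- smallStudy()
  tr <- st$truth
  nonT <- tr[!tr$is_target, ]
  expect_true(all(nonT$rna_log2fc_true == 0 & nonT$rpf_log2fc_true == 0))
  # translational repression adds to decay (beta >= 0)
  expect_true(all(tr$rpf_log2fc_true <= tr$rna_log2fc_true + 1e-12))
  tg <- tr[tr$is_target, ]
  expect_equal(tg$rna_log2fc_true, -0.25 * tg$n_sites)
})

test_that("two 8mer sites with delta = 0.5 give true RNA log2 fc of -1", {
  p <- simParams(nGenes = 100, deltaDecay = 0.5, betaTe = 0, seed = 9)
  tx <- makeTranscriptome(p)
  ids <- geneIds(tx)
  sites <- data.frame(gene_id = rep(ids[1:10], each = 2),
                      start = rep(c(5L, 30L), 10),
                      end = rep(c(13L, 38L), 10),
                      site_type = "8mer", stringsAsFactors = FALSE)
  ex <- simulateExperiment(tx, sites, p)
  tg <- ex$truth[ex$truth$is_target, ]
  expect_equal(mean(tg$rna_log2fc_true), -1.0)
  expect_equal(tg$rpf_log2fc_true, tg$rna_log2fc_true)  # beta = 0
})

test_that("expected counts are conserved at the declared depth", {
  st <- smallStudy()
  for (tb in st$tables) {
    depth <- 1e7
    cnt <- geneTable(tb)$count
    total <- sum(cnt)
    # NB bound: sd(total) ~ sqrt(sum(mu + phi mu^2)), mu estimated by counts
    sdTot <- sqrt(sum(cnt + 0.1 * cnt^2))
    expect_lt(abs(total - depth), 4 * sdTot)
  }
})

test_that("decay channel is TE-independent and coupling is monotone", {
  p <- simParams(nGenes = 800, betaTe = 0, deltaDecay = 0.4, seed = 11)
  tx <- makeTranscriptome(p)
  pl <- suppressWarnings(plantSites(tx, testMirna(), p))
  ex <- simulateExperiment(pl$transcriptome, pl$sites, p)
  tg <- ex$truth[ex$truth$is_target, ]
  fit <- lm(rna_log2fc_true ~ te, data = tg)
  ci <- confint(fit)["te", ]
  expect_true(ci[1] <= 0 && ci[2] >= 0)

  pB <- simParams(nGenes = 800, betaTe = 1, seed = 11)
  exB <- simulateExperiment(pl$transcriptome, pl$sites, pB)
  tgB <- exB$truth[exB$truth$is_target & exB$truth$n_sites == 1 &
                     exB$truth$sum_site_weight == 1, ]
  ord <- order(tgB$te)
  diffs <- (tgB$rpf_log2fc_true - tgB$rna_log2fc_true)[ord]
  expect_true(all(diff(diffs) <= 1e-12))
})

test_that("fixtures round-trip through the readers", {
  st <- smallStudy()
  dir <- withr::local_tempdir()
  paths <- writeFixture(st, dir)
  expect_true(all(file.exists(paths)))
  for (nm in names(st$tables)) {
    tb <- st$tables[[nm]]
    back <- readExpressionTable(paths[["counts"]], assayType(tb),
                                conditionType(tb))
    expect_equal(geneTable(back), geneTable(tb))
  }
  seqs <- readFixtureSequences(paths[["sequences"]])
  expect_identical(seqs$cds, setNames(as.character(st$transcriptome@cds),
                                      geneIds(st$transcriptome)))
  sitesBack <- read.delim(paths[["sites"]], stringsAsFactors = FALSE)
  expect_equal(sitesBack, st$sites, ignore_attr = TRUE)
})

test_that("identical parameters give byte-identical fixtures", {
  p <- simParams(nGenes = 40, seed = 13)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeFixture(suppressWarnings(simulateStudy(p, testMirna())), d1)
  writeFixture(suppressWarnings(simulateStudy(p, testMirna())), d2)
  for (f in c("sequences.fa", "counts.tsv", "sites.tsv", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})
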