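# Shared fixtures (memoised so several test files reuse one simulation)
# and independent brute-force oracles.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, maker) {
  if (!exists(key, envir = .fixtureCache)) {
    assign(key, maker(), envir = .fixtureCache)
  }
  get(key, envir = .fixtureCache)
}

testMirna <- function() miRNA("hsa-miR-155-5p", "UUAAUGCUAAUCGUGAUAGGGGU")

smallStudy <- function() {
  cached("smallStudy", function() {
    suppressWarnings(simulateStudy(simParams(nGenes = 300, seed = 42),
                                   testMirna()))
  })
}

utr3Named <- function(study) {
  setNames(as.character(study$transcriptome@utr3),
           geneIds(study$transcriptome))
}

truthTe <- function(study) setNames(study$truth$te, study$truth$gene_id)

# --- independent KS oracle: sup over the pooled support of the
# absolute ECDF difference, by direct enumeration
bruteKsD <- function(x, y) {
  support <- sort(unique(c(x, y)))
  fx <- vapply(support, function(t) mean(x <= t), 0)
  fy <- vapply(support, function(t) mean(y <= t), 0)
  max(abs(fx - fy))
}

# --- independent seed-site oracle: test every substring against the
# reverse complement of the seed, then apply the type hierarchy
rcChr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

bruteSeedSites <- function(utr, matureSeq) {
  utr <- chartr("Uu", "TT", toupper(utr))
  mat <- chartr("Uu", "TT", toupper(matureSeq))
  six <- rcChr(substr(mat, 2, 7))      # match to miRNA 2-7
  sev <- rcChr(substr(mat, 2, 8))      # match to miRNA 2-8
  n <- nchar(utr)
  rows <- list()
  for (i in seq_len(max(0, n - 5))) {
    if (substr(utr, i, i + 5) != six) next
    m8 <- i > 1 && substr(utr, i - 1, i + 5) == paste0(substr(sev, 1, 1), six)
    a1 <- i + 6 <= n && substr(utr, i + 6, i + 6) == "A"
    rows[[length(rows) + 1]] <-
      if (m8 && a1) c(i - 2L, i + 6L, "8mer")
      else if (m8) c(i - 2L, i + 5L, "7mer-m8")
      else if (a1) c(i - 1L, i + 6L, "7mer-a1")
      else c(i - 1L, i + 5L, "6mer")
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(),
                      site_type = character(), stringsAsFactors = FALSE))
  }
  data.frame(start = as.integer(vapply(rows, `[`, "", 1)),
             end = as.integer(vapply(rows, `[`, "", 2)),
             site_type = vapply(rows, `[`, "", 3),
             stringsAsFactors = FALSE)
}

randomUtr <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# quick expression table from counts (equal lengths unless given)
etab <- function(counts, assay, condition, lengths = rep(1000, length(counts)),
                 ids = paste0("g", seq_along(counts))) {
  expressionTable(data.frame(gene_id = ids, count = counts,
                             length = lengths, stringsAsFactors = FALSE),
                  assay, condition)
}
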