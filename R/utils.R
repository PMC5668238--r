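# internal helpers shared across modules

# Derive a child RNG seed from a master seed and a stream index so each
# output table / stage draws from its own stream; keeps seeds < 2^31-1.
childSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 7919 * stream) %% 2147483647L)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

geomMean <- function(x) exp(mean(log(x)))

# uppercase DNA with U -> T, for U/T-agnostic sequence handling
asDna <- function(x) chartr("Uu", "TT", toupper(as.character(x)))

DNA_BASES_CHR <- c("A", "C", "G", "T")

complementBase <- function(b) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[b])
}

revcompChr <- function(s) {
  paste(rev(complementBase(strsplit(s, "")[[1]])), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# as.character() that keeps names for plain character input too
asCharNamed <- function(x) {
  out <- as.character(x)
  if (is.null(names(out))) names(out) <- names(x)
  out
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
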