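# Internal helpers shared across modules.

# Characters treated as missing throughout: gaps and ambiguity codes.
# B/Z/U are treated as ordinary residues.
.MISSING_CHARS <- c("-", ".", "X", "?")

.isMissingChar <- function(ch) ch %in% .MISSING_CHARS

# Split a top-level seed into per-operation streams via a counter-based
# affine map on the 31-bit integer ring. Keeps derived seeds valid R ints.
.deriveSeed <- function(seed, counter) {
  stopifnot(length(seed) == 1L, length(counter) == 1L)
  v <- (as.double(seed) %% 2147483647) * 69069 + as.double(counter) * 1000003 + 12345
  as.integer(v %% 2147483647)
}

# Evaluate expr with a local RNG state seeded from (seed, counter);
# restores the caller's RNG state afterwards.
.withSeed <- function(seed, counter, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.deriveSeed(seed, counter))
  expr
}

# Residue string <-> character vector
.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
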