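# Internal helpers shared across the package.

DNA_BASES <- c("A", "C", "G", "T")

#' @noRd
revcomp_chr <- function(x) {
  # reverse complement of plain character sequences; N maps to N
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' @noRd
encode_seq <- function(s) {
  # map A,C,G,T -> 1..4, anything else -> NA
  match(strsplit(s, "", fixed = TRUE)[[1]], DNA_BASES)
}

#' @noRd
decode_seq <- function(idx) paste(DNA_BASES[idx], collapse = "")

# Shannon entropy in bits of a probability vector (zeros contribute 0).
#' @noRd
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards so library randomness never perturbs user code.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic substream seed, kept well below .Machine$integer.max.
#' @noRd
sub_seed <- function(seed, ...) {
  offs <- c(...)
  s <- as.double(seed)
  for (o in offs) s <- (s * 69069 + o) %% 2147483629
  as.integer(s)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
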