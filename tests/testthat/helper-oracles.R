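# Fixture builders and independent oracle implementations used across the
# suite. Oracles deliberately use different primitives (table(), pair
# counting, exhaustive loops) than the package code they check.

# motif with an exact consensus sequence (fully conserved columns)
consensus_motif <- function(id, cons) {
  idx <- match(strsplit(cons, "")[[1]], c("A", "C", "G", "T"))
  pfm <- matrix(0, 4, length(idx))
  pfm[cbind(idx, seq_along(idx))] <- 1
  motif(id, pfm)
}

rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# plant a subsequence into a random region at a 0-based sequence offset
plant_at <- function(region, inst, at0) {
  paste0(substr(region, 1, at0), inst,
         substr(region, at0 + nchar(inst) + 1, nchar(region)))
}

# entropy oracle via table()
oracle_entropy <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log2(p))
}

oracle_su <- function(x, y) {
  hx <- oracle_entropy(x); hy <- oracle_entropy(y)
  if (hx + hy == 0) return(0)
  hxy <- oracle_entropy(paste(x, y))
  2 * (hx + hy - hxy) / (hx + hy)
}

# exhaustive predominance filter (quadratic loops, table-based SU)
oracle_fcbf <- function(X, y, delta = 0) {
  su_c <- vapply(seq_len(ncol(X)), function(j) oracle_su(X[, j], y),
                 numeric(1))
  ord <- order(-su_c, seq_len(ncol(X)))
  cand <- ord[su_c[ord] > delta]
  retained <- integer(0)
  while (length(cand)) {
    f <- cand[1]
    retained <- c(retained, f)
    cand <- cand[-1]
    keep <- logical(length(cand))
    for (k in seq_along(cand))
      keep[k] <- oracle_su(X[, f], X[, cand[k]]) < su_c[cand[k]]
    cand <- cand[keep]
  }
  retained
}

# AUC by explicit pair counting
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# small feature matrix with planted informative columns
informative_fm <- function(n_pos = 60, n_neg = 120, n_noise = 17,
                           p_pos = 0.9, p_neg = 0.05, seed = 1) {
  set.seed(seed)
  y <- rep(c(1L, 0L), c(n_pos, n_neg))
  n <- n_pos + n_neg
  inf <- cbind(rbinom(n, 1, ifelse(y == 1, p_pos, p_neg)),
               rbinom(n, 1, ifelse(y == 1, p_pos, p_neg)))
  noise <- matrix(rbinom(n * n_noise, 1, 0.3), n, n_noise)
  vals <- cbind(inf, noise)
  dimnames(vals) <- list(sprintf("r%03d", seq_len(n)),
                         c("inf1", "inf2", sprintf("noise%02d", seq_len(n_noise))))
  crm_features(vals, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
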