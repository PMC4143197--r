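#' Build a position-specific scoring matrix
#'
#' Log-odds in bits against a background base distribution:
#' \code{log2((f + pc * bg) / ((1 + pc) * bg))} where \code{pc} is the
#' pseudocount fraction, so a column equal to the background scores 0 at
#' every base.
#'
#' @param m A \code{crm_motif}.
#' @param background Length-4 base frequency vector (A, C, G, T), strictly
#'   positive, summing to 1.
#' @param pseudocount Smoothing fraction (default 0.01).
#' @return Object of class \code{crm_pssm}: list(motif_id, log_odds,
#'   background, threshold, width). The threshold is NA until calibrated.
#' @export
build_pssm <- function(m, background = rep(0.25, 4), pseudocount = 0.01) {
  if (length(background) != 4 || any(background <= 0))
    stop("background must be 4 strictly positive frequencies")
  background <- background / sum(background)
  lo <- log2((m$pfm + pseudocount * background) /
               ((1 + pseudocount) * background))
  dimnames(lo) <- list(DNA_BASES, NULL)
  structure(list(motif_id = m$motif_id, log_odds = lo,
                 background = background, threshold = NA_real_,
                 width = ncol(lo)),
            class = "crm_pssm")
}

#' @export
print.crm_pssm <- function(x, ...) {
  cat(sprintf("<crm_pssm> %s: width %d, threshold %s\n", x$motif_id, x$width,
              if (is.na(x$threshold)) "uncalibrated"
              else sprintf("%.3f bits", x$threshold)))
  invisible(x)
}

# Per-window log-odds scores of an encoded sequence on one strand.
# Windows containing N (NA codes) score NA.
#' @noRd
window_scores <- function(lo, enc) {
  L <- ncol(lo)
  np <- length(enc) - L + 1L
  if (np < 1L) return(numeric(0))
  s <- numeric(np)
  for (j in seq_len(L)) s <- s + lo[, j][enc[j:(j + np - 1L)]]
  s
}

# Reverse-complemented log-odds matrix: scoring a window with it equals
# scoring the window's reverse complement with the original matrix.
#' @noRd
revcomp_matrix <- function(lo) {
  out <- lo[4:1, ncol(lo):1, drop = FALSE]
  dimnames(out) <- list(DNA_BASES, NULL)
  out
}

# Best-of-two-strands per-position scores for one sequence.
#' @noRd
best_strand_scores <- function(pssm, enc) {
  pmax(window_scores(pssm$log_odds, enc),
       window_scores(revcomp_matrix(pssm$log_odds), enc))
}

#' Estimate background base composition from sequences
#'
#' @param seqs Character vector of DNA sequences (N ignored).
#' @return Length-4 frequency vector (A, C, G, T).
#' @export
estimate_background <- function(seqs) {
  counts <- colSums(Biostrings::letterFrequency(
    Biostrings::DNAStringSet(seqs), DNA_BASES))
  if (sum(counts) == 0) stop("no A/C/G/T bases in background sequences")
  counts / sum(counts)
}

#' Calibrate the PSSM hit threshold on background sequences
#'
#' Every position of every background sequence is scored on both strands and
#' the per-position maximum pooled; the threshold is the empirical
#' \code{1 - target_rate} quantile of these scores, so that rescanning the
#' background yields about one hit per \code{1 / target_rate} bp (the default
#' reproduces one site per 5000 bp, with double-strand scanning counted once
#' per position).
#'
#' @param pssm A \code{crm_pssm}.
#' @param background_regions Character vector of background sequences (e.g.
#'   1000 random 2000-bp regions).
#' @param target_rate Target hits per position (default 1/5000).
#' @return The input PSSM with \code{threshold} set and an attribute-free
#'   numeric \code{empirical_rate} field giving the rescan rate on the
#'   calibration set.
#' @export
calibrate_threshold <- function(pssm, background_regions,
                                target_rate = 1 / 5000) {
  stopifnot(target_rate > 0, target_rate <= 1)
  scores <- unlist(lapply(background_regions, function(s)
    best_strand_scores(pssm, encode_seq(s))), use.names = FALSE)
  scores <- scores[!is.na(scores)]
  n <- length(scores)
  k <- max(1L, as.integer(ceiling((1 - target_rate) * n)))
  # an interior quantile needs enough data for a stable estimate; a target
  # rate below 1/n saturates at the maximum observed score by construction
  if (k < n && n < 10 / target_rate)
    stop("insufficient background: ", n, " scanable positions, need >= ",
         ceiling(10 / target_rate))
  thr <- sort(scores, partial = k)[k]
  pssm$threshold <- thr
  pssm$empirical_rate <- sum(scores >= thr) / n
  pssm
}

#' Scan one regulatory region for motif hits
#'
#' Every window of the motif's width is scored on both strands; windows
#' containing N are skipped. Hits are positions whose score meets the
#' calibrated threshold, reported with the TSS-relative start of the 5'-most
#' matched base on the region's sense strand (negative = upstream of the
#' TSS). Overlapping hits are retained, and a position exceeding the
#' threshold on both strands yields two hits.
#'
#' @param pssm A calibrated \code{crm_pssm}.
#' @param sequence Region sequence on the sense strand.
#' @param tss_offset 0-based position of the TSS base within the sequence.
#' @return data.frame(motif_id, start, strand, score).
#' @export
scan_region <- function(pssm, sequence, tss_offset = 1500L) {
  if (is.na(pssm$threshold)) stop("PSSM '", pssm$motif_id, "' not calibrated")
  enc <- encode_seq(sequence)
  sp <- window_scores(pssm$log_odds, enc)
  sm <- window_scores(revcomp_matrix(pssm$log_odds), enc)
  ip <- which(!is.na(sp) & sp >= pssm$threshold)
  im <- which(!is.na(sm) & sm >= pssm$threshold)
  out <- data.frame(
    motif_id = rep(pssm$motif_id, length(ip) + length(im)),
    start = c(ip - 1L, im - 1L) - as.integer(tss_offset),
    strand = rep(c("+", "-"), c(length(ip), length(im))),
    score = c(sp[ip], sm[im]),
    stringsAsFactors = FALSE)
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Scan a region set with several PSSMs
#'
#' @param pssms List of calibrated \code{crm_pssm}.
#' @param regs A \code{crm_regions} object.
#' @return data.frame(gene_id, motif_id, start, strand, score), ordered by
#'   region then start.
#' @export
scan_regions <- function(pssms, regs) {
  off <- attr(regs, "tss_offset")
  res <- lapply(seq_len(nrow(regs)), function(i) {
    h <- do.call(rbind, lapply(pssms, scan_region,
                               sequence = regs$sequence[i], tss_offset = off))
    if (nrow(h)) cbind(gene_id = regs$gene_id[i], h)
    else cbind(gene_id = character(0), h)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(match(out$gene_id, regs$gene_id), out$start, out$motif_id), ,
      drop = FALSE]
}

#' Motif over-representation index
#'
#' ORI = (hits per scanable position in the positive set) / (hits per
#' scanable position in the background set) x (fraction of positive regions
#' containing at least one hit). A zero background rate with a nonzero
#' positive rate gives +Inf with a warning.
#'
#' @param pssm A calibrated \code{crm_pssm}.
#' @param positive_regions,background_regions Character vectors of sequences.
#' @return Single numeric ORI value.
#' @export
compute_ori <- function(pssm, positive_regions, background_regions) {
  if (!length(positive_regions) || !length(background_regions))
    stop("both region sets must be nonempty")
  count_set <- function(seqs) {
    hits <- 0L; pos <- 0L; covered <- 0L
    for (s in seqs) {
      enc <- encode_seq(s)
      sp <- window_scores(pssm$log_odds, enc)
      sm <- window_scores(revcomp_matrix(pssm$log_odds), enc)
      ok <- !is.na(sp)
      h <- sum(sp[ok] >= pssm$threshold) + sum(sm[!is.na(sm)] >= pssm$threshold)
      hits <- hits + h
      pos <- pos + sum(ok)
      covered <- covered + (h > 0L)
    }
    list(hits = hits, pos = pos, covered = covered)
  }
  p <- count_set(positive_regions)
  b <- count_set(background_regions)
  if (p$pos == 0 || b$pos == 0) stop("no scanable positions in a region set")
  rp <- p$hits / p$pos
  rb <- b$hits / b$pos
  frac <- p$covered / length(positive_regions)
  if (rb == 0) {
    if (rp == 0) return(0)
    warning("background hit rate is 0; ORI is +Inf")
    return(Inf)
  }
  rp / rb * frac
}

#' Generate random background regions
#'
#' I.i.d. sequences from a base composition, used for threshold calibration.
#'
#' @param n Number of regions.
#' @param len Region length in bp (default 2000).
#' @param base_composition Length-4 probability vector (A, C, G, T).
#' @param seed RNG seed.
#' @return Character vector of sequences.
#' @export
random_regions <- function(n, len = 2000L, base_composition = rep(0.25, 4),
                           seed = 1L) {
  stopifnot(length(base_composition) == 4, all(base_composition >= 0))
  p <- base_composition / sum(base_composition)
  with_seed(seed, {
    vapply(seq_len(n), function(i)
      paste(sample(DNA_BASES, len, replace = TRUE, prob = p), collapse = ""),
      character(1))
  })
}
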