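#' Construct a motif from a position frequency matrix
#'
#' Count matrices are converted to column-stochastic frequency matrices; a
#' pseudocount is added to every cell before normalisation. The information
#' content is \eqn{\sum_j (2 + \sum_b f_{bj} \log_2 f_{bj})} bits.
#'
#' @param motif_id Motif identifier.
#' @param pfm 4 x L numeric matrix (rows A, C, G, T) of counts or frequencies.
#' @param pseudocount Added to every count cell before normalisation.
#' @return Object of class \code{crm_motif}: list(motif_id, pfm, ic, width).
#' @export
motif <- function(motif_id, pfm, pseudocount = 0) {
  pfm <- as.matrix(pfm)
  if (nrow(pfm) != 4) stop("motif '", motif_id, "': PFM must have 4 rows")
  if (any(pfm < 0)) stop("motif '", motif_id, "': negative PFM entries")
  if (ncol(pfm) < 1) stop("motif '", motif_id, "': zero-width PFM")
  cs <- colSums(pfm)
  if (any(cs == 0 & pseudocount == 0))
    stop("motif '", motif_id, "': empty PFM column and no pseudocount")
  f <- sweep(pfm + pseudocount, 2, cs + 4 * pseudocount, "/")
  dimnames(f) <- list(DNA_BASES, NULL)
  ic <- sum(apply(f, 2, function(p) 2 + sum(ifelse(p > 0, p * log2(p), 0))))
  structure(list(motif_id = motif_id, pfm = f, ic = ic, width = ncol(f)),
            class = "crm_motif")
}

#' @export
print.crm_motif <- function(x, ...) {
  cat(sprintf("<crm_motif> %s: width %d, IC %.2f bits, consensus %s\n",
              x$motif_id, x$width, x$ic, consensus(x)))
  invisible(x)
}

#' Consensus sequence of a motif
#'
#' @param m A \code{crm_motif}.
#' @return Character string; ties broken toward A < C < G < T.
#' @export
consensus <- function(m) decode_seq(apply(m$pfm, 2, which.max))

#' Read motifs from JASPAR or MEME-minimal files
#'
#' The JASPAR dialect expects \code{>id [name]} headers followed by four rows
#' (optionally prefixed with the base letter and wrapped in brackets) of
#' counts in A, C, G, T order. The MEME-minimal dialect expects \code{MOTIF}
#' blocks with a \code{letter-probability matrix} section of L rows x 4
#' columns.
#'
#' @param path Motif file path.
#' @param format \code{"jaspar"} or \code{"meme_minimal"}.
#' @param pseudocount Passed to [motif()].
#' @return List of \code{crm_motif} objects.
#' @export
read_motifs <- function(path, format = c("jaspar", "meme_minimal"),
                        pseudocount = 0) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("motif file not found: ", path)
  lines <- readLines(path)
  if (format == "jaspar") parse_jaspar(lines, pseudocount)
  else parse_meme_minimal(lines, pseudocount)
}

#' @noRd
parse_jaspar <- function(lines, pseudocount) {
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no JASPAR '>' headers found")
  bounds <- c(hdr, length(lines) + 1L)
  lapply(seq_along(hdr), function(k) {
    id <- sub("\\s.*$", "", sub("^>", "", lines[hdr[k]]))
    block <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    block <- block[nzchar(trimws(block))]
    if (length(block) != 4)
      stop("JASPAR motif '", id, "': expected 4 matrix rows, got ",
           length(block))
    rows <- lapply(block, function(l) {
      l <- gsub("^[ \t]*[ACGTacgt][ \t]*\\[?|\\]", "", l)
      v <- suppressWarnings(as.numeric(strsplit(trimws(l), "[ \t]+")[[1]]))
      if (anyNA(v)) stop("JASPAR motif '", id, "': non-numeric matrix row")
      v
    })
    if (length(unique(lengths(rows))) != 1)
      stop("JASPAR motif '", id, "': ragged matrix rows")
    motif(id, do.call(rbind, rows), pseudocount)
  })
}

#' @noRd
parse_meme_minimal <- function(lines, pseudocount) {
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) stop("no MEME 'MOTIF' blocks found")
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    id <- strsplit(trimws(lines[starts[k]]), "[ \t]+")[[1]][2]
    i <- starts[k] + 1L
    while (i <= length(lines) &&
           !grepl("^letter-probability matrix", lines[i])) i <- i + 1L
    if (i > length(lines))
      stop("MEME motif '", id, "': missing letter-probability matrix")
    w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[i]))
    rows <- lines[(i + 1L):(i + w)]
    m <- t(vapply(rows, function(l)
      as.numeric(strsplit(trimws(l), "[ \t]+")[[1]][1:4]), numeric(4)))
    if (anyNA(m)) stop("MEME motif '", id, "': malformed probability row")
    out[[k]] <- motif(id, t(m), pseudocount)
  }
  out
}

#' Write motifs to a JASPAR-style file
#'
#' @param motifs List of \code{crm_motif}.
#' @param path Output path.
#' @param counts_scale Frequencies are written as pseudo-counts scaled by this
#'   factor (default 100) for readability.
#' @export
write_motifs_jaspar <- function(motifs, path, counts_scale = 100) {
  lines <- unlist(lapply(motifs, function(m) {
    mat <- round(m$pfm * counts_scale, 4)
    c(paste0(">", m$motif_id),
      vapply(1:4, function(b)
        sprintf("%s [ %s ]", DNA_BASES[b],
                paste(format(mat[b, ], trim = TRUE), collapse = " ")),
        character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Ungapped similarity between two motifs
#'
#' Maximum over all ungapped offsets and both orientations of the mean
#' per-column Pearson correlation between aligned frequency columns, with at
#' least \code{min_overlap} overlapping columns required. Columns with zero
#' variance (uniform columns) contribute a correlation of 0.
#'
#' @param a,b \code{crm_motif} objects, both of width >= \code{min_overlap}.
#' @param min_overlap Minimum aligned columns (default 4).
#' @return Similarity in [-1, 1].
#' @export
pwm_similarity <- function(a, b, min_overlap = 4L) {
  if (a$width < min_overlap || b$width < min_overlap)
    stop("motifs must each have width >= ", min_overlap)
  rc <- function(p) p[4:1, ncol(p):1, drop = FALSE]
  col_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
    stats::cor(x, y)
  }
  best <- -1
  for (pb in list(b$pfm, rc(b$pfm))) {
    for (off in seq(-(ncol(pb) - min_overlap), a$width - min_overlap)) {
      ia <- seq(max(1L, 1L + off), min(a$width, ncol(pb) + off))
      ib <- ia - off
      cors <- vapply(seq_along(ia),
                     function(k) col_cor(a$pfm[, ia[k]], pb[, ib[k]]),
                     numeric(1))
      best <- max(best, mean(cors))
    }
  }
  best
}

#' Remove redundant motifs by information content
#'
#' Builds a graph over motifs with an edge for every match pair at
#' \code{p <= p_threshold} (e.g. TOMTOM output, or pairs derived from
#' [pwm_similarity()]); within each connected component only the motif with
#' the highest information content survives, ties broken lexicographically by
#' id.
#'
#' @param motifs List of \code{crm_motif}.
#' @param match_pairs data.frame with columns id_a, id_b, p_value.
#' @param p_threshold Significance cutoff (default 0.001).
#' @return Filtered list of \code{crm_motif}, in input order.
#' @export
remove_redundant <- function(motifs, match_pairs, p_threshold = 0.001) {
  ids <- vapply(motifs, `[[`, character(1), "motif_id")
  if (nrow(match_pairs)) {
    bad <- setdiff(c(match_pairs$id_a, match_pairs$id_b), ids)
    if (length(bad))
      stop("match_pairs reference unknown motif(s): ",
           paste(unique(bad), collapse = ", "))
  }
  sig <- match_pairs[match_pairs$p_value <= p_threshold, , drop = FALSE]
  if (!nrow(sig)) return(motifs)
  g <- igraph::graph_from_data_frame(
    sig[c("id_a", "id_b")], directed = FALSE,
    vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership[ids]
  ic <- vapply(motifs, `[[`, numeric(1), "ic")
  keep <- unlist(lapply(split(seq_along(ids), comp), function(idx) {
    idx[order(-ic[idx], ids[idx])][1]
  }))
  motifs[sort(keep)]
}
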