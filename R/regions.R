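#' Read a genome from a FASTA file
#'
#' Sequences are upper-cased and any character outside A/C/G/T is replaced by
#' N. Record ids are the first whitespace-delimited token of each header and
#' must be unique.
#'
#' @param fasta_path Path to a FASTA file.
#' @return Named character vector, one element per chromosome.
#' @export
read_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  dss <- tryCatch(Biostrings::readBStringSet(fasta_path),
                  error = function(e) stop("malformed FASTA '", fasta_path,
                                           "': ", conditionMessage(e)))
  ids <- sub("\\s.*$", "", names(dss))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA record id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(dss))
  seqs <- gsub("[^ACGT]", "N", seqs)
  names(seqs) <- ids
  seqs
}

#' Read a TSS annotation table
#'
#' Accepts either a headered TSV with columns \code{gene_id}, \code{chrom},
#' \code{strand}, \code{tss} (0-based TSS coordinate), or a headerless BED6
#' file (chrom, start, end, name, score, strand) in which the TSS is taken as
#' \code{start} for plus-strand and \code{end - 1} for minus-strand records.
#'
#' @param path Path to the annotation file.
#' @return data.frame with columns gene_id, chrom, strand, tss.
#' @export
read_tss_table <- function(path) {
  if (!file.exists(path)) stop("TSS table not found: ", path)
  first <- readLines(path, n = 1L)
  if (grepl("gene_id", first, fixed = TRUE)) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "strand", "tss")
    if (!all(need %in% names(df)))
      stop("TSS TSV must have columns: ", paste(need, collapse = ", "))
    df <- df[need]
  } else {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 6) stop("headerless TSS table must be BED6 (6 columns)")
    df <- data.frame(gene_id = as.character(df[[4]]), chrom = df[[1]],
                     strand = df[[6]],
                     tss = ifelse(df[[6]] == "+", df[[2]], df[[3]] - 1L),
                     stringsAsFactors = FALSE)
  }
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(df$tss < 0)) stop("TSS coordinates must be >= 0")
  df$tss <- as.integer(df$tss)
  df
}

#' Select one primary TSS per gene
#'
#' Among alternative TSSs of a gene the most upstream one is kept: the minimum
#' coordinate on the plus strand, the maximum on the minus strand.
#'
#' @param tss data.frame as returned by [read_tss_table()].
#' @return data.frame with one row per gene.
#' @export
select_primary_tss <- function(tss) {
  out <- lapply(split(tss, tss$gene_id), function(g) {
    if (length(unique(g$strand)) != 1L || length(unique(g$chrom)) != 1L)
      stop("gene ", g$gene_id[1], " has records on mixed strands/chromosomes")
    g[if (g$strand[1] == "+") which.min(g$tss) else which.max(g$tss), ]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$gene_id), ]
}

#' Extract TSS-anchored regulatory regions
#'
#' Each region covers \code{upstream} bp upstream and \code{downstream} bp
#' downstream of the TSS (the TSS base is the first downstream base) and is
#' returned on the gene's sense strand, reading 5' to 3' toward the gene body.
#' Coordinates are 0-based half-open: plus-strand genes take the genomic
#' interval \code{[tss - upstream, tss + downstream)}; minus-strand genes take
#' \code{[tss - downstream + 1, tss + upstream + 1)} reverse-complemented.
#' Positions beyond the chromosome ends are padded with N
#' (\code{boundary = "pad"}) or the gene is dropped with a warning
#' (\code{boundary = "skip"}); genes whose region lies entirely off the
#' chromosome are always dropped with a warning.
#'
#' @param genome Named character vector from [read_genome()].
#' @param tss data.frame with one row per gene (see [select_primary_tss()]).
#' @param upstream,downstream Region extent in bp.
#' @param boundary Boundary policy, \code{"pad"} or \code{"skip"}.
#' @return An object of class \code{crm_regions}: a data.frame with columns
#'   \code{gene_id} and \code{sequence}, with attributes \code{upstream},
#'   \code{downstream} and \code{tss_offset} (= upstream).
#' @export
extract_regions <- function(genome, tss, upstream = 1500L, downstream = 500L,
                            boundary = c("pad", "skip")) {
  boundary <- match.arg(boundary)
  stopifnot(upstream >= 0, downstream >= 0, upstream + downstream > 0)
  len <- upstream + downstream
  keep <- logical(nrow(tss))
  seqs <- character(nrow(tss))
  for (i in seq_len(nrow(tss))) {
    chrom <- tss$chrom[i]
    if (!chrom %in% names(genome))
      stop("unknown chromosome '", chrom, "' for gene ", tss$gene_id[i])
    clen <- nchar(genome[[chrom]])
    if (tss$strand[i] == "+") {
      g0 <- tss$tss[i] - upstream          # 0-based half-open [g0, g1)
      g1 <- tss$tss[i] + downstream
    } else {
      g0 <- tss$tss[i] - downstream + 1L
      g1 <- tss$tss[i] + upstream + 1L
    }
    lo <- max(g0, 0L); hi <- min(g1, clen)
    if (lo >= hi) {
      warning("region of gene ", tss$gene_id[i],
              " lies entirely outside chromosome ", chrom, "; skipped")
      next
    }
    if ((lo > g0 || hi < g1) && boundary == "skip") {
      warning("region of gene ", tss$gene_id[i],
              " exceeds chromosome bounds; skipped")
      next
    }
    core <- substr(genome[[chrom]], lo + 1L, hi)
    s <- paste0(strrep("N", lo - g0), core, strrep("N", g1 - hi))
    if (tss$strand[i] == "-") s <- revcomp_chr(s)
    seqs[i] <- s
    keep[i] <- TRUE
  }
  regions(tss$gene_id[keep], seqs[keep], upstream, downstream)
}

#' Construct a regulatory-region set from sequences
#'
#' @param gene_id Character vector of region ids (unique).
#' @param sequence Character vector of equal-length DNA sequences on the
#'   gene's sense strand.
#' @param upstream,downstream Extent of the regions around the TSS;
#'   \code{upstream + downstream} must equal the sequence length.
#' @return A \code{crm_regions} object.
#' @export
regions <- function(gene_id, sequence, upstream = 1500L, downstream = 500L) {
  if (anyDuplicated(gene_id)) stop("duplicated region ids")
  if (length(sequence) && any(nchar(sequence) != upstream + downstream))
    stop("all region sequences must have length upstream + downstream")
  out <- data.frame(gene_id = as.character(gene_id),
                    sequence = as.character(sequence),
                    stringsAsFactors = FALSE)
  attr(out, "upstream") <- as.integer(upstream)
  attr(out, "downstream") <- as.integer(downstream)
  attr(out, "tss_offset") <- as.integer(upstream)
  class(out) <- c("crm_regions", "data.frame")
  out
}

#' @export
print.crm_regions <- function(x, ...) {
  cat(sprintf("<crm_regions> %d regions, %d bp upstream + %d bp downstream of the TSS\n",
              nrow(x), attr(x, "upstream"), attr(x, "downstream")))
  invisible(x)
}

#' Read a genes x samples expression matrix
#'
#' Tab-separated, first column gene ids, remaining columns numeric samples.
#'
#' @param path TSV file path.
#' @return Numeric matrix with gene-id rownames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Derive positive and negative gene sets from expression
#'
#' Positives are the \code{top_n} genes by mean expression across the target
#' tissue samples. Negatives are genes whose tissue Z-score, the mean tissue
#' expression standardised against the gene's own mean and standard deviation
#' across all samples, falls below \code{z_threshold}. Genes with zero
#' variance are excluded from the negative set with a warning, and positives
#' are never also negatives.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param tissue_columns Column names (or indices) of the target tissue.
#' @param top_n Number of positive genes.
#' @param z_threshold Z-score cutoff for negatives (default -1).
#' @return list(positive = ids, negative = ids, z = named Z-score vector).
#' @export
select_gene_sets <- function(expr, tissue_columns, top_n, z_threshold = -1) {
  if (is.character(tissue_columns) &&
      !all(tissue_columns %in% colnames(expr)))
    stop("tissue_columns not all present in expression matrix")
  if (ncol(expr) < 2) stop("need >= 2 samples per gene for Z-scores")
  tis <- expr[, tissue_columns, drop = FALSE]
  tmean <- rowMeans(tis)
  gmean <- rowMeans(expr)
  gsd <- apply(expr, 1, stats::sd)
  positive <- names(sort(tmean, decreasing = TRUE))[seq_len(min(top_n, nrow(expr)))]
  z <- (tmean - gmean) / gsd
  if (any(gsd == 0)) {
    warning(sum(gsd == 0), " zero-variance gene(s) excluded from Z-scoring")
    z[gsd == 0] <- NA_real_
  }
  negative <- setdiff(rownames(expr)[!is.na(z) & z < z_threshold], positive)
  list(positive = positive, negative = negative, z = z)
}
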