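# Structural features are represented as canonical strings so that equal
# features always serialize identically and can be hashed with match():
#   tss|<motif>|<u|d><bin>|<+|-|.>     distance bin from the TSS, signed
#   pair|<m1>,<m2>|<bin>|<s1s2>        unsigned start-to-start spacing bin
#   orient|<motif>|<+|->               orientation, position-free
#   order|<m1>m2[>m3]                 5'->3' motif order, orientation-free
# '.' denotes the either-strand variant of a constraint.

#' @noRd
tss_bin_label <- function(start, window) {
  ifelse(start < 0,
         paste0("u", (-start) %/% window),
         paste0("d", start %/% window))
}

#' Enumerate the structural features of one region
#'
#' Given the motif hits of a single regulatory region, emits every binary
#' structural feature the region exhibits, in four classes: position of each
#' motif relative to the TSS in \code{window}-bp bins (strand-specific and
#' either-strand variants), unsigned pairwise start-to-start spacing of every
#' hit pair in \code{window}-bp bins (strand-pair and either-strand
#' variants), motif orientation irrespective of position, and 5'-to-3' motif
#' order over every subsequence of 2..\code{max_order} hits, irrespective of
#' orientation and distance.
#'
#' @param hits data.frame with columns motif_id, start (TSS-relative bp,
#'   negative = upstream), strand, for one region.
#' @param window Bin width in bp (default 100).
#' @param max_order Maximum motifs per order feature (default 3).
#' @return Character vector of canonical feature ids (unique, sorted).
#' @export
features_of_region <- function(hits, window = 100L, max_order = 3L) {
  stopifnot(window > 0, max_order >= 2)
  n <- nrow(hits)
  if (!n) return(character(0))
  hits <- hits[order(hits$start, hits$motif_id, hits$strand), , drop = FALSE]
  bin <- tss_bin_label(hits$start, window)
  feats <- c(
    paste0("tss|", hits$motif_id, "|", bin, "|", hits$strand),
    paste0("tss|", hits$motif_id, "|", bin, "|."),
    paste0("orient|", hits$motif_id, "|", hits$strand))
  if (n >= 2) {
    pr <- utils::combn(n, 2)
    i <- pr[1, ]; j <- pr[2, ]
    d <- abs(hits$start[j] - hits$start[i]) %/% window
    # canonical member order: by motif id, then strand (+ before -)
    swap <- hits$motif_id[i] > hits$motif_id[j] |
      (hits$motif_id[i] == hits$motif_id[j] &
         hits$strand[i] > hits$strand[j])
    a <- ifelse(swap, j, i); b <- ifelse(swap, i, j)
    feats <- c(feats,
      paste0("pair|", hits$motif_id[a], ",", hits$motif_id[b], "|", d, "|",
             hits$strand[a], hits$strand[b]),
      paste0("pair|", hits$motif_id[a], ",", hits$motif_id[b], "|", d, "|.."))
    for (k in 2:min(max_order, n)) {
      idx <- utils::combn(n, k)
      feats <- c(feats, paste0("order|", apply(idx, 2, function(ii)
        paste(hits$motif_id[ii], collapse = ">"))))
    }
  }
  sort(unique(feats))
}

#' Build the structural-feature library from positive regions
#'
#' Union of [features_of_region()] over every positive region, deduplicated
#' and canonically ordered. The library size is data-dependent.
#'
#' @param hits data.frame of hits with a gene_id column covering the positive
#'   regions.
#' @param region_ids Ids of the positive regions (regions without hits
#'   contribute nothing).
#' @param window,max_order Passed to [features_of_region()].
#' @return Sorted character vector of feature ids.
#' @export
build_feature_library <- function(hits, region_ids = unique(hits$gene_id),
                                  window = 100L, max_order = 3L) {
  if (!length(region_ids)) stop("need at least one positive region")
  per <- lapply(split(hits, factor(hits$gene_id, levels = region_ids)),
                features_of_region, window = window, max_order = max_order)
  sort(unique(unlist(per, use.names = FALSE)))
}

#' Binarize feature presence over a region cohort
#'
#' @param library Feature ids (columns), e.g. from
#'   [build_feature_library()].
#' @param hits data.frame of hits with gene_id column for all regions.
#' @param region_ids Region ids (rows); must be unique.
#' @param labels Binary vector (1 = positive class), one per region.
#' @param window,max_order Passed to [features_of_region()].
#' @return Object of class \code{crm_features}: list(values = 0/1 integer
#'   matrix regions x features, labels, features).
#' @export
binarize <- function(library, hits, region_ids, labels,
                     window = 100L, max_order = 3L) {
  if (anyDuplicated(region_ids)) stop("duplicated region ids")
  if (length(labels) != length(region_ids))
    stop("labels length must equal number of regions")
  m <- matrix(0L, length(region_ids), length(library),
              dimnames = list(region_ids, library))
  per <- split(hits, factor(hits$gene_id, levels = region_ids))
  for (r in seq_along(region_ids)) {
    f <- features_of_region(per[[r]], window = window, max_order = max_order)
    m[r, stats::na.omit(match(f, library))] <- 1L
  }
  crm_features(m, labels)
}

#' Construct a feature matrix object
#'
#' @param values 0/1 matrix, regions x features, with dimnames.
#' @param labels Binary class vector (1 = positive), length nrow(values).
#' @return A \code{crm_features} object.
#' @export
crm_features <- function(values, labels) {
  stopifnot(is.matrix(values), all(values %in% c(0L, 1L)),
            length(labels) == nrow(values), all(labels %in% c(0L, 1L)))
  if (anyDuplicated(colnames(values))) stop("duplicate features")
  structure(list(values = values, labels = as.integer(labels),
                 features = colnames(values)),
            class = "crm_features")
}

#' @export
print.crm_features <- function(x, ...) {
  cat(sprintf("<crm_features> %d regions (%d positive) x %d features; fill %.3f\n",
              nrow(x$values), sum(x$labels), ncol(x$values),
              mean(x$values)))
  invisible(x)
}

#' Decode feature ids into a table
#'
#' @param ids Canonical feature id strings.
#' @return data.frame(feature, kind, motifs, bin, strands); bin is NA for
#'   orientation and order features, strands is NA for order features.
#' @export
feature_table <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  kind <- vapply(parts, `[[`, character(1), 1)
  motifs <- vapply(parts, `[[`, character(1), 2)
  bin <- rep(NA_character_, length(ids))
  strands <- rep(NA_character_, length(ids))
  tssk <- kind == "tss"; pk <- kind == "pair"; ok <- kind == "orient"
  bin[tssk] <- vapply(parts[tssk], `[[`, character(1), 3)
  strands[tssk] <- vapply(parts[tssk], `[[`, character(1), 4)
  bin[pk] <- vapply(parts[pk], `[[`, character(1), 3)
  strands[pk] <- vapply(parts[pk], `[[`, character(1), 4)
  strands[ok] <- vapply(parts[ok], `[[`, character(1), 3)
  motifs[kind == "order"] <- gsub(">", ",", motifs[kind == "order"])
  data.frame(feature = ids, kind = kind, motifs = motifs, bin = bin,
             strands = strands, stringsAsFactors = FALSE)
}

#' Number of motifs referenced by each feature
#'
#' @param ids Canonical feature ids.
#' @return Integer vector.
#' @export
feature_arity <- function(ids) {
  tab <- feature_table(ids)
  lengths(strsplit(tab$motifs, ",", fixed = TRUE))
}
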