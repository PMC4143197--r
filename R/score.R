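#' Presence profile of the final features in one region
#'
#' Re-uses the feature enumeration of [features_of_region()] exactly, so
#' detection can never drift from the features the model was trained on.
#'
#' @param hits Hit table of a single region (motif_id, start, strand).
#' @param final_features Character vector of feature ids.
#' @param window,max_order Feature enumeration parameters.
#' @return Integer 0/1 vector, one entry per final feature.
#' @export
feature_presence_profile <- function(hits, final_features,
                                     window = 100L, max_order = 3L) {
  present <- features_of_region(hits, window = window, max_order = max_order)
  as.integer(final_features %in% present)
}

#' Score regulatory regions genome-wide
#'
#' Every region is scanned with the calibrated PSSMs, its structural features
#' are detected, and its score is the sum of the normalised weights of the
#' final features it contains. Regions are ranked by descending score, ties
#' broken lexicographically by gene id.
#'
#' @param regs A \code{crm_regions} object (the genome-wide region set).
#' @param pssms List of calibrated \code{crm_pssm}.
#' @param final_features Feature ids of the model (e.g.
#'   \code{fit$final_features}).
#' @param weights Named weight vector covering \code{final_features} (e.g.
#'   \code{fit$weights$weights}).
#' @param window,max_order Feature enumeration parameters.
#' @param top_k Optionally keep only the k highest-scoring regions.
#' @return data.frame(rank, gene_id, score, n_features, features) sorted by
#'   rank; \code{features} is a semicolon-joined list of present final
#'   features.
#' @export
score_genome <- function(regs, pssms, final_features, weights,
                         window = 100L, max_order = 3L, top_k = NULL) {
  if (!nrow(regs)) stop("empty region set")
  if (!all(final_features %in% names(weights)))
    stop("weights must cover every final feature")
  hits <- scan_regions(pssms, regs)
  per <- split(hits, factor(hits$gene_id, levels = regs$gene_id))
  prof <- t(vapply(per, feature_presence_profile,
                   integer(length(final_features)),
                   final_features = final_features, window = window,
                   max_order = max_order))
  score <- drop(prof %*% weights[final_features])
  out <- data.frame(gene_id = regs$gene_id,
                    score = as.numeric(score),
                    n_features = rowSums(prof),
                    features = apply(prof, 1, function(p)
                      paste(final_features[p == 1L], collapse = ";")),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene_id), ]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  if (!is.null(top_k)) out <- out[seq_len(min(top_k, nrow(out))), ]
  out
}

#' Conservation of final features in ortholog regulatory regions
#'
#' Scans the regulatory regions of orthologs in other species for the model's
#' final features. By default (\code{recalibrate = "auto"}) PSSM thresholds
#' are recalibrated against each species' own region set when it offers
#' enough scanable sequence for the empirical quantile, and the reference
#' thresholds are kept otherwise; \code{"always"}/\code{"never"} force either
#' behaviour.
#'
#' @param ortholog_regions Named list (species -> \code{crm_regions}).
#' @param pssms List of calibrated \code{crm_pssm} (reference thresholds).
#' @param final_features Feature ids of the model.
#' @param target_rate Calibration target hit rate (default 1/5000).
#' @param recalibrate "auto", "always" or "never".
#' @param window,max_order Feature enumeration parameters.
#' @return List with \code{records}, a data.frame (species, gene_id, one 0/1
#'   column per feature), and \code{summary}, a species x feature count
#'   matrix.
#' @export
conservation_scan <- function(ortholog_regions, pssms, final_features,
                              target_rate = 1 / 5000,
                              recalibrate = c("auto", "always", "never"),
                              window = 100L, max_order = 3L) {
  recalibrate <- match.arg(recalibrate)
  recs <- list()
  for (sp in names(ortholog_regions)) {
    regs <- ortholog_regions[[sp]]
    if (is.null(regs) || !nrow(regs)) {
      warning("species '", sp, "' has no regions; skipped")
      next
    }
    sp_pssms <- pssms
    enough <- sum(nchar(regs$sequence)) >= 10 / target_rate
    if (recalibrate == "always" || (recalibrate == "auto" && enough)) {
      sp_pssms <- lapply(pssms, calibrate_threshold,
                         background_regions = regs$sequence,
                         target_rate = target_rate)
    }
    hits <- scan_regions(sp_pssms, regs)
    per <- split(hits, factor(hits$gene_id, levels = regs$gene_id))
    prof <- t(vapply(per, feature_presence_profile,
                     integer(length(final_features)),
                     final_features = final_features, window = window,
                     max_order = max_order))
    colnames(prof) <- final_features
    recs[[sp]] <- data.frame(species = sp, gene_id = regs$gene_id,
                             prof, check.names = FALSE,
                             stringsAsFactors = FALSE)
  }
  if (!length(recs)) stop("no species with regions to scan")
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  summ <- t(vapply(recs, function(r)
    colSums(as.matrix(r[final_features])), numeric(length(final_features))))
  colnames(summ) <- final_features
  list(records = records, summary = summ)
}
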