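#' Fit a structural-feature model of regulatory architecture
#'
#' The central model fit. Starting from a binary feature matrix over positive
#' and negative regulatory regions, the fit (i) removes irrelevant and
#' redundant features with the symmetrical-uncertainty correlation filter
#' ([fcbf_filter()]), (ii) weights the surviving features with the
#' Kullback-Leibler relevance metric ([kl_weights()]), and (iii) selects the
#' optimal feature subset with a genetic algorithm under stratified
#' cross-validation ([ga_select()]), keeping the features present in the
#' consensus of the fold winners. Held-out AUCs are computed in nested mode:
#' the filter and the weights are re-estimated on each training part, so the
#' reported cross-validated AUC is not biased by label reuse. The deployed
#' weights (used by [score_genome()] and [predict.crm_fit()]) are computed
#' once on the full matrix and normalised to sum to 1.
#'
#' @param fm A \code{crm_features} matrix (see [binarize()]).
#' @param delta Relevance threshold of the correlation filter.
#' @param smoothing Laplace smoothing of the KL weights.
#' @param control A [ga_config()].
#' @return Object of class \code{crm_fit} with elements
#'   \code{final_features}, \code{weights} (a \code{crm_weights} over the
#'   filtered feature set), \code{filtered}, \code{cv}, \code{fold_winners},
#'   \code{mean_test_auc}, \code{traces}, \code{control}, \code{call}.
#' @seealso [score_genome()], [predict.crm_fit()]
#' @export
crm_fit <- function(fm, delta = 0, smoothing = 1, control = ga_config()) {
  stopifnot(inherits(fm, "crm_features"))
  kept <- fcbf_filter(fm, delta = delta)
  sel <- ga_select(fm, weights = NULL, config = control,
                   delta = delta, smoothing = smoothing)
  # deployment weight space: full-data filtered set plus any consensus
  # feature a training fold surfaced that the full-data filter dropped
  wspace <- union(fm$features[kept], sel$final_features)
  wspace <- fm$features[fm$features %in% wspace]
  w <- kl_weights(crm_features(fm$values[, wspace, drop = FALSE], fm$labels),
                  smoothing = smoothing)
  structure(list(final_features = sel$final_features,
                 weights = w,
                 filtered = fm$features[kept],
                 cv = sel$cv,
                 fold_winners = sel$fold_winners,
                 mean_test_auc = sel$mean_test_auc,
                 traces = sel$traces,
                 repeat_chosen = sel$repeat_chosen,
                 n_features_input = length(fm$features),
                 control = control,
                 call = match.call()),
            class = "crm_fit")
}

#' @export
print.crm_fit <- function(x, ...) {
  cat("Structural-feature model of cis-regulatory architecture\n")
  cat(sprintf("  features: %d in library -> %d after correlation filter -> %d in consensus set\n",
              x$n_features_input, length(x$filtered),
              length(x$final_features)))
  cat(sprintf("  cross-validated AUC (mean of %d folds): %.3f\n",
              nrow(x$cv), x$mean_test_auc))
  invisible(x)
}

#' @export
summary.crm_fit <- function(object, ...) {
  w <- object$weights$weights
  ff <- object$final_features
  cons <- table(unlist(object$fold_winners))[ff]
  tab <- data.frame(feature = ff,
                    weight = unname(w[ff]),
                    folds = as.integer(cons),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$weight), ]
  rownames(tab) <- NULL
  out <- list(fit = object, features = tab, cv = object$cv)
  class(out) <- "summary.crm_fit"
  out
}

#' @export
print.summary.crm_fit <- function(x, ...) {
  print(x$fit)
  cat("\nHeld-out AUC per fold:\n")
  print(x$cv, row.names = FALSE)
  cat("\nConsensus features (weight, folds selecting them):\n")
  print(x$features, row.names = FALSE)
  invisible(x)
}

#' @describeIn crm_fit Normalised weights of the consensus features.
#' @param object,... S3 method arguments.
#' @export
coef.crm_fit <- function(object, ...) {
  object$weights$weights[object$final_features]
}

#' Score new regions with a fitted model
#'
#' The score of a region is the sum of the weights of the consensus features
#' it contains (between 0 and 1, since weights are normalised over the
#' weighted feature space).
#'
#' @param object A \code{crm_fit}.
#' @param newdata Either a \code{crm_features} matrix containing the model's
#'   features, or a data.frame of motif hits with a \code{gene_id} column
#'   (as from [scan_regions()]) together with \code{region_ids}.
#' @param region_ids Region ids when \code{newdata} is a hit table.
#' @param window,max_order Feature enumeration parameters (hit-table input).
#' @param ... Unused.
#' @return Named numeric score vector.
#' @export
predict.crm_fit <- function(object, newdata, region_ids = NULL,
                            window = 100L, max_order = 3L, ...) {
  ff <- object$final_features
  w <- object$weights$weights
  if (inherits(newdata, "crm_features")) {
    miss <- setdiff(ff, newdata$features)
    prof <- matrix(0L, nrow(newdata$values), length(ff),
                   dimnames = list(rownames(newdata$values), ff))
    have <- intersect(ff, newdata$features)
    prof[, have] <- newdata$values[, have, drop = FALSE]
    drop(prof %*% w[ff])
  } else {
    if (is.null(region_ids)) region_ids <- unique(newdata$gene_id)
    prof <- t(vapply(split(newdata,
                           factor(newdata$gene_id, levels = region_ids)),
                     feature_presence_profile, integer(length(ff)),
                     final_features = ff, window = window,
                     max_order = max_order))
    stats::setNames(drop(prof %*% w[ff]), region_ids)
  }
}

#' @describeIn crm_fit Plot the GA fitness trace of each cross-validation
#'   fold.
#' @param x A \code{crm_fit}.
#' @export
plot.crm_fit <- function(x, ...) {
  tr <- x$traces
  ng <- max(1L, max(lengths(tr)))
  m <- sapply(tr, function(t) c(t, rep(NA, ng - length(t))))
  if (!is.matrix(m)) m <- matrix(m, nrow = ng)
  graphics::matplot(m, type = "l", lty = 1,
                    xlab = "generation", ylab = "best training fitness",
                    main = "GA convergence per fold", ...)
  invisible(x)
}
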