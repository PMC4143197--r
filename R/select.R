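#' Symmetrical uncertainty between two binary vectors
#'
#' \eqn{SU = 2 [H(X) - H(X|Y)] / (H(X) + H(Y))} with entropies in bits;
#' returns 0 when both entropies are zero.
#'
#' @param x,y Binary vectors of equal length >= 2.
#' @return Value in [0, 1].
#' @export
symmetrical_uncertainty <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2) stop("need length >= 2")
  su_vec(matrix(as.integer(x), ncol = 1), as.integer(y))[1]
}

# Vectorized SU between each column of a 0/1 matrix X and a 0/1 vector y.
#' @noRd
su_vec <- function(X, y) {
  n <- nrow(X)
  cx <- colSums(X)
  n11 <- as.vector(crossprod(X, y))
  ny <- sum(y)
  n10 <- cx - n11
  n01 <- ny - n11
  n00 <- n - cx - n01
  h2 <- function(p) ifelse(p > 0, -p * log2(p), 0)
  hx <- h2(cx / n) + h2(1 - cx / n)
  hy <- h2(ny / n) + h2(1 - ny / n)
  hxy <- h2(n11 / n) + h2(n10 / n) + h2(n01 / n) + h2(n00 / n)
  su <- 2 * (hx + hy - hxy) / (hx + hy)
  su[hx + hy == 0] <- 0
  # clip tiny negative rounding noise
  pmin(pmax(su, 0), 1)
}

#' Fast correlation-based feature filter (predominance)
#'
#' Features are ranked by their symmetrical uncertainty with the class label;
#' those with \eqn{SU \le \delta} are dropped, and the ranked list is then
#' swept so that a feature g is removed whenever an earlier retained feature
#' f satisfies \eqn{SU(f, g) \ge SU(g, class)}. Rank ties break by feature
#' index for determinism.
#'
#' @param fm A \code{crm_features} object (both classes present).
#' @param delta Relevance threshold (default 0).
#' @return Integer indices of retained features, in ranking order.
#' @export
fcbf_filter <- function(fm, delta = 0) {
  y <- fm$labels
  if (length(unique(y)) < 2) stop("labels must contain both classes")
  X <- fm$values
  su_c <- su_vec(X, y)
  ord <- order(-su_c, seq_along(su_c))
  cand <- ord[su_c[ord] > delta]
  retained <- integer(0)
  while (length(cand)) {
    f <- cand[1]
    retained <- c(retained, f)
    cand <- cand[-1]
    if (length(cand)) {
      su_fg <- su_vec(X[, cand, drop = FALSE], X[, f])
      cand <- cand[su_fg < su_c[cand]]
    }
  }
  retained
}

#' Kullback-Leibler feature weights
#'
#' For feature i and observed value \eqn{j \in \{0,1\}},
#' \eqn{D_{KL}(C|o_{ij}) = \sum_c P(c|o_{ij}) \log_2 (P(c|o_{ij}) / P(c))}
#' and the raw weight is \eqn{w(i) = \sum_j P(o_{ij}) D_{KL}(C|o_{ij})};
#' weights are then normalised to sum to 1. Conditional probabilities use
#' add-\code{smoothing} Laplace smoothing over the 2x2 table so rare cells
#' never produce log(0); \code{smoothing = 0} gives the plug-in estimate.
#' Features independent of the class get raw weight 0.
#'
#' @param fm A \code{crm_features} object with both classes present.
#' @param smoothing Laplace pseudo-count per cell (default 1).
#' @return Object of class \code{crm_weights}: list(weights (normalised,
#'   named), raw, prior).
#' @export
kl_weights <- function(fm, smoothing = 1) {
  y <- fm$labels
  if (length(unique(y)) < 2) stop("labels must contain both classes")
  X <- fm$values
  n <- nrow(X)
  prior <- c(`0` = mean(y == 0), `1` = mean(y == 1))
  n11 <- as.vector(crossprod(X, y))          # feature=1, class=1
  n1 <- colSums(X)                           # feature=1
  n10 <- n1 - n11                            # feature=1, class=0
  n01 <- sum(y) - n11                        # feature=0, class=1
  n0 <- n - n1
  n00 <- n0 - n01
  dkl <- function(p1, p0, pr1, pr0) {
    t1 <- ifelse(p1 > 0, p1 * log2(p1 / pr1), 0)
    t0 <- ifelse(p0 > 0, p0 * log2(p0 / pr0), 0)
    t1 + t0
  }
  s <- smoothing
  pc1_f1 <- (n11 + s) / (n1 + 2 * s); pc0_f1 <- (n10 + s) / (n1 + 2 * s)
  pc1_f0 <- (n01 + s) / (n0 + 2 * s); pc0_f0 <- (n00 + s) / (n0 + 2 * s)
  # cells of an absent value (n_j = 0, smoothing 0) contribute nothing
  d1 <- ifelse(n1 + 2 * s > 0, dkl(pc1_f1, pc0_f1, prior["1"], prior["0"]), 0)
  d0 <- ifelse(n0 + 2 * s > 0, dkl(pc1_f0, pc0_f0, prior["1"], prior["0"]), 0)
  raw <- (n1 / n) * d1 + (n0 / n) * d0
  raw <- pmax(raw, 0)
  names(raw) <- fm$features
  w <- if (sum(raw) > 0) raw / sum(raw) else raw
  structure(list(weights = w, raw = raw, prior = prior),
            class = "crm_weights")
}

#' @export
print.crm_weights <- function(x, ...) {
  cat(sprintf("<crm_weights> %d features, class prior P(1) = %.3f\n",
              length(x$weights), x$prior["1"]))
  invisible(x)
}

#' Weighted score of a region under a feature subset
#'
#' \eqn{score = \sum_i subset_i \, w_i \, x_i}.
#'
#' @param region_features Binary presence vector.
#' @param weights Numeric weight vector (same length).
#' @param subset_bits Binary subset indicator (same length).
#' @return Single numeric score.
#' @export
score_with_subset <- function(region_features, weights, subset_bits) {
  stopifnot(length(region_features) == length(weights),
            length(weights) == length(subset_bits))
  sum(subset_bits * weights * region_features)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, ties counted 1/2.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1 = positive).
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# Classification accuracy at the Youden-optimal threshold (max sens+spec-1),
# used for the GA's early-stopping rule.
#' @noRd
youden_accuracy <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  best <- which.max(sens + spec - 1)
  (sens[best] * length(pos) + spec[best] * length(neg)) / length(scores)
}

#' Genetic-algorithm configuration
#'
#' Canonical GA settings: fitness-proportionate (roulette) parent selection,
#' single-point crossover, independent per-bit mutation, elitism of one. The
#' search stops once the best chromosome reaches
#' \code{accuracy_stop} classification accuracy (at the Youden-optimal score
#' threshold) on the training folds, or after \code{max_iterations}
#' generations. Cross-validation is stratified \code{n_folds}-fold, repeated
#' \code{n_repeats} times with fresh fold assignments and GA seeds; the
#' repeat with the best mean held-out AUC is kept, and the consensus feature
#' set collects features present in at least \code{consensus_min} of the fold
#' winners.
#'
#' @param population_size Chromosomes per generation.
#' @param crossover_rate Probability a parent pair recombines.
#' @param mutation_rate Per-bit flip probability; default \code{1/k} for k
#'   candidate features.
#' @param max_iterations Generation cap.
#' @param accuracy_stop Early-stopping training accuracy.
#' @param n_folds,n_repeats,consensus_min Cross-validation layout.
#' @param fitness \code{"auc"} (default) or \code{"accuracy"}.
#' @param seed Master seed; all folds/repeats derive substreams from it.
#' @return List of class \code{crm_ga_config}.
#' @export
ga_config <- function(population_size = 100L, crossover_rate = 0.8,
                      mutation_rate = NULL, max_iterations = 10000L,
                      accuracy_stop = 0.9, n_folds = 5L, n_repeats = 1L,
                      consensus_min = 3L, fitness = c("auc", "accuracy"),
                      seed = 1L) {
  fitness <- match.arg(fitness)
  stopifnot(population_size >= 2, crossover_rate >= 0, crossover_rate <= 1,
            is.null(mutation_rate) ||
              (mutation_rate >= 0 && mutation_rate <= 1),
            max_iterations >= 1, accuracy_stop > 0, accuracy_stop <= 1,
            n_folds >= 2, n_repeats >= 1, consensus_min >= 1)
  structure(list(population_size = as.integer(population_size),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 max_iterations = as.integer(max_iterations),
                 accuracy_stop = accuracy_stop,
                 n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 consensus_min = as.integer(consensus_min),
                 fitness = fitness, seed = as.integer(seed)),
            class = "crm_ga_config")
}

# One GA run on a training matrix. X: n x k 0/1, w: weights (length k),
# y: labels. Returns best chromosome, its fitness, and the fitness trace.
#' @noRd
ga_run <- function(X, y, w, config, seed) {
  k <- ncol(X)
  mut <- config$mutation_rate %||% (1 / k)
  pop_n <- config$population_size
  with_seed(seed, {
    pop <- matrix(stats::rbinom(pop_n * k, 1L, 0.5), pop_n, k)
    eval_pop <- function(pop) {
      S <- X %*% (t(pop) * w)                    # n x pop score matrix
      if (config$fitness == "auc")
        apply(S, 2, auc, labels = y)
      else
        apply(S, 2, youden_accuracy, labels = y)
    }
    fit <- eval_pop(pop)
    trace <- numeric(0)
    gen <- 0L
    stopped <- "max_iterations"
    repeat {
      gen <- gen + 1L
      best <- which.max(fit)
      trace[gen] <- fit[best]
      sc_best <- as.vector(X %*% (pop[best, ] * w))
      if (youden_accuracy(sc_best, y) >= config$accuracy_stop) {
        stopped <- "accuracy"
        break
      }
      if (gen >= config$max_iterations) break
      # roulette selection; degenerate all-zero fitness -> uniform
      p <- if (sum(fit) > 0) fit / sum(fit) else rep(1 / pop_n, pop_n)
      parents <- sample.int(pop_n, 2L * pop_n, replace = TRUE, prob = p)
      nxt <- matrix(0L, pop_n, k)
      nxt[1, ] <- pop[best, ]                    # elitism of 1
      for (i in 2:pop_n) {
        a <- pop[parents[2 * i - 1], ]; b <- pop[parents[2 * i], ]
        child <- a
        if (k >= 2 && stats::runif(1) < config$crossover_rate) {
          cut <- sample.int(k - 1L, 1L)
          child <- c(a[seq_len(cut)], b[(cut + 1L):k])
        }
        flip <- stats::runif(k) < mut
        child[flip] <- 1L - child[flip]
        nxt[i, ] <- child
      }
      pop <- nxt
      fit <- eval_pop(pop)
    }
    best <- which.max(fit)
    list(bits = pop[best, ], fitness = fit[best], trace = trace,
         generations = gen, stopped = stopped)
  })
}

# Stratified fold assignment; errors if a class cannot reach every fold.
#' @noRd
stratified_folds <- function(y, n_folds, seed) {
  if (min(sum(y == 1), sum(y == 0)) < n_folds)
    stop("too few members of a class for ", n_folds, "-fold stratification")
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in c(0L, 1L)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' Genetic-algorithm feature-subset selection under cross-validation
#'
#' Regions are split into stratified folds; on each fold's training part a GA
#' evolves feature-subset chromosomes maximising the fitness of the weighted
#' region score, and the winning chromosome's held-out AUC is recorded. With
#' \code{weights = NULL} (nested mode, the default used by [crm_fit()]) the
#' correlation-based filter and the Kullback-Leibler weights are recomputed
#' on each training part so held-out AUCs are unbiased; supplying a
#' \code{crm_weights} object instead evaluates the given (already filtered)
#' feature space directly. The cross-validation is repeated
#' \code{config$n_repeats} times and the repeat with the best mean held-out
#' AUC kept; the consensus set collects features present in at least
#' \code{config$consensus_min} fold winners.
#'
#' @param fm A \code{crm_features} matrix (filtered already when
#'   \code{weights} is supplied).
#' @param weights Optional \code{crm_weights} over \code{fm$features}.
#' @param config A [ga_config()].
#' @param delta,smoothing Filter threshold and KL smoothing used in nested
#'   mode.
#' @return List with elements \code{final_features} (consensus ids),
#'   \code{fold_winners} (list of feature-id vectors), \code{cv} (data.frame
#'   fold, test_auc, generations, stopped), \code{mean_test_auc},
#'   \code{traces}, \code{repeat_chosen}, \code{config}.
#' @export
ga_select <- function(fm, weights = NULL, config = ga_config(),
                      delta = 0, smoothing = 1) {
  y <- fm$labels
  nested <- is.null(weights)
  run_repeat <- function(r) {
    fold <- stratified_folds(y, config$n_folds,
                             sub_seed(config$seed, 101L, r))
    winners <- vector("list", config$n_folds)
    traces <- vector("list", config$n_folds)
    cv <- data.frame(fold = seq_len(config$n_folds), test_auc = NA_real_,
                     generations = NA_integer_, stopped = NA_character_)
    for (f in seq_len(config$n_folds)) {
      tr <- fold != f
      if (nested) {
        sub <- crm_features(fm$values[tr, , drop = FALSE], y[tr])
        kept <- fcbf_filter(sub, delta = delta)
        feats <- fm$features[kept]
        w_all <- if (length(kept)) kl_weights(
          crm_features(sub$values[, kept, drop = FALSE], y[tr]),
          smoothing = smoothing)$weights else numeric(0)
      } else {
        feats <- fm$features
        w_all <- weights$weights
      }
      if (!length(feats)) {
        winners[[f]] <- character(0)
        cv$test_auc[f] <- 0.5
        cv$generations[f] <- 0L; cv$stopped[f] <- "no_features"
        traces[[f]] <- numeric(0)
        next
      }
      Xtr <- fm$values[tr, feats, drop = FALSE]
      res <- ga_run(Xtr, y[tr], w_all[feats], config,
                    sub_seed(config$seed, 211L, r, f))
      winners[[f]] <- feats[res$bits == 1L]
      sel <- feats[res$bits == 1L]
      Xte <- fm$values[!tr, feats, drop = FALSE]
      sc <- as.vector(Xte %*% (res$bits * w_all[feats]))
      cv$test_auc[f] <- if (length(unique(sc)) == 1) 0.5
                        else auc(sc, y[!tr])
      cv$generations[f] <- res$generations
      cv$stopped[f] <- res$stopped
      traces[[f]] <- res$trace
    }
    list(winners = winners, cv = cv, traces = traces,
         mean_auc = mean(cv$test_auc))
  }
  reps <- lapply(seq_len(config$n_repeats), run_repeat)
  best_r <- which.max(vapply(reps, `[[`, numeric(1), "mean_auc"))
  br <- reps[[best_r]]
  counts <- table(unlist(br$winners))
  final <- sort(names(counts)[counts >= config$consensus_min])
  list(final_features = final, fold_winners = br$winners, cv = br$cv,
       mean_test_auc = br$mean_auc, traces = br$traces,
       repeat_chosen = best_r, config = config)
}
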