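test_that("symmetrical uncertainty matches an independent entropy oracle", {
  x <- rep(c(0L, 1L), 20)
  expect_equal(symmetrical_uncertainty(x, x), 1.0)
  expect_equal(symmetrical_uncertainty(rep(0L, 40), x), 0.0)
  expect_equal(symmetrical_uncertainty(rep(1L, 10), rep(0L, 10)), 0.0)
  # joint table [[30,10],[10,30]]
  x2 <- rep(c(0L, 0L, 1L, 1L), c(30, 10, 10, 30))
  y2 <- rep(c(0L, 1L, 0L, 1L), c(30, 10, 10, 30))
  expect_equal(symmetrical_uncertainty(x2, y2), oracle_su(x2, y2),
               tolerance = 1e-12)
  expect_error(symmetrical_uncertainty(1:3, 1:4), "mismatch")
})

test_that("the correlation filter removes duplicates and irrelevant features", {
  set.seed(1)
  y <- rep(c(1L, 0L), each = 30)
  perfect <- y
  vals <- cbind(f1 = perfect, f2 = perfect,      # exact duplicate
                n1 = rbinom(60, 1, 0.5), n2 = rbinom(60, 1, 0.5))
  fm <- crm_features(vals, y)
  kept <- fcbf_filter(fm)
  expect_equal(kept[1], 1L)                      # highest SU, first index
  expect_false(2L %in% kept)                     # duplicate removed
  # features exactly independent of the class are dropped at delta = 0
  flat <- cbind(a = rep(c(0L, 1L), 30), b = rep(c(1L, 0L), 30))
  fm2 <- crm_features(flat, y)
  expect_length(fcbf_filter(fm2), 0L)
  expect_error(fcbf_filter(crm_features(flat, rep(1L, 60))), "both classes")
})

test_that("the filter equals the exhaustive predominance oracle", {
  for (s in 1:8) {
    set.seed(s)
    n <- 120
    y <- rbinom(n, 1, 0.4)
    X <- cbind(matrix(rbinom(n * 2, 1, ifelse(y == 1, 0.8, 0.2)), n, 2),
               matrix(rbinom(n * 6, 1, 0.5), n, 6))
    X[, 3] <- X[, 1]; X[, 4] <- X[, 2]          # redundant copies
    colnames(X) <- sprintf("f%d", 1:8)
    if (length(unique(y)) < 2) next
    fm <- crm_features(X, y)
    expect_identical(fcbf_filter(fm), oracle_fcbf(X, y))
  }
})

test_that("filter output is invariant to duplicating a retained feature", {
  set.seed(12)
  y <- rep(c(1L, 0L), c(40, 80))
  X <- cbind(a = rbinom(120, 1, ifelse(y == 1, 0.9, 0.1)),
             b = rbinom(120, 1, 0.4), c = rbinom(120, 1, 0.6))
  fm <- crm_features(X, y)
  kept <- fcbf_filter(fm)
  Xdup <- cbind(X, a2 = X[, "a"])
  kept_dup <- fcbf_filter(crm_features(Xdup, y))
  expect_identical(colnames(X)[kept], colnames(Xdup)[kept_dup])
})

test_that("KL weights reproduce the hand-computed oracle", {
  y <- rep(c(1L, 0L), each = 20)
  vals <- cbind(same = y, indep = rep(c(0L, 1L), 20))
  fm <- crm_features(vals, y)
  w0 <- kl_weights(fm, smoothing = 0)
  # balanced classes, feature == class: w = 0.5*log2(2) + 0.5*log2(2) = 1 bit
  expect_equal(unname(w0$raw["same"]), 1.0)
  expect_equal(unname(w0$raw["indep"]), 0.0)
  expect_equal(sum(w0$weights), 1.0, tolerance = 1e-9)
  # smoothing keeps weights finite and ordered the same way
  w1 <- kl_weights(fm, smoothing = 1)
  expect_true(all(is.finite(w1$raw)))
  expect_gt(w1$raw["same"], w1$raw["indep"])
  expect_equal(sum(w1$weights), 1.0, tolerance = 1e-9)
})

test_that("subset scores are additive in present features", {
  w <- c(0.5, 0.3, 0.2)
  x <- c(1, 1, 1)
  expect_equal(score_with_subset(x, w, c(0, 0, 0)), 0)
  expect_equal(score_with_subset(x, w, c(1, 1, 1)), 1.0)
  s0 <- score_with_subset(c(1, 0, 1), w, c(1, 0, 0))
  s1 <- score_with_subset(c(1, 0, 1), w, c(1, 0, 1))
  expect_equal(s1 - s0, 0.2)
})

test_that("AUC follows the Mann-Whitney pair-counting oracle", {
  expect_equal(auc(c(5, 4, 1, 2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc(rep(3, 6), rep(c(1, 0), 3)), 0.5)
  sc <- c(3, 2, 1, 2); lb <- c(1, 1, 0, 0)
  expect_equal(auc(sc, lb), 0.875)
  expect_equal(auc(sc, lb), oracle_auc(sc, lb))
  set.seed(8)
  sc2 <- rnorm(30); lb2 <- rbinom(30, 1, 0.5)
  if (length(unique(lb2)) == 2) {
    expect_equal(auc(sc2, lb2), oracle_auc(sc2, lb2))
    # invariance under strictly monotone transforms
    expect_equal(auc(exp(sc2), lb2), auc(sc2, lb2))
    expect_equal(auc(rank(sc2), lb2), auc(sc2, lb2))
  }
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("the GA recovers informative features and reports honest CV AUC", {
  fm <- informative_fm(n_pos = 60, n_neg = 140, n_noise = 17, seed = 4)
  cfg <- ga_config(population_size = 60, max_iterations = 60, seed = 4)
  # supplied-weights mode: evaluate the given feature space directly
  w <- kl_weights(fm)
  sel <- ga_select(fm, weights = w, config = cfg)
  expect_true(all(c("inf1", "inf2") %in% sel$final_features))
  expect_gt(mean(sel$cv$test_auc), 0.9)
  # nested mode re-filters per fold and behaves the same here
  sel2 <- ga_select(fm, config = cfg)
  expect_true(all(c("inf1", "inf2") %in% sel2$final_features))
  expect_gt(sel2$mean_test_auc, 0.9)
})

test_that("impossible consensus thresholds empty the final set", {
  fm <- informative_fm(seed = 6)
  cfg <- ga_config(population_size = 30, max_iterations = 10,
                   consensus_min = 6L, n_folds = 5L, seed = 6)
  sel <- ga_select(fm, weights = kl_weights(fm), config = cfg)
  expect_length(sel$final_features, 0L)
})

test_that("folds stay stratified and tiny classes are rejected", {
  y <- c(rep(1L, 3), rep(0L, 50))
  vals <- matrix(rbinom(53 * 4, 1, 0.5), 53, 4,
                 dimnames = list(NULL, paste0("f", 1:4)))
  fm <- crm_features(vals, y)
  expect_error(ga_select(fm, weights = kl_weights(fm),
                         config = ga_config(n_folds = 5, seed = 1)),
               "stratification")
})
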