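# independent PLS reference: weights from the SVD of the cross-covariance
# X'Y at each deflation step (no power iteration)
svd_pls <- function(X, Y, ncomp) {
  Xc <- scale(X, TRUE, TRUE)
  Yc <- scale(Y, TRUE, FALSE)
  W <- matrix(0, ncol(X), ncomp); Tm <- matrix(0, nrow(X), ncomp)
  ssy <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    sv <- svd(crossprod(Xc, Yc))
    w <- sv$u[, 1]
    tt <- Xc %*% w
    q <- crossprod(Yc, tt) / sum(tt^2)
    p <- crossprod(Xc, tt) / sum(tt^2)
    W[, a] <- w; Tm[, a] <- tt
    ssy[a] <- sum(tt^2) * sum(q^2)
    Xc <- Xc - tt %*% t(p)
    Yc <- Yc - tt %*% t(q)
  }
  list(W = W, Tm = Tm, ssy = ssy)
}

test_that("PLSDA separates constructed classes and weights the informative column", {
  set.seed(1)
  X <- matrix(stats::rnorm(40 * 6, sd = 0.2), 40, 6)
  y <- factor(rep(c("a", "b"), each = 20))
  X[, 3] <- X[, 3] + ifelse(y == "a", 3, -3)
  colnames(X) <- paste0("f", 1:6)
  m <- fit_plsda(X, y, ncomp = 2)
  s1 <- m$scores[, 1]
  expect_true(max(s1[y == "b"]) < min(s1[y == "a"]) ||
                max(s1[y == "a"]) < min(s1[y == "b"]))
  expect_equal(which.max(abs(m$weights[, 1])), c(f3 = 3L))
  expect_error(fit_plsda(X, y, ncomp = 0), "ncomp")
  Xz <- X; Xz[, 2] <- 1
  expect_error(fit_plsda(Xz, y), "zero-variance.*f2")
})

test_that("NIPALS matches the SVD-based reference and scores are orthogonal", {
  set.seed(4)
  X <- matrix(stats::rnorm(30 * 8), 30, 8)
  y <- factor(rep(c("a", "b", "c"), each = 10))
  Y <- stats::model.matrix(~ y - 1)
  m <- fit_plsda(X, y, ncomp = 3)
  ref <- svd_pls(X, Y, 3)
  for (a in 1:3) {
    sgn <- sign(sum(m$weights[, a] * ref$W[, a]))
    expect_equal(m$weights[, a], sgn * ref$W[, a], tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(m$ssy[a], ref$ssy[a], tolerance = 1e-6)
  }
  G <- crossprod(m$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  expect_true(all(abs(colSums(m$weights^2) - 1) < 1e-10))
})

test_that("VIP scores satisfy the mean-square identity and the defining formula", {
  set.seed(9)
  X <- matrix(stats::rnorm(24 * 7), 24, 7)
  y <- factor(rep(c("a", "b", "c"), each = 8))
  m <- fit_plsda(X, y, ncomp = 2)
  v <- vip_scores(m)
  expect_equal(mean(v^2), 1, tolerance = 1e-12)
  # from-the-definition recomputation
  p <- nrow(m$weights)
  vip_hand <- vapply(seq_len(p), function(j) {
    num <- 0; den <- 0
    for (a in seq_len(m$ncomp)) {
      wja <- m$weights[j, a] / sqrt(sum(m$weights[, a]^2))
      num <- num + m$ssy[a] * wja^2
      den <- den + m$ssy[a]
    }
    sqrt(p * num / den)
  }, numeric(1))
  expect_equal(unname(v), vip_hand, tolerance = 1e-10)
  # exchangeable features: every VIP equals 1
  Xe <- matrix(rep(stats::rnorm(24), 4), 24, 4)
  ye <- factor(rep(c("a", "b"), each = 12))
  ve <- vip_scores(fit_plsda(Xe, ye, ncomp = 1, scale = FALSE))
  expect_equal(unname(ve), rep(1, 4), tolerance = 1e-10)
})

test_that("penalized logistic spans the unregularized and fully-shrunk limits", {
  set.seed(2)
  X <- matrix(stats::rnorm(30 * 2, sd = 0.3), 30, 2)
  y <- factor(rep(c("a", "b", "c"), each = 10))
  X[, 1] <- X[, 1] + c(-4, 0, 4)[as.integer(y)]
  X[, 2] <- X[, 2] + c(0, 4, -4)[as.integer(y)]
  f_big <- fit_penalized_logistic(X, y, C = 1e6)
  expect_equal(mean(predict(f_big, X) == y), 1)
  f_tiny <- fit_penalized_logistic(X, y, C = 1e-9)
  expect_lt(max(abs(f_tiny$W)), 1e-4)
  probs <- predict(f_tiny, X, type = "prob")
  expect_true(all(abs(probs - 1 / 3) < 1e-3))
  expect_error(fit_penalized_logistic(X, y, C = 0), "positive")
  expect_error(fit_penalized_logistic(X, factor(rep("a", 30))), "two classes")
})

test_that("the penalized optimum matches an independent optimizer and satisfies stationarity", {
  set.seed(6)
  X <- matrix(stats::rnorm(10 * 3), 10, 3)
  y <- factor(c("a", "b", "c", "a", "b", "c", "a", "b", "c", "a"))
  C <- 0.001
  fit <- fit_penalized_logistic(X, y, C = C)
  # independent route: generic quasi-Newton with numerical derivatives from
  # a different start
  X1 <- cbind(1, X)
  Yh <- stats::model.matrix(~ y - 1)
  nll <- function(w) {
    W <- matrix(w, 3, 4)
    S <- X1 %*% t(W)
    -sum(S[cbind(1:10, as.integer(y))] - log(rowSums(exp(S)))) +
      sum(w^2) / (2 * C)
  }
  ref <- stats::nlm(nll, rep(0.05, 12), gradtol = 1e-12, iterlim = 1000)
  expect_lt(max(abs(as.numeric(fit$W) - ref$estimate)), 1e-4)
  expect_equal(nll(as.numeric(fit$W)), ref$minimum, tolerance = 1e-8)
  # stationarity of the convex objective at the returned solution
  g <- numDeriv_grad(nll, as.numeric(fit$W))
  expect_lt(max(abs(g)), 1e-3)
})

test_that("cross-validation folds mice, standardizes on training data only", {
  sim <- small_cohort(seed = 10)
  pp <- preprocess_cohort(sim$samples, sim$wake, study_design())
  fm <- build_feature_matrix(pp$zmatrix, study_design())
  cv <- repeated_stratified_cv(fm$X, fm$y, fm$mouse, reps = 2, seed = 3,
                               instrument = TRUE)
  expect_true(all(cv$accuracies >= 0 & cv$accuracies <= 1))
  expect_true(all(cv$ci >= 0 & cv$ci <= 1))
  test_sets <- lapply(cv$instrumentation, `[[`, "test_mice")
  # the three folds partition the mice
  expect_setequal(unlist(test_sets), unique(fm$mouse))
  expect_equal(sum(lengths(test_sets)), length(unique(fm$mouse)))
  for (fold in cv$instrumentation) {
    train_rows <- !(fm$mouse %in% fold$test_mice)
    expect_equal(fold$train_mean, colMeans(fm$X[train_rows, , drop = FALSE]))
    expect_equal(fold$train_sd, apply(fm$X[train_rows, , drop = FALSE], 2,
                                      stats::sd))
  }
  # determinism under a fixed seed
  cv2 <- repeated_stratified_cv(fm$X, fm$y, fm$mouse, reps = 2, seed = 3)
  expect_identical(cv$accuracies, cv2$accuracies)
  expect_error(repeated_stratified_cv(fm$X, fm$y, fm$mouse, K = 7),
               "fewer mice than folds")
  bad_mouse <- fm$mouse; bad_mouse[1] <- tail(fm$mouse, 1)
  expect_error(repeated_stratified_cv(fm$X, fm$y, bad_mouse, reps = 1),
               "more than one label")
})

test_that("mouse-level altering of held-out data cannot affect training", {
  sim <- small_cohort(seed = 10)
  pp <- preprocess_cohort(sim$samples, sim$wake, study_design())
  fm <- build_feature_matrix(pp$zmatrix, study_design())
  cv <- repeated_stratified_cv(fm$X, fm$y, fm$mouse, reps = 1, seed = 5,
                               instrument = TRUE)
  fold1 <- cv$instrumentation[[1]]
  spiked <- fm$X
  spiked[fm$mouse %in% fold1$test_mice, ] <-
    spiked[fm$mouse %in% fold1$test_mice, ] + 1e6
  cv_spiked <- repeated_stratified_cv(spiked, fm$y, fm$mouse, reps = 1,
                                      seed = 5, instrument = TRUE)
  expect_equal(cv_spiked$instrumentation[[1]]$train_mean, fold1$train_mean)
  expect_equal(cv_spiked$instrumentation[[1]]$train_sd, fold1$train_sd)
})

test_that("permutation p-values hit the floor for strongly separated classes", {
  set.seed(12)
  n_mice <- 12
  mouse <- rep(sprintf("m%02d", 1:n_mice), each = 4)
  y <- factor(rep(rep(c("S6", "EW6"), each = n_mice / 2), each = 4),
              levels = c("S6", "EW6"))
  X <- matrix(stats::rnorm(length(y) * 5, sd = 0.2), ncol = 5)
  X[, 1] <- X[, 1] + ifelse(y == "S6", 5, -5)
  pt <- permutation_test(X, y, mouse, n_permutations = 99, reps_observed = 5,
                         reps_perm = 1, seed = 4)
  expect_equal(pt$observed$mean_accuracy, 1)
  expect_equal(pt$p, 1 / 100)
  expect_gte(pt$p, 1 / (pt$n_permutations + 1))
})

test_that("pairwise comparisons equal the full machinery restricted to two labels", {
  sim <- small_cohort(seed = 15)
  pp <- preprocess_cohort(sim$samples, sim$wake, study_design())
  fm <- build_feature_matrix(pp$zmatrix, study_design())
  pw <- pairwise_comparisons(fm$X, fm$y, fm$mouse, pairs = list(c("S6", "EW6")),
                             n_permutations = 10, reps_observed = 3,
                             reps_perm = 1, seed = 7)
  keep <- fm$y %in% c("S6", "EW6")
  direct <- permutation_test(fm$X[keep, , drop = FALSE],
                             droplevels(fm$y[keep]), fm$mouse[keep],
                             n_permutations = 10, reps_observed = 3,
                             reps_perm = 1, seed = 7 + 1)
  expect_equal(pw$S6_vs_EW6$observed$mean_accuracy,
               direct$observed$mean_accuracy)
  expect_equal(pw$S6_vs_EW6$perm_accuracies, direct$perm_accuracies)
  expect_error(pairwise_comparisons(fm$X, fm$y, fm$mouse,
                                    pairs = list(c("S6", "REM"))),
               "absent condition")
})
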