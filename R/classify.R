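#' Build the epoch-by-analyte feature matrix for classification
#'
#' Observation units are mouse-hour epochs over the requested hours (default
#' the first six experimental hours, during which each arm is in its
#' nominal behavioral state). Columns are region-tagged analytes from both
#' brain regions; the class label of an epoch is the arm's dominant
#' first-6-h state (`S6`, `EW6`, `SW6`). Requires a complete (imputed)
#' z-matrix.
#'
#' @param zm Imputed z-matrix tibble from [preprocess_cohort()].
#' @param design A [study_design()].
#' @param hours Hours to include (default 1:6).
#' @return List with `X` (numeric matrix, rows `mouse:hour`), `y` (factor of
#'   condition labels per row), `mouse` (character vector per row).
#' @export
build_feature_matrix <- function(zm, design, hours = 1:6) {
  x <- dplyr::filter(zm, .data$hour %in% hours)
  if (any(is.na(x$z))) stop("feature matrix requires an imputed z-matrix")
  x$feature <- paste(x$region, x$analyte_id, sep = ":")
  wide <- tidyr::pivot_wider(
    x[c("mouse_id", "group", "hour", "feature", "z")],
    names_from = "feature", values_from = "z"
  )
  wide <- wide[, c(TRUE, TRUE, TRUE, colSums(is.na(wide[, -(1:3)])) == 0)]
  X <- as.matrix(wide[, -(1:3)])
  rownames(X) <- paste(wide$mouse_id, wide$hour, sep = ":")
  cond <- design$groups$condition6[match(wide$group, design$groups$group)]
  list(X = X,
       y = factor(cond, levels = intersect(c("S6", "EW6", "SW6"), unique(cond))),
       mouse = wide$mouse_id)
}

#' Partial least squares discriminant analysis (PLS2, iterative deflation)
#'
#' Regresses the one-hot class indicator matrix on the feature matrix using
#' the classical nonlinear iterative partial least squares algorithm with
#' deflation. Weight vectors have unit norm and successive score vectors are
#' mutually orthogonal. Suited to flat data where features outnumber
#' observations.
#'
#' @param X Numeric feature matrix (rows = observations).
#' @param y Factor of class labels (or an already one-hot numeric matrix).
#' @param ncomp Number of components (default 2).
#' @param scale Standardize columns of `X` to unit variance (default TRUE;
#'   columns are always mean-centered).
#' @param tol,max_iter NIPALS convergence controls.
#' @return Object of class `plsda`: `weights` (p x A), `loadings`,
#'   `scores` (n x A), `y_loadings` (K x A), `ssy` (Y-variance captured per
#'   component), `explained_y` (fractions), centering/scaling vectors and
#'   class levels.
#' @export
fit_plsda <- function(X, y, ncomp = 2, scale = TRUE, tol = 1e-9, max_iter = 1000) {
  if (ncomp < 1) stop("ncomp must be at least 1")
  X <- as.matrix(X)
  if (is.factor(y) || is.character(y)) {
    y <- factor(y)
    Y <- stats::model.matrix(~ y - 1)
    colnames(Y) <- levels(y)
    lev <- levels(y)
  } else {
    Y <- as.matrix(y)
    lev <- colnames(Y)
  }
  x_center <- colMeans(X)
  x_scale <- if (scale) apply(X, 2, stats::sd) else rep(1, ncol(X))
  if (any(x_scale == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(X)[x_scale == 0], collapse = ", "))
  }
  Xc <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  Yc <- sweep(Y, 2, colMeans(Y))
  ss_y_total <- sum(Yc^2)
  n <- nrow(Xc); p <- ncol(Xc); K <- ncol(Yc)
  if (ncomp > min(n - 1, p)) stop("ncomp exceeds the rank bound of X")
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); Q <- matrix(0, K, ncomp)
  ssy <- numeric(ncomp)
  Xd <- Xc; Yd <- Yc
  for (a in seq_len(ncomp)) {
    u <- Yd[, which.max(colSums(Yd^2))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u)
      w <- w / sqrt(sum(w^2))
      tt <- Xd %*% w
      q <- crossprod(Yd, tt) / sum(tt^2)
      u <- Yd %*% q / sum(q^2)
      if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) break
      t_old <- tt
    }
    pp <- crossprod(Xd, tt) / sum(tt^2)
    W[, a] <- w; P[, a] <- pp; Tm[, a] <- tt; Q[, a] <- q
    ssy[a] <- sum(tt^2) * sum(q^2)      # Y sum-of-squares captured by t_a q_a'
    Xd <- Xd - tt %*% t(pp)
    Yd <- Yd - tt %*% t(q)
  }
  rownames(W) <- rownames(P) <- colnames(X)
  structure(list(weights = W, loadings = P, scores = Tm, y_loadings = Q,
                 ssy = ssy, explained_y = ssy / ss_y_total,
                 x_center = x_center, x_scale = x_scale, levels = lev,
                 ncomp = ncomp),
            class = "plsda")
}

#' Variable importance in projection (VIP) scores
#'
#' For feature j over A components,
#' `VIP_j = sqrt( p * sum_a SSY_a * (w_ja / ||w_a||)^2 / sum_a SSY_a )`
#' where `p` is the number of features and `SSY_a` the Y-variance captured
#' by component a. The mean of squared VIPs over features is exactly 1, so
#' features with VIP > 1 contribute more than an average feature; VIP > 1.0
#' conventionally marks the most influential variables.
#'
#' @param model A fitted [fit_plsda()] object.
#' @return Named numeric vector of VIP scores, decreasingly sortable.
#' @export
vip_scores <- function(model) {
  W <- model$weights
  wn <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  p <- nrow(W)
  v <- sqrt(p * as.numeric(wn^2 %*% model$ssy) / sum(model$ssy))
  names(v) <- rownames(W)
  v
}

#' Multinomial logistic regression with an l2 penalty
#'
#' Minimizes the penalized multinomial negative log-likelihood
#' `sum_i -log p(y_i | x_i) + (1 / (2C)) * ||W||^2` over the full parameter
#' matrix `W` (one row of weights plus intercept per class; the penalty
#' applies to every entry, which keeps the symmetric softmax
#' parameterization identifiable and makes the fully-shrunk limit predict
#' classes exchangeably rather than by class frequency). Smaller `C`
#' restricts the model. Optimization is BFGS on the convex objective with
#' analytic gradient.
#'
#' @param X Numeric feature matrix.
#' @param y Factor of class labels (at least 2 levels present).
#' @param C Inverse regularization strength (default 0.001).
#' @param maxit BFGS iteration cap.
#' @return Object of class `penlogit` with `W` (K x (p+1), intercept first),
#'   `levels`, `C`, and `converged`.
#' @export
fit_penalized_logistic <- function(X, y, C = 0.001, maxit = 200) {
  if (C <= 0) stop("C must be positive")
  y <- droplevels(factor(y))
  K <- nlevels(y)
  if (K < 2) stop("y must contain at least two classes")
  X1 <- cbind(`(Intercept)` = 1, as.matrix(X))
  n <- nrow(X1); p1 <- ncol(X1)
  Yh <- stats::model.matrix(~ y - 1)
  yi <- cbind(seq_len(n), as.integer(y))
  row_max <- function(S) {
    m <- S[, 1]
    for (k in 2:ncol(S)) m <- pmax(m, S[, k])
    m
  }
  obj <- function(w) {
    W <- matrix(w, K, p1)
    S <- tcrossprod(X1, W)               # n x K scores
    S <- S - row_max(S)
    logZ <- log(rowSums(exp(S)))
    -sum(S[yi] - logZ) + sum(w^2) / (2 * C)
  }
  grad <- function(w) {
    W <- matrix(w, K, p1)
    S <- tcrossprod(X1, W)
    E <- exp(S - row_max(S))
    Pm <- E / rowSums(E)
    as.numeric(crossprod(Pm - Yh, X1)) + w / C
  }
  fit <- stats::optim(rep(0, K * p1), obj, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  W <- matrix(fit$par, K, p1, dimnames = list(levels(y), colnames(X1)))
  structure(list(W = W, levels = levels(y), C = C,
                 converged = fit$convergence == 0),
            class = "penlogit")
}

#' @rdname fit_penalized_logistic
#' @param object A `penlogit` fit.
#' @param newdata Feature matrix to predict.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
#' @export
predict.penlogit <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X1 <- cbind(1, as.matrix(newdata))
  S <- tcrossprod(X1, object$W)
  if (type == "prob") {
    S <- S - apply(S, 1, max)
    P <- exp(S) / rowSums(exp(S))
    colnames(P) <- object$levels
    return(P)
  }
  factor(object$levels[max.col(S, ties.method = "first")], levels = object$levels)
}

# deal each condition's shuffled mice round-robin into K folds
stratified_mouse_folds <- function(mouse_labels, K) {
  fold <- integer(length(mouse_labels))
  names(fold) <- names(mouse_labels)
  offset <- 0L
  for (lv in levels(mouse_labels)) {
    idx <- which(mouse_labels == lv)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% K) + 1L
    offset <- offset + length(idx)      # rotate which fold gets the extra mouse
  }
  fold
}

# standardize by training statistics only; constant columns pass unscaled
standardize_by_train <- function(X_train, X_test) {
  mu <- colMeans(X_train)
  sg <- apply(X_train, 2, stats::sd)
  sg[sg == 0] <- 1
  list(train = sweep(sweep(X_train, 2, mu), 2, sg, "/"),
       test = sweep(sweep(X_test, 2, mu), 2, sg, "/"),
       mu = mu, sd = sg)
}

#' Repeated stratified cross-validation with mouse-level folds
#'
#' Mice (not epochs) are partitioned into `K` folds with the number of mice
#' from each condition approximately equal across folds, so all epochs of a
#' mouse share a fold and no information leaks between training and test
#' data. Feature standardization uses training-fold statistics only. The
#' partition is redrawn `reps` times; each repetition's accuracy is the
#' fraction of held-out epochs labeled correctly across its `K` folds. The
#' accuracy distribution over repetitions yields the non-parametric 95%
#' percentile confidence interval.
#'
#' @param X Feature matrix (epochs x features).
#' @param y Factor of epoch labels.
#' @param mouse Character vector of mouse ids per epoch.
#' @param K Number of folds (default 3).
#' @param reps Repetitions (default 100).
#' @param C Logistic regularization parameter (default 0.001).
#' @param seed Optional integer; when given, the fold sequence is drawn
#'   under a private RNG stream so results are reproducible.
#' @param instrument When TRUE, also return per-fold standardization means
#'   and fold memberships of the first repetition (used to audit the
#'   no-leakage property).
#' @return List of class `cv_result`: `mean_accuracy`, `accuracies`, `ci`
#'   (2.5/97.5 percentiles), `K`, `reps`, and optionally `instrumentation`.
#' @export
repeated_stratified_cv <- function(X, y, mouse, K = 3, reps = 100, C = 0.001,
                                   seed = NULL, instrument = FALSE) {
  y <- droplevels(factor(y))
  mouse_label <- tapply(as.character(y), mouse, function(v) {
    u <- unique(v)
    if (length(u) > 1) stop("a mouse carries more than one label")
    u
  })
  mouse_label <- factor(mouse_label, levels = levels(y))
  if (any(table(mouse_label) < K)) {
    stop("parameter error: fewer mice than folds in some condition")
  }
  run <- function() {
    acc <- numeric(reps)
    instr <- NULL
    for (r in seq_len(reps)) {
      fold <- stratified_mouse_folds(mouse_label, K)
      correct <- 0L; total <- 0L
      for (k in seq_len(K)) {
        test_mice <- names(fold)[fold == k]
        te <- mouse %in% test_mice
        std <- standardize_by_train(X[!te, , drop = FALSE], X[te, , drop = FALSE])
        fit <- fit_penalized_logistic(std$train, y[!te], C = C)
        pred <- predict(fit, std$test)
        correct <- correct + sum(pred == y[te])
        total <- total + sum(te)
        if (instrument && r == 1) {
          instr <- c(instr, list(list(fold = k, test_mice = test_mice,
                                      train_mean = std$mu, train_sd = std$sd)))
        }
      }
      acc[r] <- correct / total
    }
    list(acc = acc, instr = instr)
  }
  out <- if (is.null(seed)) run() else with_local_seed(seed, run())
  res <- list(mean_accuracy = mean(out$acc), accuracies = out$acc,
              ci = stats::quantile(out$acc, c(0.025, 0.975), names = FALSE),
              K = K, reps = reps)
  if (instrument) res$instrumentation <- out$instr
  structure(res, class = "cv_result")
}

#' Permutation test of classifier accuracy
#'
#' Condition labels are permuted at the mouse level (each mouse keeps all
#' its epochs; the multiset of labels is preserved), the full
#' cross-validation machinery is re-run per permutation, and the p-value is
#' `(1 + #\{permuted accuracy >= observed\}) / (1 + n_permutations)`. The
#' permutation distribution also captures the expected chance accuracy given
#' the design-matrix structure (about 1/k for k classes).
#'
#' @inheritParams repeated_stratified_cv
#' @param n_permutations Number of label permutations (default 1000).
#' @param reps_observed CV repetitions for the observed accuracy (default
#'   100).
#' @param reps_perm CV repetitions inside each permutation (default 3; the
#'   permutation p-value integrates over permutations, so few repetitions
#'   per permutation suffice).
#' @param seed Integer seed for the whole procedure.
#' @return List of class `perm_result`: `p`, `observed` (a `cv_result`),
#'   `perm_accuracies`, `mean_perm_accuracy`, `n_permutations`.
#' @export
permutation_test <- function(X, y, mouse, K = 3, C = 0.001,
                             n_permutations = 1000, reps_observed = 100,
                             reps_perm = 3, seed = 1L) {
  if (n_permutations < 1) stop("n_permutations must be at least 1")
  y <- droplevels(factor(y))
  with_local_seed(seed, {
    observed <- repeated_stratified_cv(X, y, mouse, K = K, reps = reps_observed, C = C)
    mice <- unique(mouse)
    mouse_label <- y[match(mice, mouse)]
    perm_acc <- vapply(seq_len(n_permutations), function(i) {
      perm <- mouse_label[sample.int(length(mice))]
      y_perm <- perm[match(mouse, mice)]
      repeated_stratified_cv(X, y_perm, mouse, K = K, reps = reps_perm,
                             C = C)$mean_accuracy
    }, numeric(1))
    structure(list(
      p = (1 + sum(perm_acc >= observed$mean_accuracy)) / (1 + n_permutations),
      observed = observed,
      perm_accuracies = perm_acc,
      mean_perm_accuracy = mean(perm_acc),
      n_permutations = n_permutations
    ), class = "perm_result")
  })
}

#' Pairwise condition classification
#'
#' Restricts the epochs to each requested pair of conditions and runs the
#' full cross-validation and permutation machinery; chance accuracy is 50%.
#'
#' @inheritParams permutation_test
#' @param pairs List of 2-vectors of condition labels; default all pairs of
#'   the levels of `y`.
#' @return Named list (one entry per pair) of [permutation_test()] results.
#' @export
pairwise_comparisons <- function(X, y, mouse, pairs = NULL, K = 3, C = 0.001,
                                 n_permutations = 1000, reps_observed = 100,
                                 reps_perm = 3, seed = 1L) {
  y <- droplevels(factor(y))
  if (is.null(pairs)) {
    pairs <- utils::combn(levels(y), 2, simplify = FALSE)
  }
  out <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    keep <- y %in% pr
    if (!all(pr %in% y)) stop("pair contains an absent condition: ",
                              paste(pr, collapse = " vs "))
    permutation_test(X[keep, , drop = FALSE], droplevels(y[keep]), mouse[keep],
                     K = K, C = C, n_permutations = n_permutations,
                     reps_observed = reps_observed, reps_perm = reps_perm,
                     seed = seed + i)
  })
  names(out) <- vapply(pairs, paste, "", collapse = "_vs_")
  out
}
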