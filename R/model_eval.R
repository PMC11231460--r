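as01 <- function(y) {
  if (is.factor(y)) as.integer(y == levels(y)[2]) else as.integer(y)
}

#' Fit a logistic-regression classifier
#'
#' Plain binomial logistic regression fitted by iteratively reweighted least
#' squares with step-halving; a tiny ridge (`1e-8` by default) keeps the
#' Newton system well conditioned on separable subsets without materially
#' penalizing the fit. Deterministic given the data.
#'
#' @param X numeric matrix (rows = subjects).
#' @param y binary labels: 0/1 or a two-level factor (second level =
#'   positive class).
#' @param ridge ridge penalty on the non-intercept coefficients.
#' @param max_iter,tol IRLS iteration cap and relative deviance tolerance.
#' @return object of class `fnirs_logistic` with `coefficients` (intercept
#'   first), `deviance`, `iterations`, `converged`.
#' @export
fit_logistic <- function(X, y, ridge = 1e-8, max_iter = 100, tol = 1e-8) {
  X <- as.matrix(X)
  y01 <- as01(y)
  if (length(unique(y01)) < 2)
    stop("both classes must be present in the training labels")
  n <- nrow(X); d <- ncol(X)
  Xd <- cbind(`(Intercept)` = 1, X)
  beta <- numeric(d + 1L)
  pen_mask <- c(0, rep(1, d))
  obj <- function(b) {
    eta <- drop(Xd %*% b)
    # 2*sum(log(1+exp(eta)) - y*eta), computed stably
    2 * sum(pmax(eta, 0) + log1p(exp(-abs(eta))) - y01 * eta) +
      ridge * sum(pen_mask * b^2)
  }
  dev <- obj(beta)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta <- drop(Xd %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    grad <- drop(crossprod(Xd, y01 - p)) - ridge * pen_mask * beta
    H <- crossprod(Xd * w, Xd)
    diag(H) <- diag(H) + ridge * pen_mask + 1e-12
    delta <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(delta)) delta <- grad / (max(diag(H)) + 1)
    step <- 1
    repeat {
      cand <- beta + step * delta
      dev_new <- obj(cand)
      if (dev_new <= dev + 1e-12 || step < 1e-10) break
      step <- step / 2
    }
    if (abs(dev - dev_new) < tol * (abs(dev_new) + 0.1) || dev_new < 1e-6) {
      # second condition: perfect separation, the fit cannot improve
      # classification further
      beta <- cand; dev <- dev_new; converged <- TRUE; break
    }
    beta <- cand; dev <- dev_new
  }
  if (!converged && it >= max_iter)
    stop(sprintf(
      "logistic fit did not converge in %d iterations (deviance %.6g)",
      max_iter, dev))
  structure(list(coefficients = stats::setNames(beta, colnames(Xd)),
                 deviance = dev, iterations = it, converged = converged),
            class = "fnirs_logistic")
}

#' @param object an `fnirs_logistic`.
#' @param newdata numeric matrix with the training columns.
#' @param ... unused.
#' @return predicted probability of the positive class per row.
#' @rdname fit_logistic
#' @export
predict.fnirs_logistic <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  plogis(drop(cbind(1, newdata) %*% object$coefficients))
}

#' Stratified k-fold assignment
#'
#' Deals the shuffled indices of each class round-robin into `k` folds, so
#' every fold holds (as nearly as possible) the same class proportions and
#' every subject is held out exactly once.
#'
#' @param y binary labels.
#' @param k number of folds.
#' @param seed shuffle seed.
#' @param stratified preserve class proportions per fold (default TRUE).
#' @return integer fold id (1..k) per subject.
#' @export
make_folds <- function(y, k, seed = 1L, stratified = TRUE) {
  n <- length(y)
  if (k < 2 || k > n) stop("`k` must be in [2, n]")
  fold <- integer(n)
  withr::with_seed(seed, {
    if (stratified) {
      offset <- 0L
      for (cl in unique(y)) {
        idx <- which(y == cl)
        idx <- idx[sample.int(length(idx))]
        # rotate the fold assignment across classes so that no fold is left
        # empty when k approaches n (e.g. leave-one-out)
        fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
        offset <- offset + length(idx)
      }
    } else {
      fold <- rep_len(seq_len(k), n)[sample.int(n)]
    }
  })
  fold
}

#' Confusion-matrix metrics
#'
#' Accuracy `(TP+TN)/(TP+FN+TN+FP)`, recall `TP/(TP+FN)`, precision
#' `TP/(TP+FP)` and `F1 = 2TP/(2TP+FP+FN)`. A metric with a zero denominator
#' is returned as `NA` and named in `flags` — degenerate folds stay visible
#' instead of silently scoring 0.
#'
#' @param tp,fp,tn,fn non-negative confusion counts.
#' @return list with `accuracy`, `precision`, `recall`, `f1`, `flags`.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("confusion counts sum to zero")
  flags <- character(0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    flags <- c(flags, "precision_undefined"); NA_real_ }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    flags <- c(flags, "recall_undefined"); NA_real_ }
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else {
    flags <- c(flags, "f1_undefined"); NA_real_ }
  list(accuracy = (tp + tn) / total, precision = precision,
       recall = recall, f1 = f1, flags = flags)
}

#' Rank-based ROC AUC
#'
#' The probability that a random positive outscores a random negative, ties
#' counted one half — the Mann-Whitney statistic scaled by `n1 * n0`, equal
#' to the trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric classifier scores.
#' @param labels binary labels (positive = second factor level or 1).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  y01 <- as01(labels)
  n1 <- sum(y01 == 1); n0 <- sum(y01 == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[y01 == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' k-fold cross-validated evaluation of a logistic classifier
#'
#' Stratified k-fold CV restricted to the masked feature columns: the model
#' is fitted on k-1 folds and scored on the held-out fold; per-fold confusion
#' counts and metrics are aggregated by averaging the fold metrics. AUC is
#' reported both pooled over all held-out probabilities (headline, stable for
#' small folds) and as the per-fold average.
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @param mask logical or integer column selection (default all).
#' @param k number of folds (5 or 10 typically).
#' @param seed fold-shuffle seed.
#' @param stratified stratify folds by class (default TRUE).
#' @return object of class `fnirs_cv_result`: `folds` data.frame (counts +
#'   metrics per fold), `aggregate` list (accuracy, precision, recall, f1,
#'   auc_pooled, auc_fold_mean), `fold_id`, `k`.
#' @export
kfold_evaluate <- function(X, y, mask = NULL, k = 5, seed = 1L,
                           stratified = TRUE) {
  X <- as.matrix(X)
  if (is.null(mask)) mask <- rep(TRUE, ncol(X))
  if (is.logical(mask)) mask <- which(mask)
  if (!length(mask)) stop("`mask` selects no features")
  y01 <- as01(y)
  fold <- make_folds(y01, k, seed = seed, stratified = stratified)
  Xs <- X[, mask, drop = FALSE]
  rows <- vector("list", k)
  pooled_scores <- numeric(length(y01))
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    model <- fit_logistic(Xs[tr, , drop = FALSE], y01[tr])
    p <- predict(model, Xs[te, , drop = FALSE])
    pooled_scores[te] <- p
    pred <- as.integer(p >= 0.5)
    tp <- sum(pred == 1 & y01[te] == 1)
    fp <- sum(pred == 1 & y01[te] == 0)
    tn <- sum(pred == 0 & y01[te] == 0)
    fn <- sum(pred == 0 & y01[te] == 1)
    m <- confusion_metrics(tp, fp, tn, fn)
    auc_f <- if (length(unique(y01[te])) == 2) roc_auc(p, y01[te]) else
      NA_real_
    rows[[f]] <- data.frame(fold = f, n = sum(te), tp = tp, fp = fp,
                            tn = tn, fn = fn, accuracy = m$accuracy,
                            precision = m$precision, recall = m$recall,
                            f1 = m$f1, auc = auc_f)
  }
  folds <- do.call(rbind, rows)
  agg <- list(
    accuracy = mean(folds$accuracy),
    precision = mean(folds$precision, na.rm = TRUE),
    recall = mean(folds$recall, na.rm = TRUE),
    f1 = mean(folds$f1, na.rm = TRUE),
    auc_pooled = roc_auc(pooled_scores, y01),
    auc_fold_mean = if (all(is.na(folds$auc))) NA_real_ else
      mean(folds$auc, na.rm = TRUE)
  )
  structure(list(folds = folds, aggregate = agg, fold_id = fold, k = k,
                 n_features = length(mask)),
            class = "fnirs_cv_result")
}

#' @export
print.fnirs_cv_result <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf(
    "%d-fold CV (%d features): accuracy %.3f | precision %.3f | recall %.3f | F1 %.3f | AUC %.3f\n",
    x$k, x$n_features, a$accuracy, a$precision, a$recall, a$f1,
    a$auc_pooled))
  invisible(x)
}
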