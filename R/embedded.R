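#' Elastic-net logistic feature subset
#'
#' Fits an elastic-net-penalized logistic regression (glmnet) and keeps the
#' features with nonzero coefficients. When `penalty_strength` is `NULL` the
#' penalty is chosen by internal k-fold cross-validation on a deterministic
#' fold assignment.
#'
#' @param X standardized feature matrix.
#' @param y binary labels.
#' @param penalty_strength glmnet `lambda`; `NULL` for internal CV,
#'   `Inf` shrinks everything away.
#' @param l1_ratio elastic-net mixing `alpha` (1 = lasso, 0 = ridge;
#'   default 0.5).
#' @param seed fold seed for the internal CV.
#' @param nfolds internal CV folds (default 5).
#' @param rule penalty choice when CV-tuned: `"lambda.1se"` (default; the
#'   sparser model within one standard error of the CV optimum, the stabler
#'   choice at small n) or `"lambda.min"`.
#' @return an `fnirs_subset`.
#' @export
elastic_net_subset <- function(X, y, penalty_strength = NULL,
                               l1_ratio = 0.5, seed = 1L, nfolds = 5,
                               rule = c("lambda.1se", "lambda.min")) {
  X <- as.matrix(X)
  y01 <- as01(y)
  rule <- match.arg(rule)
  if (is.null(penalty_strength)) {
    foldid <- make_folds(y01, nfolds, seed = seed)
    # selection with more active coefficients than samples is
    # unidentifiable, so the path is capped at n active features
    # glmnet warns when the path stops at the pmax cap; that truncation is
    # exactly what the cap is for
    cvfit <- suppressWarnings(
      glmnet::cv.glmnet(X, y01, family = "binomial",
                        alpha = l1_ratio, foldid = foldid,
                        standardize = FALSE,
                        pmax = min(ncol(X), nrow(X))))
    lam <- cvfit[[rule]]
    fit <- cvfit$glmnet.fit
    co <- as.numeric(stats::coef(fit, s = lam))[-1]
    if (!any(abs(co) > 1e-8)) {
      # chosen penalty empties the model: back off to the largest penalty on
      # the path that keeps at least one coefficient
      nz <- which(fit$df > 0)
      if (length(nz))
        co <- as.numeric(stats::coef(fit, s = fit$lambda[nz[1]]))[-1]
    }
  } else if (is.infinite(penalty_strength)) {
    co <- numeric(ncol(X))
  } else {
    fit <- glmnet::glmnet(X, y01, family = "binomial", alpha = l1_ratio,
                          lambda = penalty_strength, standardize = FALSE)
    if (!fit$jerr == 0 && is.null(fit$beta))
      stop("elastic-net optimization failed (glmnet jerr = ", fit$jerr, ")")
    co <- as.numeric(stats::coef(fit))[-1]
  }
  new_subset(abs(co) > 1e-8, sprintf("elastic_net(alpha=%g)", l1_ratio))
}

# L1-penalized squared-hinge linear SVM solved by FISTA (proximal gradient
# with Nesterov acceleration); the intercept is unpenalized.
fista_l1svm <- function(X, yy, lambda, max_iter = 300, tol = 1e-7) {
  n <- nrow(X); d <- ncol(X)
  Xd <- cbind(X, 1)
  L <- 2 * (norm(Xd, "F")^2) / n + 1e-8   # Lipschitz bound for sq. hinge
  w <- numeric(d + 1L)
  v <- w
  t_k <- 1
  obj <- function(w) {
    m <- pmax(0, 1 - yy * drop(Xd %*% w))
    mean(m^2) + lambda * sum(abs(w[seq_len(d)]))
  }
  f_old <- obj(w)
  for (it in seq_len(max_iter)) {
    m <- pmax(0, 1 - yy * drop(Xd %*% v))
    grad <- drop(crossprod(Xd, -2 * yy * m)) / n
    z <- v - grad / L
    # soft-threshold feature weights only
    z[seq_len(d)] <- sign(z[seq_len(d)]) *
      pmax(0, abs(z[seq_len(d)]) - lambda / L)
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    v <- z + ((t_k - 1) / t_new) * (z - w)
    w <- z
    t_k <- t_new
    f_new <- obj(w)
    if (abs(f_old - f_new) < tol * (abs(f_old) + 1e-10)) break
    f_old <- f_new
  }
  w
}

#' L1-norm linear SVM feature subset
#'
#' Linear support-vector classifier with squared hinge loss and an L1
#' penalty, solved by accelerated proximal gradient descent; the L1 penalty
#' drives irrelevant coefficients exactly to zero and the surviving features
#' form the subset. When `penalty_strength` is `NULL` it is chosen from a
#' log-spaced grid by internal cross-validated accuracy (ties toward the
#' stronger penalty, i.e. the sparser model).
#'
#' @param X standardized feature matrix.
#' @param y binary labels.
#' @param penalty_strength L1 weight `lambda`; `NULL` for internal CV,
#'   `Inf` empties the subset.
#' @param seed fold seed for the internal CV.
#' @param nfolds internal CV folds (default 5).
#' @param grid_length penalty grid resolution (default 6).
#' @return an `fnirs_subset`.
#' @export
l1_svm_subset <- function(X, y, penalty_strength = NULL, seed = 1L,
                          nfolds = 5, grid_length = 6) {
  X <- as.matrix(X)
  y01 <- as01(y)
  yy <- ifelse(y01 == 1, 1, -1)
  d <- ncol(X)
  if (!is.null(penalty_strength) && is.infinite(penalty_strength))
    return(new_subset(rep(FALSE, d), "l1_svm(lambda=Inf)"))
  if (is.null(penalty_strength)) {
    lam_max <- max(abs(drop(crossprod(X, yy))) * 2 / nrow(X))
    # start just under lambda_max (at which the fit is exactly empty) so the
    # head of the grid is the sparsest attainable non-empty model
    grid <- lam_max * 10^seq(-0.05, -3, length.out = grid_length)
    foldid <- make_folds(y01, nfolds, seed = seed)
    acc <- vapply(grid, function(lam) {
      correct <- 0L
      for (f in seq_len(nfolds)) {
        tr <- foldid != f
        w <- fista_l1svm(X[tr, , drop = FALSE], yy[tr], lam)
        pred <- sign(drop(cbind(X[!tr, , drop = FALSE], 1) %*% w))
        pred[pred == 0] <- 1
        correct <- correct + sum(pred == yy[!tr])
      }
      correct / length(yy)
    }, 0)
    # ties toward the sparser (larger-penalty) model: grid is descending.
    # Among (near-)equally accurate penalties prefer the sparsest non-empty
    # model, and never accept more active coefficients than samples (an
    # unidentifiable selection); fall back to the best-accuracy non-empty
    # model if no candidate satisfies the cap.
    n_cap <- min(d, nrow(X))
    chosen <- NULL; fallback <- NULL
    for (i in order(-acc, seq_along(grid))) {
      w_i <- fista_l1svm(X, yy, grid[i])
      nnz <- sum(abs(w_i[seq_len(d)]) > 1e-8)
      if (nnz > 0 && is.null(fallback)) {
        fallback <- list(w = w_i, lam = grid[i])
      }
      if (nnz > 0 && nnz <= n_cap) {
        chosen <- list(w = w_i, lam = grid[i])
        break
      }
    }
    if (is.null(chosen) && !is.null(fallback)) {
      # on label-free data the path can jump from empty straight to dense;
      # keep only the largest-magnitude coefficients within the cap
      w_f <- fallback$w
      keep <- order(-abs(w_f[seq_len(d)]))[seq_len(n_cap)]
      w_f[setdiff(seq_len(d), keep)] <- 0
      chosen <- list(w = w_f, lam = fallback$lam)
    }
    if (is.null(chosen)) chosen <- list(w = fista_l1svm(X, yy, grid[1]),
                                        lam = grid[1])
    w <- chosen$w
    penalty_strength <- chosen$lam
  } else {
    w <- fista_l1svm(X, yy, penalty_strength)
  }
  new_subset(abs(w[seq_len(d)]) > 1e-8,
             sprintf("l1_svm(lambda=%.4g)", penalty_strength))
}
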