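new_ranking <- function(method, scores, removed = NULL) {
  d <- length(scores)
  # descending score; ties broken by ascending feature index (deterministic)
  ord <- order(-scores, seq_len(d))
  rank <- integer(d)
  rank[ord] <- seq_len(d)
  structure(list(method = method, scores = scores, rank = rank,
                 order = ord,
                 removed = if (is.null(removed)) rep(FALSE, d) else removed),
            class = "fnirs_ranking")
}

#' Top-p% feature set of a ranking
#'
#' The indices of the `ceiling(p * d / 100)` best-scoring features (ceiling
#' guarantees a non-empty set at p = 1); nested in `p` by construction.
#'
#' @param ranking an `fnirs_ranking`.
#' @param p percentage in (0, 100].
#' @return integer vector of feature indices.
#' @export
top_p_set <- function(ranking, p) {
  stopifnot(inherits(ranking, "fnirs_ranking"), p > 0, p <= 100)
  d <- length(ranking$scores)
  ranking$order[seq_len(ceiling(p * d / 100))]
}

#' Mean-absolute-difference (MAD) filter scores
#'
#' Scores each feature by the mean absolute deviation of its values from
#' their mean; higher dispersion is taken as more informative. Features with
#' zero mean absolute difference are flagged as removed.
#'
#' @param X numeric matrix (subjects x features).
#' @return an `fnirs_ranking` with `removed` marking zero-MAD features.
#' @export
mad_scores <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 rows")
  mu <- colMeans(X)
  scores <- colMeans(abs(sweep(X, 2, mu)))
  new_ranking("MAD", scores, removed = scores == 0)
}

#' Mutual-information-gain (MIG) filter scores
#'
#' Plug-in mutual information (bits) between each feature and the binary
#' label, after equal-frequency discretization of the feature into
#' `min(10, floor(n/4))` bins. Binning uses average ranks, so the estimate is
#' invariant to monotone transforms and to row order.
#'
#' @param X numeric matrix.
#' @param y binary labels.
#' @param n_bins override for the bin count.
#' @return an `fnirs_ranking`.
#' @export
mig_scores <- function(X, y, n_bins = NULL) {
  X <- as.matrix(X)
  y01 <- as01(y)
  if (length(unique(y01)) < 2) stop("both classes required for MIG")
  if (min(table(y01)) < 2) stop("need at least 2 rows per class")
  n <- nrow(X)
  if (is.null(n_bins)) n_bins <- min(10L, n %/% 4L)
  n_bins <- max(2L, n_bins)
  mi_one <- function(x) {
    b <- ceiling(rank(x, ties.method = "average") * n_bins / n)
    tab <- table(factor(b, levels = seq_len(n_bins)), y01)
    pj <- tab / n
    pr <- rowSums(pj); pc <- colSums(pj)
    nz <- pj > 0
    sum(pj[nz] * log2(pj[nz] / (pr[row(pj)][nz] * pc[col(pj)][nz])))
  }
  new_ranking("MIG", apply(X, 2, mi_one))
}

#' Fisher scores
#'
#' Ratio of the between-class variance of the class means (class-size
#' weighted) to the pooled within-class variance, per feature. `0/0` is
#' defined as 0; a positive numerator over zero within-class variance gives
#' `Inf`, which sorts to the top rank.
#'
#' @param X numeric matrix.
#' @param y binary labels.
#' @return an `fnirs_ranking`.
#' @export
fisher_scores <- function(X, y) {
  X <- as.matrix(X)
  y01 <- as01(y)
  cls <- sort(unique(y01))
  if (length(cls) < 2) stop("both classes required for Fisher score")
  n <- nrow(X)
  mu <- colMeans(X)
  between <- 0; within <- 0
  for (c in cls) {
    Xc <- X[y01 == c, , drop = FALSE]
    w <- nrow(Xc) / n
    muc <- colMeans(Xc)
    between <- between + w * (muc - mu)^2
    within <- within + w * colMeans(sweep(Xc, 2, muc)^2)
  }
  scores <- ifelse(within > 0, between / within,
                   ifelse(between > 0, Inf, 0))
  new_ranking("Fisher", scores)
}

#' Two-of-three top-percentile vote
#'
#' A feature enters the voted subset when it appears in the top-p% set of at
#' least two of the three filter rankings.
#'
#' @param filters list of exactly 3 `fnirs_ranking`s over the same features.
#' @param p percentage in (0, 100].
#' @return an `fnirs_subset` (logical mask + provenance).
#' @export
vote_subset <- function(filters, p) {
  stopifnot(length(filters) == 3)
  d <- length(filters[[1]]$scores)
  for (f in filters) {
    stopifnot(inherits(f, "fnirs_ranking"))
    if (length(f$scores) != d) stop("rankings cover different feature sets")
  }
  votes <- integer(d)
  for (f in filters) votes[top_p_set(f, p)] <- votes[top_p_set(f, p)] + 1L
  new_subset(votes >= 2L, sprintf("vote(p=%g%%, 2-of-3)", p))
}

#' Accuracy sweep over vote percentiles 1..10
#'
#' Evaluates the two-of-three voted subset for p = 1..10 % with the supplied
#' evaluator (cross-validated logistic accuracy by default use) and returns
#' the best subset. Ties are broken toward the smaller subset, then the
#' smaller p. Empty subsets are recorded with `NA` accuracy and skipped.
#'
#' @param filters list of 3 `fnirs_ranking`s.
#' @param evaluator `function(mask) -> accuracy in [0, 1]`.
#' @param p_grid percentages to sweep (default 1:10).
#' @return list with `best` (an `fnirs_subset`), `best_p`, and `table`
#'   (data.frame p / size / accuracy).
#' @export
vote_sweep <- function(filters, evaluator, p_grid = 1:10) {
  rows <- vector("list", length(p_grid))
  subsets <- vector("list", length(p_grid))
  for (i in seq_along(p_grid)) {
    s <- vote_subset(filters, p_grid[i])
    subsets[[i]] <- s
    acc <- if (subset_size(s) > 0) evaluator(s$mask) else NA_real_
    rows[[i]] <- data.frame(p = p_grid[i], size = subset_size(s),
                            accuracy = acc)
  }
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$accuracy))
  if (!length(ok)) stop("all voted subsets were empty")
  best_i <- ok[order(-tab$accuracy[ok], tab$size[ok], tab$p[ok])][1]
  best <- subsets[[best_i]]
  best$provenance <- sprintf("vote_sweep(best p=%g%%)", tab$p[best_i])
  list(best = best, best_p = tab$p[best_i], table = tab)
}

#' Combine selector subsets by union
#'
#' Merges the voted-filter subset with the elastic-net and L1-SVM subsets by
#' set union: a feature kept by any selector survives, matching the
#' ensemble's goal of combining the strengths of heterogeneous methods.
#'
#' @param ... two or more `fnirs_subset`s over the same feature universe.
#' @return an `fnirs_subset`.
#' @export
ensemble_combine <- function(...) {
  subs <- list(...)
  stopifnot(length(subs) >= 2)
  d <- length(subs[[1]]$mask)
  mask <- rep(FALSE, d)
  for (s in subs) {
    stopifnot(inherits(s, "fnirs_subset"))
    if (length(s$mask) != d) stop("subsets cover different feature sets")
    mask <- mask | s$mask
  }
  new_subset(mask, paste0("union(",
                          paste(vapply(subs, `[[`, "", "provenance"),
                                collapse = " + "), ")"))
}

# ---- feature subset container ----

new_subset <- function(mask, provenance) {
  structure(list(mask = as.logical(mask), provenance = provenance),
            class = "fnirs_subset")
}

#' Size of a feature subset
#' @param s an `fnirs_subset`.
#' @return number of selected features.
#' @export
subset_size <- function(s) sum(s$mask)

#' @export
print.fnirs_ranking <- function(x, ...) {
  cat(sprintf("%s ranking over %d features (%d flagged removed)\n",
              x$method, length(x$scores), sum(x$removed)))
  invisible(x)
}

#' @export
print.fnirs_subset <- function(x, ...) {
  cat(sprintf("feature subset: %d of %d features [%s]\n",
              subset_size(x), length(x$mask), x$provenance))
  invisible(x)
}
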