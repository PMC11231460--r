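#' Standardize a feature matrix
#'
#' Centers and scales every column using mean/sd computed on `fit_rows` only,
#' so the identical transform can be applied to held-out rows without
#' information leaking from them (see [apply_standardization()]). Columns with
#' zero variance among the fit rows are centered, passed through with sd
#' treated as 1, and flagged rather than crashing.
#'
#' @param fm an `fnirs_features`.
#' @param fit_rows integer/logical row subset the statistics are computed on
#'   (default all rows, the protocol-faithful whole-cohort fit).
#' @return list with `features` (standardized `fnirs_features`), `center`,
#'   `scale` (per-feature statistics) and `zero_variance` (logical flags).
#' @export
standardize_features <- function(fm, fit_rows = NULL) {
  stopifnot(inherits(fm, "fnirs_features"))
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(fm$X))
  Xf <- fm$X[fit_rows, , drop = FALSE]
  if (!nrow(Xf)) stop("`fit_rows` must be non-empty")
  center <- colMeans(Xf)
  n <- nrow(Xf)
  scale <- sqrt(colSums((Xf - rep(center, each = n))^2) / max(1, n - 1))
  zero_variance <- !is.na(scale) & scale == 0
  scale[zero_variance | is.na(scale)] <- 1
  out <- fm
  out$X <- sweep(sweep(fm$X, 2, center), 2, scale, "/")
  list(features = out, center = center, scale = scale,
       zero_variance = zero_variance)
}

#' Apply previously fitted standardization statistics
#'
#' @param fm an `fnirs_features` (e.g. held-out rows).
#' @param stats the list returned by [standardize_features()].
#' @return standardized `fnirs_features`.
#' @export
apply_standardization <- function(fm, stats) {
  stopifnot(inherits(fm, "fnirs_features"))
  out <- fm
  out$X <- sweep(sweep(fm$X, 2, stats$center), 2, stats$scale, "/")
  out
}

#' Invert a standardization
#'
#' @param X standardized matrix.
#' @param stats the list returned by [standardize_features()].
#' @return matrix on the original scale.
#' @export
unstandardize <- function(X, stats) {
  sweep(sweep(X, 2, stats$scale, "*"), 2, stats$center, "+")
}
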