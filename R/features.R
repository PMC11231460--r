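feature_names_12 <- function() {
  c("t_maxabs", "t_mean", "t_var", "t_skew", "t_zcint", "t_zcpeak",
    "s_mean", "s_var", "s_skew", "s_kurt", "s_energy", "s_domfreq")
}

pop_moments <- function(x) {
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  m3 <- mean(d^3)
  m4 <- mean(d^4)
  list(mean = m, var = m2,
       skew = if (m2 > 0) m3 / m2^1.5 else 0,
       kurt = if (m2 > 0) m4 / m2^2 else 0)
}

# Zero-crossing positions (fractional sample index, 1-based) of a
# mean-removed trace. A sample exactly at zero counts as one crossing; runs
# of zeros collapse to a single crossing at their first sample.
zero_crossings <- function(z) {
  n <- length(z)
  is0 <- z == 0
  pos <- numeric(0)
  if (any(is0)) {
    r <- rle(is0)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    pos <- starts[r$values]
  }
  s <- sign(z)
  i <- which(s[-n] * s[-1] < 0)
  if (length(i)) {
    # linear interpolation of the crossing point between i and i+1
    frac <- z[i] / (z[i] - z[i + 1])
    pos <- c(pos, i + frac)
  }
  sort(pos)
}

local_extrema <- function(z) {
  dz <- diff(z)
  s <- sign(dz)
  s[s == 0] <- 1
  which(diff(s) != 0) + 1L
}

#' Temporal features of one signal
#'
#' The six time-domain descriptors computed per channel and band: (1) maximum
#' absolute value, (2) mean, (3) population variance, (4) population skewness,
#' (5) mean interval between consecutive zero crossings (s), (6) mean
#' interval from a zero crossing to the next local extremum (s). Zero
#' crossings are taken on the mean-removed trace (resting concentration
#' traces have arbitrary offsets). With fewer than two crossings, features
#' 5-6 fall back to the record duration as a sentinel and are flagged.
#'
#' @param x numeric signal (uM).
#' @param fs sampling frequency in Hz.
#' @return named numeric vector of length 6 with attribute `flags`
#'   (character vector of degenerate-case markers, possibly empty).
#' @export
temporal_features <- function(x, fs) {
  if (length(x) < 2) stop("signal must have at least 2 samples")
  if (fs <= 0) stop("fs must be positive")
  flags <- character(0)
  mom <- pop_moments(x)
  if (mom$var == 0) flags <- c(flags, "constant_signal")
  z <- x - mom$mean
  cross <- zero_crossings(z)
  duration <- length(x) / fs
  if (length(cross) >= 2) {
    zcint <- mean(diff(cross)) / fs
  } else {
    zcint <- duration
    flags <- c(flags, "no_zero_crossings")
  }
  ext <- local_extrema(z)
  if (length(cross) >= 1 && length(ext) >= 1) {
    nxt <- findInterval(cross, ext) + 1L   # first extremum after each crossing
    valid <- nxt <= length(ext)
    zcpeak <- if (any(valid))
      mean((ext[nxt[valid]] - cross[valid]) / fs) else duration
  } else {
    zcpeak <- duration
    flags <- c(flags, "no_peaks")
  }
  out <- c(t_maxabs = max(abs(x)), t_mean = mom$mean, t_var = mom$var,
           t_skew = mom$skew, t_zcint = zcint, t_zcpeak = zcpeak)
  attr(out, "flags") <- flags
  out
}

#' One-sided magnitude spectrum
#'
#' Magnitude of the discrete Fourier transform of the mean-removed, untapered
#' signal; one-sided, DC excluded, scaled by `sqrt(2/N)` (Nyquist bin by
#' `sqrt(1/N)`) so that `sum(magnitude^2)` equals the time-domain energy of
#' the mean-removed signal (Parseval).
#'
#' @param x numeric signal.
#' @param fs sampling frequency in Hz.
#' @return object of class `fnirs_spectrum`: list with `freq` (Hz),
#'   `magnitude`, `resolution` (Hz).
#' @export
power_spectrum <- function(x, fs) {
  n <- length(x)
  if (n < 2) stop("signal must have at least 2 samples")
  z <- x - mean(x)
  F <- stats::fft(z)
  k_max <- if (n %% 2 == 0) n %/% 2 else (n - 1) %/% 2
  k <- seq_len(k_max)
  mag <- sqrt(2 / n) * Mod(F[k + 1])
  if (n %% 2 == 0) mag[k_max] <- Mod(F[k_max + 1]) / sqrt(n)
  structure(list(freq = k * fs / n, magnitude = mag, resolution = fs / n),
            class = "fnirs_spectrum")
}

#' Spectral features of one spectrum
#'
#' The six frequency-domain descriptors: mean, population variance,
#' population skewness, (non-excess) population kurtosis of the magnitude
#' values, total energy `sum(magnitude^2)`, and the dominant frequency (the
#' bin of maximum magnitude; earliest bin on exact ties). An all-zero
#' spectrum returns zero moments and a flagged `NA` dominant frequency.
#'
#' @param sp an `fnirs_spectrum` from [power_spectrum()].
#' @return named numeric vector of length 6 with attribute `flags`.
#' @export
spectral_features <- function(sp) {
  stopifnot(inherits(sp, "fnirs_spectrum"))
  m <- sp$magnitude
  if (!length(m)) stop("empty spectrum")
  flags <- character(0)
  mom <- pop_moments(m)
  energy <- sum(m^2)
  if (all(m == 0)) {
    domfreq <- NA_real_
    flags <- c(flags, "zero_spectrum")
  } else {
    domfreq <- sp$freq[which.max(m)]
  }
  out <- c(s_mean = mom$mean, s_var = mom$var, s_skew = mom$skew,
           s_kurt = mom$kurt, s_energy = energy, s_domfreq = domfreq)
  attr(out, "flags") <- flags
  out
}

# Vectorized per-band feature computation; kept numerically identical to the
# per-signal temporal_features()/spectral_features() path (asserted in the
# test suite). Spectra of all channels of a band are batched through mvfft.
record_features <- function(record) {
  nc <- dim(record$data)[2]
  n <- dim(record$data)[3]
  fs <- record$fs
  bands <- record$bands
  nb <- length(bands)
  duration <- n / fs
  vals <- array(NA_real_, dim = c(12L, nb, nc))
  k_max <- if (n %% 2 == 0) n %/% 2 else (n - 1) %/% 2
  freq <- seq_len(k_max) * fs / n
  for (b in seq_len(nb)) {
    mat <- record$data[b, , , drop = FALSE]      # nc x n
    dim(mat) <- c(nc, n)
    mu <- rowMeans(mat)
    D <- mat - mu
    m2 <- rowMeans(D^2)
    m3 <- rowMeans(D^3)
    skew <- ifelse(m2 > 0, m3 / m2^1.5, 0)
    FZ <- stats::mvfft(t(D))                     # n x nc
    mag <- sqrt(2 / n) * Mod(FZ[1L + seq_len(k_max), , drop = FALSE])
    if (n %% 2 == 0) mag[k_max, ] <- Mod(FZ[k_max + 1L, ]) / sqrt(n)
    smu <- colMeans(mag)
    SD <- mag - rep(smu, each = k_max)
    sm2 <- colMeans(SD^2)
    sm3 <- colMeans(SD^3)
    sm4 <- colMeans(SD^4)
    for (ch in seq_len(nc)) {
      if (!isTRUE(record$channel_meta$retained[ch])) next
      z <- D[ch, ]
      cross <- zero_crossings(z)
      zcint <- if (length(cross) >= 2) mean(diff(cross)) / fs else duration
      ext <- local_extrema(z)
      if (length(cross) >= 1 && length(ext) >= 1) {
        nxt <- findInterval(cross, ext) + 1L
        valid <- nxt <= length(ext)
        zcpeak <- if (any(valid))
          mean((ext[nxt[valid]] - cross[valid]) / fs) else duration
      } else zcpeak <- duration
      vals[, b, ch] <- c(
        max(abs(mat[ch, ])), mu[ch], m2[ch], skew[ch], zcint, zcpeak,
        smu[ch], sm2[ch],
        if (sm2[ch] > 0) sm3[ch] / sm2[ch]^1.5 else 0,
        if (sm2[ch] > 0) sm4[ch] / sm2[ch]^2 else 0,
        sum(mag[, ch]^2),
        if (all(mag[, ch] == 0)) NA_real_ else freq[which.max(mag[, ch])])
    }
  }
  # layout: channel-major, band next, the 12 features fastest
  as.numeric(vals)
}

#' Extract the full feature matrix of a cohort
#'
#' Computes the 12 temporal + spectral descriptors for every (channel, band)
#' pair of every subject: `n_channels x 3 x 12` named columns (792 for the
#' default 22-channel layout), ordered channel-major, band (HbO, HbR, HbT)
#' next, temporal features before spectral. Channels flagged as pruned are
#' filled with the cohort column median and recorded in the provenance table,
#' so the column layout is identical for every subject.
#'
#' @param cohort an `fnirs_cohort`.
#' @return object of class `fnirs_features`: list with `X` (subjects x
#'   features matrix), `y` (factor labels), `subjects`, `feature_info`
#'   (name/channel/band/domain/feature table), `filled` (logical matrix of
#'   median-imputed cells).
#' @export
extract_feature_matrix <- function(cohort) {
  stopifnot(inherits(cohort, "fnirs_cohort"))
  if (!length(cohort$records)) stop("empty cohort")
  nc <- dim(cohort$records[[1]]$data)[2]
  for (rec in cohort$records)
    if (dim(rec$data)[2] != nc)
      stop("inconsistent channel layouts across subjects")
  bands <- band_names()
  info <- expand.grid(feature = feature_names_12(), band = bands,
                      channel = seq_len(nc), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  info <- info[, c("channel", "band", "feature")]
  info$domain <- ifelse(startsWith(info$feature, "t_"), "temporal",
                        "spectral")
  info$name <- sprintf("ch%02d_%s_%s", info$channel, info$band, info$feature)
  X <- t(vapply(cohort$records, record_features,
                numeric(nc * length(bands) * 12L)))
  colnames(X) <- info$name
  rownames(X) <- vapply(cohort$records, `[[`, "", "subject_id")
  filled <- is.na(X)
  if (any(filled)) {
    med <- apply(X, 2, stats::median, na.rm = TRUE)
    for (j in which(colSums(filled) > 0))
      X[filled[, j], j] <- med[j]
  }
  structure(list(X = X, y = cohort$labels,
                 subjects = rownames(X),
                 feature_info = info[, c("name", "channel", "band",
                                         "domain", "feature")],
                 filled = filled),
            class = "fnirs_features")
}

#' Feature dictionary
#'
#' @return data.frame mapping each of the 12 per-(channel, band) feature ids
#'   to its definition, units and convention.
#' @export
feature_dictionary <- function() {
  data.frame(
    feature = feature_names_12(),
    domain = rep(c("temporal", "spectral"), each = 6),
    definition = c(
      "maximum absolute value of the trace",
      "mean of the trace",
      "population variance (divide by N)",
      "population skewness m3/m2^1.5; 0 for constant trace",
      "mean interval between consecutive zero crossings of the mean-removed trace",
      "mean interval from a zero crossing to the next local extremum",
      "mean of the one-sided DFT magnitude (DC excluded)",
      "population variance of the magnitude values",
      "population skewness of the magnitude values",
      "population kurtosis (non-excess) of the magnitude values",
      "sum of squared magnitudes (= time-domain energy, Parseval)",
      "frequency of the maximum-magnitude bin"),
    units = c("uM", "uM", "uM^2", "", "s", "s",
              "uM", "uM^2", "", "", "uM^2", "Hz"),
    stringsAsFactors = FALSE
  )
}

#' Write / read a feature matrix as CSV (+ JSON feature dictionary)
#'
#' @param fm an `fnirs_features`.
#' @param path CSV file path; the dictionary is written next to it as
#'   `<path>.dict.json`.
#' @return `path` invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "fnirs_features"))
  dt <- data.table::data.table(subject_id = fm$subjects,
                               label = as.character(fm$y))
  dt <- cbind(dt, data.table::as.data.table(fm$X))
  data.table::fwrite(dt, path)
  jsonlite::write_json(feature_dictionary(), paste0(path, ".dict.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  dt <- data.table::fread(path)
  stopifnot(all(c("subject_id", "label") %in% names(dt)))
  X <- as.matrix(dt[, setdiff(names(dt), c("subject_id", "label")),
                    with = FALSE])
  rownames(X) <- dt$subject_id
  nm <- colnames(X)
  parts <- regmatches(nm, regexec("^ch(\\d+)_(Hb[ORT])_([ts]_.+)$", nm))
  info <- data.frame(
    name = nm,
    channel = as.integer(vapply(parts, `[`, "", 2)),
    band = vapply(parts, `[`, "", 3),
    feature = vapply(parts, `[`, "", 4),
    stringsAsFactors = FALSE)
  info$domain <- ifelse(startsWith(info$feature, "t_"), "temporal",
                        "spectral")
  structure(list(X = X,
                 y = factor(dt$label, levels = c("control", "PD")),
                 subjects = dt$subject_id,
                 feature_info = info[, c("name", "channel", "band",
                                         "domain", "feature")],
                 filled = matrix(FALSE, nrow(X), ncol(X))),
            class = "fnirs_features")
}

#' @export
print.fnirs_features <- function(x, ...) {
  cat(sprintf("fNIRS feature matrix: %d subjects x %d features (%d imputed cells)\n",
              nrow(x$X), ncol(x$X), sum(x$filled)))
  invisible(x)
}
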