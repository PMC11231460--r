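#' Optical conversion parameters for the modified Beer-Lambert law
#'
#' Extinction coefficients, differential pathlength factors (DPF) and the
#' source-detector separation used to convert dual-wavelength optical-density
#' changes into hemoglobin concentration changes. Defaults are standard
#' order-of-magnitude values for the 757/843 nm LED pair: HbR absorbs more
#' strongly at the shorter wavelength, HbO at the longer one, which keeps the
#' 2x2 system well conditioned.
#'
#' @param wavelengths_nm the two wavelengths (informational).
#' @param extinction 2x2 matrix, rows = wavelengths, columns = (HbO, HbR),
#'   units 1/(uM cm), so that solved concentrations come out in uM directly.
#' @param dpf differential pathlength factor per wavelength (dimensionless).
#' @param distance_cm source-detector separation in cm.
#' @return an object of class `od_params`.
#' @export
od_params <- function(wavelengths_nm = c(757, 843),
                      extinction = matrix(c(1.35e-3, 3.75e-3,
                                            2.20e-3, 1.70e-3),
                                          nrow = 2, byrow = TRUE,
                                          dimnames = list(NULL,
                                                          c("HbO", "HbR"))),
                      dpf = c(6, 6),
                      distance_cm = 3) {
  stopifnot(all(dim(extinction) == c(2, 2)), length(dpf) == 2,
            distance_cm > 0)
  if (abs(det(extinction)) < 1e-12 || !is.finite(kappa(extinction)))
    stop("extinction matrix is singular or ill-conditioned")
  structure(list(wavelengths_nm = wavelengths_nm, extinction = extinction,
                 dpf = dpf, distance_cm = distance_cm),
            class = "od_params")
}

#' Convert optical-density changes to hemoglobin concentration changes
#'
#' Solves the modified Beer-Lambert 2x2 system per sample:
#' `dOD_lambda = (eps_lambda,HbO * dHbO + eps_lambda,HbR * dHbR) * d * DPF_lambda`
#' with concentrations in the units implied by the extinction coefficients
#' (uM for the defaults).
#'
#' @param od 2 x N matrix of optical-density changes, rows in the order of
#'   `params$wavelengths_nm`.
#' @param params an [od_params()].
#' @return list with numeric vectors `HbO` and `HbR` (uM).
#' @seealso [hemoglobin_to_od()] for the forward model.
#' @export
beer_lambert <- function(od, params = od_params()) {
  stopifnot(inherits(params, "od_params"))
  od <- as.matrix(od)
  if (nrow(od) != 2) stop("`od` must have two wavelength rows")
  A <- params$extinction * (params$distance_cm * params$dpf)
  if (abs(det(A)) < 1e-16) stop("extinction matrix is singular")
  conc <- solve(A, od)   # 2 x N
  list(HbO = conc[1, ], HbR = conc[2, ])
}

#' Forward modified Beer-Lambert model
#'
#' Maps hemoglobin concentration changes (uM) to dual-wavelength
#' optical-density changes; exact inverse of [beer_lambert()].
#'
#' @param hbo,hbr concentration change vectors in uM, equal length.
#' @param params an [od_params()].
#' @return 2 x N matrix of OD changes.
#' @export
hemoglobin_to_od <- function(hbo, hbr, params = od_params()) {
  if (length(hbo) != length(hbr)) stop("HbO/HbR length mismatch")
  A <- params$extinction * (params$distance_cm * params$dpf)
  A %*% rbind(hbo, hbr)
}

#' Total hemoglobin
#'
#' @param hbo,hbr equal-length concentration change vectors.
#' @return their samplewise sum.
#' @export
total_hemoglobin <- function(hbo, hbr) {
  if (length(hbo) != length(hbr)) stop("HbO/HbR length mismatch")
  hbo + hbr
}

cardiac_bandpass <- function(x, fs, band = c(0.7, 1.5)) {
  ny <- fs / 2
  bf <- signal::butter(4, pmin(band / ny, 0.99), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Prune channels with poor signal quality
#'
#' Quality score per channel: the absolute correlation between the
#' cardiac-band (0.7-1.5 Hz) filtered HbO and HbR traces, in the spirit of
#' the scalp-coupling index. A well-coupled optode sees the same cardiac
#' pulsation in both chromophores; a detached or noise-dominated channel does
#' not. Channels scoring below `quality_threshold` are flagged
#' `retained = FALSE` but kept in place, so the channel layout (and hence the
#' feature-vector layout) is stable. Idempotent.
#'
#' @param record an `fnirs_record`.
#' @param quality_threshold minimum score to retain (default 0.7); `-Inf`
#'   retains everything.
#' @return list with `record` (flags updated) and `report` (class
#'   `prune_report`: per-channel score, retained mask, threshold).
#' @export
prune_channels <- function(record, quality_threshold = 0.7) {
  stopifnot(inherits(record, "fnirs_record"))
  nc <- dim(record$data)[2]
  score <- vapply(seq_len(nc), function(ch) {
    hbo_c <- cardiac_bandpass(record$data[1, ch, ], record$fs)
    hbr_c <- cardiac_bandpass(record$data[2, ch, ], record$fs)
    if (sd(hbo_c) == 0 || sd(hbr_c) == 0) return(0)
    abs(stats::cor(hbo_c, hbr_c))
  }, 0)
  retained <- score >= quality_threshold
  if (!any(retained))
    stop("all channels pruned at threshold ", quality_threshold,
         "; pipeline cannot proceed")
  record$channel_meta$retained <- retained
  report <- structure(list(score = score, retained = retained,
                           threshold = quality_threshold),
                      class = "prune_report")
  list(record = record, report = report)
}

# Haar DWT for arbitrary lengths: odd-length levels carry their last sample
# into the approximation untouched, so the pyramid is exactly invertible.
haar_decompose <- function(x, level) {
  details <- vector("list", level)
  carries <- logical(level)
  a <- x
  for (l in seq_len(level)) {
    n <- length(a)
    if (n < 2) { level <- l - 1; break }
    carries[l] <- (n %% 2 == 1)
    m <- n %/% 2
    odd <- a[seq(1, 2 * m, by = 2)]
    even <- a[seq(2, 2 * m, by = 2)]
    details[[l]] <- (odd - even) / sqrt(2)
    app <- (odd + even) / sqrt(2)
    if (carries[l]) app <- c(app, a[n])
    a <- app
  }
  list(approx = a, details = details, carries = carries, level = level)
}

haar_reconstruct <- function(dec) {
  a <- dec$approx
  for (l in rev(seq_len(dec$level))) {
    d <- dec$details[[l]]
    if (is.null(d)) next
    carry <- NULL
    if (dec$carries[l]) {
      carry <- a[length(a)]
      a <- a[-length(a)]
    }
    odd <- (a + d) / sqrt(2)
    even <- (a - d) / sqrt(2)
    out <- numeric(2 * length(a))
    out[seq(1, length(out), by = 2)] <- odd
    out[seq(2, length(out), by = 2)] <- even
    a <- c(out, carry)
  }
  a
}

correct_motion_trace <- function(x, fs, detection_zscore, wavelet_level) {
  n <- length(x)
  flagged <- rep(FALSE, n)
  if (is.finite(detection_zscore)) {
    k <- max(3L, as.integer(fs) %/% 2 * 2 + 1)  # ~1 s odd window
    smooth <- stats::runmed(x, k)
    resid <- x - smooth
    s <- stats::mad(resid)
    if (s > 0) {
      z <- abs(resid) / s
      flagged <- z > detection_zscore
      # step shifts: flag jumps of the smoothed trace, measured against the
      # same residual scale (the jump distribution itself is too narrow to
      # be its own yardstick)
      dsm <- c(0, diff(smooth))
      flagged <- flagged | (abs(dsm) / s > detection_zscore)
      # dilate by 3 samples to cover artifact flanks
      if (any(flagged)) {
        idx <- which(flagged)
        idx <- unique(pmax(1L, pmin(n, rep(idx, each = 7) + (-3:3))))
        flagged[] <- FALSE
        flagged[idx] <- TRUE
      }
    }
    if (all(flagged))
      stop("detected artifact segment spans the entire record")
    if (any(flagged)) {
      good <- which(!flagged)
      x[flagged] <- stats::spline(good, x[good], xout = which(flagged),
                                  method = "natural")$y
    }
    # residual wavelet detail thresholding at the same z level
    dec <- haar_decompose(x, wavelet_level)
    changed <- FALSE
    for (l in seq_len(dec$level)) {
      d <- dec$details[[l]]
      s <- stats::mad(d)
      if (s > 0) {
        big <- abs(d) > detection_zscore * s
        if (any(big)) {
          dec$details[[l]][big] <- sign(d[big]) * detection_zscore * s
          changed <- TRUE
        }
      }
    }
    if (changed) x <- haar_reconstruct(dec)
  }
  list(x = x, flagged = flagged)
}

#' Simplified motion-artifact correction
#'
#' A deliberately lightweight two-stage correction: (1) samples whose
#' deviation from a ~1 s running median exceeds `detection_zscore` robust
#' standard deviations (or whose running-median jump does) are replaced by
#' natural cubic-spline interpolation of the flanking samples; (2) Haar
#' wavelet detail coefficients exceeding the same robust z level are clipped.
#' `detection_zscore = Inf` disables both stages (identity). HbO and HbR are
#' corrected independently; HbT is recomputed as their sum.
#'
#' @param record an `fnirs_record`.
#' @param detection_zscore robust z threshold for spike/shift detection
#'   (default 5).
#' @param wavelet_level Haar decomposition depth (default 4).
#' @return list with `record` (corrected) and `flagged` (channel x time
#'   logical matrix of samples treated in either chromophore).
#' @export
correct_motion <- function(record, detection_zscore = 5, wavelet_level = 4) {
  stopifnot(inherits(record, "fnirs_record"))
  nc <- dim(record$data)[2]
  n <- dim(record$data)[3]
  flagged <- matrix(FALSE, nc, n)
  for (ch in seq_len(nc)) {
    for (b in 1:2) {
      res <- correct_motion_trace(record$data[b, ch, ], record$fs,
                                  detection_zscore, wavelet_level)
      record$data[b, ch, ] <- res$x
      flagged[ch, ] <- flagged[ch, ] | res$flagged
    }
  }
  record$data[3, , ] <- record$data[1, , ] + record$data[2, , ]
  list(record = record, flagged = flagged)
}
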