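#' @importFrom stats rnorm runif rpois sd median mad quantile var fft plogis
#'   rbinom spline splinefun setNames
NULL

# Deterministic child-seed rule: subject streams are independent of cohort
# size, so adding a subject never perturbs earlier ones. Kept below 2^31 - 1.
derive_seed <- function(root, index) {
  as.integer((as.numeric(root) %% 2147483647 * 48271 + index * 65537) %%
               2147483647)
}

band_names <- function() c("HbO", "HbR", "HbT")

#' Generate one synthetic fNIRS record
#'
#' Simulates a single subject's three-band (HbO, HbR, HbT) concentration
#' traces as a sum of sinusoidal physiological components (cardiac,
#' respiratory, Mayer wave, slow drift) with per-channel random phase, small
#' frequency jitter and additive white noise. HbR components are
#' anti-correlated copies of the HbO components (`hbr_ratio`); HbT is
#' constructed as HbO + HbR exactly. For a `"PD"` label, channels listed in
#' `spec$effect_channels` (long channels only) have their Mayer-wave amplitude
#' scaled by `1 + effect_size` and its frequency shifted by
#' `0.01 * effect_size` Hz. Short channels carry only superficial systemic
#' components at half amplitude and never an effect.
#'
#' @param spec a [cohort_spec()].
#' @param model a [signal_model()].
#' @param label `"PD"` or `"control"`.
#' @param seed integer seed for this record's private stream.
#' @param subject_id subject identifier string.
#' @return an object of class `fnirs_record` with fields `data` (band x
#'   channel x time array, uM), `fs`, `channel_meta`, `label`, `subject_id`
#'   and `ground_truth` (realized per-channel component frequencies and
#'   amplitudes).
#' @export
generate_record <- function(spec, model, label = c("control", "PD"),
                            seed = 1L, subject_id = "S01") {
  stopifnot(inherits(spec, "fnirs_cohort_spec"),
            inherits(model, "fnirs_signal_model"))
  label <- match.arg(label)
  if (any(model$components$freq_hz >= spec$fs / 2))
    stop("aliasing error: component frequency at or above fs/2")
  n <- spec$n_samples
  nc <- spec$n_channels
  tt <- (seq_len(n) - 1) / spec$fs
  comp <- model$components
  hbo <- matrix(0, nc, n)
  hbr <- matrix(0, nc, n)
  gt <- vector("list", nc)
  withr::with_seed(seed, {
    for (ch in seq_len(nc)) {
      is_short <- ch > spec$n_long_channels
      ch_scale <- if (is_short) 0.5 else 1
      f <- comp$freq_hz + rnorm(nrow(comp)) * comp$freq_jitter
      a <- comp$amplitude * exp(rnorm(nrow(comp)) * 0.1) * ch_scale
      ph <- runif(nrow(comp), 0, 2 * pi)
      if (label == "PD" && !is_short && ch %in% spec$effect_channels) {
        i <- which(comp$name == "mayer")
        a[i] <- a[i] * (1 + spec$effect_size)
        f[i] <- f[i] + 0.01 * spec$effect_size
      }
      f <- pmin(f, spec$fs / 2 - 1e-6)
      sig <- 0
      for (i in seq_len(nrow(comp)))
        sig <- sig + a[i] * sin(2 * pi * f[i] * tt + ph[i])
      hbo[ch, ] <- sig + rnorm(n, 0, spec$noise_sd)
      hbr[ch, ] <- model$hbr_ratio * sig + rnorm(n, 0, spec$noise_sd * 0.5)
      gt[[ch]] <- data.frame(channel = ch, component = comp$name,
                             freq_hz = f, amplitude = a)
    }
  })
  data <- array(0, dim = c(3L, nc, n),
                dimnames = list(band = band_names(), channel = NULL,
                                time = NULL))
  data[1, , ] <- hbo
  data[2, , ] <- hbr
  data[3, , ] <- hbo + hbr
  meta <- data.frame(
    channel = seq_len(nc),
    source = paste0("S", ((seq_len(nc) - 1) %/% 2) + 1),
    detector = paste0("D", ((seq_len(nc) - 1) %% 8) + 1),
    sep_class = ifelse(seq_len(nc) > spec$n_long_channels, "short", "long"),
    retained = TRUE,
    stringsAsFactors = FALSE
  )
  structure(list(
    subject_id = subject_id,
    bands = band_names(),
    data = data,
    fs = spec$fs,
    channel_meta = meta,
    label = label,
    ground_truth = do.call(rbind, gt)
  ), class = "fnirs_record")
}

#' Generate a balanced two-class synthetic cohort
#'
#' Produces `2 * spec$n_per_class` records (cases first, then controls), each
#' from its own seed stream derived from `spec$seed`, so the cohort is fully
#' reproducible and enlarging it leaves existing subjects bit-identical.
#'
#' @param spec a [cohort_spec()].
#' @param model a [signal_model()]; default model if missing.
#' @return an object of class `fnirs_cohort`: list with `records`, `labels`
#'   (factor, levels control/PD), `spec`, `model`.
#' @export
generate_cohort <- function(spec, model = signal_model(fs_check = spec$fs)) {
  stopifnot(inherits(spec, "fnirs_cohort_spec"))
  if (spec$n_per_class < 1) stop("`n_per_class` must be >= 1")
  records <- vector("list", 2L * spec$n_per_class)
  for (j in seq_len(spec$n_per_class)) {
    records[[j]] <- generate_record(
      spec, model, "PD", seed = derive_seed(spec$seed, j),
      subject_id = sprintf("P%02d", j))
  }
  for (j in seq_len(spec$n_per_class)) {
    records[[spec$n_per_class + j]] <- generate_record(
      spec, model, "control", seed = derive_seed(spec$seed, 100000L + j),
      subject_id = sprintf("C%02d", j))
  }
  labels <- factor(vapply(records, `[[`, "", "label"),
                   levels = c("control", "PD"))
  structure(list(records = records, labels = labels, spec = spec,
                 model = model), class = "fnirs_cohort")
}

#' Inject motion artifacts into a record
#'
#' Adds transient spikes (decaying-exponential pulses of
#' `model$spike_amplitude` times the channel sd) and persistent step baseline
#' shifts at Poisson-distributed times on randomly chosen channels. Both HbO
#' and HbR receive the artifact (HbR scaled by `hbr_ratio`), and HbT is
#' recomputed, mimicking how real motion contaminates all chromophores.
#'
#' @param record an `fnirs_record`.
#' @param model a [signal_model()] carrying `spike_rate` / `shift_rate`
#'   (events per minute).
#' @param seed integer seed.
#' @return list with `record` (contaminated copy) and `artifacts`
#'   (data.frame: channel, type, start, end sample indices — the ground
#'   truth for motion-correction tests).
#' @export
inject_artifacts <- function(record, model, seed = 1L) {
  stopifnot(inherits(record, "fnirs_record"))
  if (model$spike_rate < 0 || model$shift_rate < 0)
    stop("artifact rates must be >= 0")
  n <- dim(record$data)[3]
  nc <- dim(record$data)[2]
  fs <- record$fs
  minutes <- n / fs / 60
  out <- record
  rows <- list()
  withr::with_seed(seed, {
    n_spikes <- rpois(1, model$spike_rate * minutes)
    n_shifts <- rpois(1, model$shift_rate * minutes)
    for (i in seq_len(n_spikes)) {
      ch <- sample.int(nc, 1)
      t0 <- sample.int(n - as.integer(fs), 1)
      dur <- as.integer(round(runif(1, 0.2, 0.5) * fs))
      idx <- t0:min(n, t0 + dur)
      base_sd <- sd(out$data[1, ch, ])
      shape <- exp(-(seq_along(idx) - 1) / (0.5 * fs))
      pulse <- model$spike_amplitude * base_sd * shape
      out$data[1, ch, idx] <- out$data[1, ch, idx] + pulse
      out$data[2, ch, idx] <- out$data[2, ch, idx] + model$hbr_ratio * pulse
      rows[[length(rows) + 1L]] <- data.frame(
        channel = ch, type = "spike", start = idx[1], end = idx[length(idx)])
    }
    for (i in seq_len(n_shifts)) {
      ch <- sample.int(nc, 1)
      t0 <- sample.int(n - 1L, 1)
      base_sd <- sd(out$data[1, ch, ])
      step <- model$shift_amplitude * base_sd * sample(c(-1, 1), 1)
      out$data[1, ch, t0:n] <- out$data[1, ch, t0:n] + step
      out$data[2, ch, t0:n] <- out$data[2, ch, t0:n] +
        model$hbr_ratio * step
      rows[[length(rows) + 1L]] <- data.frame(
        channel = ch, type = "shift", start = t0, end = n)
    }
  })
  out$data[3, , ] <- out$data[1, , ] + out$data[2, , ]
  artifacts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(channel = integer(), type = character(),
               start = integer(), end = integer())
  list(record = out, artifacts = artifacts)
}

#' @export
print.fnirs_record <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("fNIRS record %s [%s]: %d bands x %d channels x %d samples @ %g Hz\n",
              x$subject_id, x$label, d[1], d[2], d[3], x$fs))
  invisible(x)
}

#' @export
print.fnirs_cohort <- function(x, ...) {
  cat(sprintf("fNIRS cohort: %d records (%d PD / %d control), %d channels\n",
              length(x$records), sum(x$labels == "PD"),
              sum(x$labels == "control"), x$spec$n_channels))
  invisible(x)
}
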