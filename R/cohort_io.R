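#' Write a cohort to disk
#'
#' On-disk layout: one CSV per subject per band (`<subject>_<band>.csv`,
#' header `time_s, ch01...chNN`) plus a JSON manifest (`manifest.json`)
#' holding sampling parameters, per-channel metadata and the subject/label
#' table. Plain-text and diffable by design.
#'
#' @param cohort an `fnirs_cohort`.
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "fnirs_cohort"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  subjects <- lapply(cohort$records, function(rec) {
    files <- stats::setNames(
      sprintf("%s_%s.csv", rec$subject_id, rec$bands), rec$bands)
    n <- dim(rec$data)[3]
    time_s <- (seq_len(n) - 1) / rec$fs
    for (b in seq_along(rec$bands)) {
      dt <- data.table::as.data.table(t(rec$data[b, , , drop = TRUE]))
      data.table::setnames(dt, sprintf("ch%02d", seq_len(ncol(dt))))
      dt <- cbind(data.table::data.table(time_s = time_s), dt)
      data.table::fwrite(dt, file.path(path, files[[b]]))
    }
    list(subject_id = rec$subject_id, label = rec$label, files = as.list(files))
  })
  manifest <- list(
    format = "fnirsdx-cohort-v1",
    fs = cohort$spec$fs,
    duration_s = cohort$spec$duration_s,
    n_long_channels = cohort$spec$n_long_channels,
    n_short_channels = cohort$spec$n_short_channels,
    channel_meta = cohort$records[[1]]$channel_meta,
    subjects = subjects
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a cohort from disk
#'
#' Inverse of [write_cohort()]. Fails loudly on a missing manifest, a missing
#' label, or a malformed/truncated channel column (naming the offending
#' subject and channel) rather than silently defaulting.
#'
#' @param path directory written by [write_cohort()].
#' @return an `fnirs_cohort` (without generator ground truth).
#' @export
read_cohort <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf))
    stop("cohort manifest not found: ", mf)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  meta <- as.data.frame(manifest$channel_meta)
  nc <- nrow(meta)
  subjects <- manifest$subjects
  n_sub <- if (is.data.frame(subjects)) nrow(subjects) else length(subjects)
  get_sub <- function(i) {
    if (is.data.frame(subjects)) {
      list(subject_id = subjects$subject_id[i], label = subjects$label[i],
           files = lapply(subjects$files, `[[`, i))
    } else subjects[[i]]
  }
  records <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    s <- get_sub(i)
    if (is.null(s$label) || is.na(s$label) || !nzchar(s$label))
      stop("missing label for subject ", s$subject_id,
           " in cohort manifest")
    bands <- band_names()
    mats <- vector("list", 3)
    for (b in seq_along(bands)) {
      f <- file.path(path, s$files[[bands[b]]])
      if (!file.exists(f)) stop("missing band file: ", f)
      dt <- data.table::fread(f)
      chcols <- sprintf("ch%02d", seq_len(nc))
      missing_cols <- setdiff(chcols, names(dt))
      if (length(missing_cols))
        stop("parse error in ", basename(f), ": missing channel column(s) ",
             paste(missing_cols, collapse = ", "))
      m <- t(as.matrix(dt[, chcols, with = FALSE]))
      if (anyNA(m)) {
        bad <- chcols[rowSums(is.na(m)) > 0][1]
        stop("parse error in ", basename(f), ": non-numeric or truncated ",
             "values in channel ", bad)
      }
      mats[[b]] <- m
    }
    n <- ncol(mats[[1]])
    if (ncol(mats[[2]]) != n || ncol(mats[[3]]) != n)
      stop("parse error for subject ", s$subject_id,
           ": bands have unequal sample counts")
    data <- array(0, dim = c(3L, nc, n),
                  dimnames = list(band = bands, channel = NULL, time = NULL))
    for (b in 1:3) data[b, , ] <- mats[[b]]
    records[[i]] <- structure(list(
      subject_id = s$subject_id, bands = bands, data = data,
      fs = manifest$fs, channel_meta = meta, label = s$label,
      ground_truth = NULL
    ), class = "fnirs_record")
  }
  labels <- factor(vapply(records, `[[`, "", "label"),
                   levels = c("control", "PD"))
  spec <- cohort_spec(
    n_per_class = max(1L, sum(labels == "PD")),
    n_long_channels = manifest$n_long_channels,
    n_short_channels = manifest$n_short_channels,
    fs = manifest$fs, duration_s = manifest$duration_s
  )
  structure(list(records = records, labels = labels, spec = spec,
                 model = NULL), class = "fnirs_cohort")
}
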