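test_that("temporal features recover the analytic values of a pure sine", {
  fs <- 25
  x <- sin(2 * pi * 1 * (0:8999) / fs)
  f <- temporal_features(x, fs)
  # half-period between zero crossings, quarter-period crossing-to-peak
  expect_lt(abs(f[["t_zcint"]] - 0.5), 1 / fs)
  expect_lt(abs(f[["t_zcpeak"]] - 0.25), 1 / fs)
  expect_equal(f[["t_mean"]], 0, tolerance = 1e-12)
  expect_equal(f[["t_var"]], 0.5, tolerance = 1e-3)
})

test_that("temporal moments match direct evaluation of the formulas", {
  x <- c(-3, 1, 2)
  f <- temporal_features(x, fs = 1)
  # oracle: population moments computed by hand-expanded arithmetic
  m2 <- (9 + 1 + 4) / 3
  m3 <- (-27 + 1 + 8) / 3
  expect_equal(f[["t_maxabs"]], 3)
  expect_equal(f[["t_mean"]], 0)
  expect_equal(f[["t_var"]], m2)
  expect_equal(f[["t_skew"]], m3 / m2^1.5)
  expect_false(f[["t_skew"]] == 0)
})

test_that("temporal features transform predictably under negation", {
  withr::with_seed(8, x <- cumsum(rnorm(500)) + sin(2 * pi * (1:500) / 40))
  a <- temporal_features(x, 25)
  b <- temporal_features(-x, 25)
  for (nm in c("t_maxabs", "t_var", "t_zcint", "t_zcpeak"))
    expect_equal(a[[nm]], b[[nm]], tolerance = 1e-12)
  expect_equal(a[["t_mean"]], -b[["t_mean"]])
  expect_equal(a[["t_skew"]], -b[["t_skew"]], tolerance = 1e-12)
})

test_that("degenerate signals use the documented conventions", {
  f <- temporal_features(rep(2, 100), fs = 25)
  expect_equal(f[["t_var"]], 0)
  expect_equal(f[["t_skew"]], 0)
  expect_equal(f[["t_zcint"]], 4)   # sentinel: record duration
  expect_true("constant_signal" %in% attr(f, "flags"))
  expect_error(temporal_features(1, 25), "at least 2 samples")
})

test_that("the spectrum is peak-correct and satisfies Parseval", {
  fs <- 25; n <- 2000
  t <- (0:(n - 1)) / fs
  sp <- power_spectrum(sin(2 * pi * 2 * t), fs)
  expect_lt(abs(sp$freq[which.max(sp$magnitude)] - 2), sp$resolution)
  expect_true(all(diff(sp$freq) > 0))
  expect_lte(max(sp$freq), fs / 2)

  two <- 2 * sin(2 * pi * 0.1 * t) + sin(2 * pi * 1 * t)
  sp2 <- power_spectrum(two, fs)
  i01 <- which.min(abs(sp2$freq - 0.1)); i1 <- which.min(abs(sp2$freq - 1))
  expect_gt(sp2$magnitude[i01], sp2$magnitude[i1])

  withr::with_seed(3, x <- rnorm(999))   # odd length too
  for (sig in list(two, x)) {
    spx <- power_spectrum(sig, fs)
    z <- sig - mean(sig)
    expect_equal(sum(spx$magnitude^2), sum(z^2), tolerance = 1e-9)
  }
})

test_that("spectral features match direct evaluation on a 4-bin spectrum", {
  sp <- structure(list(freq = c(0.5, 1, 1.5, 2),
                       magnitude = c(0, 0, 4, 0), resolution = 0.5),
                  class = "fnirs_spectrum")
  f <- spectral_features(sp)
  expect_equal(f[["s_energy"]], 16)
  expect_equal(f[["s_domfreq"]], 1.5)
  expect_equal(f[["s_mean"]], 1)
  expect_equal(f[["s_var"]], 3)                 # ((1+1+9+1)/4)
  expect_equal(f[["s_skew"]], 6 / 3^1.5)        # m3 = (−1−1+27−1)/4 = 6
  expect_equal(f[["s_kurt"]], (84 / 4) / 9)     # m4 = (1+1+81+1)/4
})

test_that("spectral features obey scale homogeneity", {
  withr::with_seed(5, x <- rnorm(800))
  sp <- power_spectrum(x, 25)
  f1 <- spectral_features(sp)
  sp$magnitude <- 3 * sp$magnitude
  f2 <- spectral_features(sp)
  expect_equal(f2[["s_energy"]], 9 * f1[["s_energy"]])
  expect_equal(f2[["s_domfreq"]], f1[["s_domfreq"]])
  expect_equal(f2[["s_skew"]], f1[["s_skew"]], tolerance = 1e-12)
})

test_that("features are invariant to circular shifts of a periodic signal", {
  fs <- 25
  t <- (0:(25 * 40 - 1)) / fs
  x <- sin(2 * pi * 0.5 * t) + 0.3 * sin(2 * pi * 2 * t)
  xs <- c(x[101:length(x)], x[1:100])
  a <- temporal_features(x, fs); b <- temporal_features(xs, fs)
  for (nm in c("t_maxabs", "t_mean", "t_var", "t_skew"))
    expect_equal(a[[nm]], b[[nm]], tolerance = 1e-9)
  for (nm in c("t_zcint", "t_zcpeak"))
    expect_lt(abs(a[[nm]] - b[[nm]]), 1 / fs)
  sa <- spectral_features(power_spectrum(x, fs))
  sb <- spectral_features(power_spectrum(xs, fs))
  expect_equal(sa[["s_energy"]], sb[["s_energy"]], tolerance = 1e-9)
  expect_equal(sa[["s_domfreq"]], sb[["s_domfreq"]])
})

test_that("the feature matrix has the full layout with parseable names", {
  co <- generate_cohort(small_spec(n_per_class = 2, seed = 2,
                                   n_long = 1, n_short = 0))
  fm <- extract_feature_matrix(co)
  expect_equal(ncol(fm$X), 36L)   # 1 channel x 3 bands x 12 features
  expect_false(anyDuplicated(colnames(fm$X)) > 0)
  expect_match(colnames(fm$X),
               "^ch\\d{2}_(HbO|HbR|HbT)_[ts]_[a-z]+$", all = TRUE)
  expect_identical(fm$feature_info$name, colnames(fm$X))
  expect_equal(sum(fm$feature_info$domain == "temporal"), 18L)

  # column values agree with the single-signal API
  rec <- co$records[[1]]
  ref <- c(temporal_features(rec$data[2, 1, ], rec$fs),
           spectral_features(power_spectrum(rec$data[2, 1, ], rec$fs)))
  got <- fm$X[1, grepl("_HbR_", colnames(fm$X))]
  expect_equal(unname(got), unname(ref), tolerance = 1e-10)
})

test_that("pruned channels are median-filled without disturbing the layout", {
  co <- small_cohort(n_per_class = 2, seed = 17, n_long = 4, n_short = 0)
  co$records[[1]]$channel_meta$retained[2] <- FALSE
  fm <- extract_feature_matrix(co)
  expect_equal(ncol(fm$X), 4L * 36L)
  cols <- grepl("^ch02_", colnames(fm$X))
  expect_true(all(fm$filled[1, cols]))
  expect_false(any(fm$filled[-1, ]))
  others <- fm$X[-1, cols, drop = FALSE]
  expect_equal(unname(fm$X[1, cols]),
               unname(apply(others, 2, median)))
})

test_that("class effects concentrate on the designated channels", {
  # mean absolute Cohen's d on effect channels vs the other long channels,
  # averaged over 10 cohorts
  d_eff <- d_rest <- numeric(10)
  for (r in 1:10) {
    co <- small_cohort(n_per_class = 4, seed = 300 + r)
    fm <- extract_feature_matrix(co)
    pd <- fm$y == "PD"
    cohend <- abs(colMeans(fm$X[pd, ]) - colMeans(fm$X[!pd, ])) /
      (apply(fm$X, 2, sd) + 1e-12)
    ch <- fm$feature_info$channel
    d_eff[r] <- mean(cohend[ch %in% 1:5])
    d_rest[r] <- mean(cohend[ch %in% 6:20])
  }
  expect_gt(mean(d_eff), mean(d_rest))
})

test_that("feature matrices round-trip through CSV", {
  co <- small_cohort(n_per_class = 2, seed = 19, n_long = 2, n_short = 0)
  fm <- extract_feature_matrix(co)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_equal(back$X, fm$X, tolerance = 1e-12)
  expect_identical(back$y, fm$y)
  expect_identical(back$feature_info$name, fm$feature_info$name)
  expect_true(file.exists(paste0(path, ".dict.json")))
})
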