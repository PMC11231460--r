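test_that("MAD scores follow the mean-absolute-deviation definition", {
  X <- cbind(a = c(1, 1, 3, 3), b = rep(5, 4), c = c(0, 2, 4, 6))
  r <- mad_scores(X)
  expect_equal(unname(r$scores["a"]), 1)
  expect_equal(unname(r$scores["b"]), 0)
  expect_true(r$removed[2])
  expect_false(any(r$removed[c(1, 3)]))
  # homogeneity: common positive scaling preserves order and scales scores
  r2 <- mad_scores(X * 3)
  expect_equal(r2$scores, r$scores * 3)
  expect_identical(r2$order, r$order)
})

test_that("MIG equals the label entropy for a label-copy feature", {
  y <- rep(c(0, 1), each = 20)
  X <- cbind(copy = y, noise = withr::with_seed(1, rnorm(40)))
  r <- mig_scores(X, y)
  expect_equal(unname(r$scores["copy"]), 1.0)     # H(y) = 1 bit, balanced
  expect_equal(r$order[1], 1L)
  expect_error(mig_scores(X, rep(0, 40)), "both classes")
})

test_that("MIG is invariant to monotone transforms and row order", {
  withr::with_seed(7, {
    y <- rep(c(0, 1), each = 20)
    x <- rnorm(40) + y
    X <- cbind(x = x, ex = exp(x), neg = -x)
    r <- mig_scores(X, y)
    expect_equal(unname(r$scores["ex"]), unname(r$scores["x"]))
    expect_equal(unname(r$scores["neg"]), unname(r$scores["x"]))
    perm <- sample(40)
    r2 <- mig_scores(X[perm, ], y[perm])
    expect_equal(r2$scores, r$scores)
  })
})

test_that("MIG of an independent feature sits inside its permutation null", {
  withr::with_seed(11, {
    y <- rep(c(0, 1), each = 20)
    x <- rnorm(40)
    obs <- mig_scores(cbind(x), y)$scores[1]
    null <- vapply(1:200, function(i)
      mig_scores(cbind(x), sample(y))$scores[1], 0)
    expect_lte(obs, quantile(null, 0.975))
  })
})

test_that("Fisher scores match a hand-computed ratio and handle degeneracy", {
  # 6-row two-class column, brute-force oracle written out in full
  x <- c(1, 2, 3, 6, 7, 11)
  y <- c(0, 0, 0, 1, 1, 1)
  mu <- mean(x); mu0 <- mean(x[1:3]); mu1 <- mean(x[4:6])
  between <- 0.5 * (mu0 - mu)^2 + 0.5 * (mu1 - mu)^2
  within <- 0.5 * mean((x[1:3] - mu0)^2) + 0.5 * mean((x[4:6] - mu1)^2)
  r <- fisher_scores(cbind(x), y)
  expect_equal(unname(r$scores[1]), between / within)

  # zero within-class variance: infinite score ranks first
  X <- cbind(sep = rep(c(-1, 1), each = 3), const = rep(2, 6),
             noise = c(0.3, -1, 2, 0.1, -0.4, 1))
  r2 <- fisher_scores(X, y)
  expect_identical(unname(r2$scores["sep"]), Inf)
  expect_equal(r2$order[1], 1L)
  expect_equal(unname(r2$scores["const"]), 0)   # 0/0 convention
})

test_that("Fisher scores of label-independent columns stay near zero", {
  # null oracle: with balanced classes of 20, between ~ sigma^2 chi2_1 / 40
  # and within ~ sigma^2, so P(score < 0.1) = P(chi2_1 < 4) ~ 0.954
  hits <- 0
  scores <- numeric(100)
  for (i in 1:100) {
    withr::with_seed(2000 + i, {
      y <- rep(c(0, 1), each = 20)
      x <- rnorm(40)
    })
    scores[i] <- fisher_scores(cbind(x), y)$scores[1]
    if (scores[i] < 0.1) hits <- hits + 1
  }
  expect_gte(hits, 90)
  expect_lt(median(scores), 0.05)
})

test_that("filters are invariant to adding a constant to a column", {
  withr::with_seed(9, {
    y <- rep(c(0, 1), each = 10)
    x <- rnorm(20) + y
  })
  X1 <- cbind(x); X2 <- cbind(x + 100)
  expect_equal(mad_scores(X2)$scores, mad_scores(X1)$scores,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(fisher_scores(X2, y)$scores, fisher_scores(X1, y)$scores,
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(mig_scores(X2, y)$scores, mig_scores(X1, y)$scores,
               ignore_attr = TRUE)
})

make_ranking_from_scores <- function(scores) fnirsdx:::new_ranking("toy", scores)

test_that("the two-of-three vote implements the ceiling top-set rule", {
  d <- 792
  withr::with_seed(4, {
    s1 <- rnorm(d); s2 <- rnorm(d); s3 <- rnorm(d)
  })
  # plant agreement: feature 5 tops all three, feature 9 tops only one
  s1[5] <- s2[5] <- s3[5] <- 100
  s1[9] <- 99
  s2[9] <- s3[9] <- -100
  filters <- lapply(list(s1, s2, s3), make_ranking_from_scores)
  expect_length(top_p_set(filters[[1]], 1), 8L)   # ceiling(7.92)
  v <- vote_subset(filters, 1)
  expect_true(v$mask[5])
  expect_false(v$mask[9])
  # monotone, nested top sets imply subset sizes non-decreasing in p
  sizes <- vapply(1:10, function(p) subset_size(vote_subset(filters, p)), 0)
  expect_true(all(diff(sizes) >= 0))
  for (p in 1:9) {
    a <- vote_subset(filters, p)$mask
    b <- vote_subset(filters, p + 1)$mask
    expect_true(all(b[a]))
  }
})

test_that("the vote sweep returns ten candidates and keeps planted signal", {
  found <- 0
  for (r in 1:20) {
    pm <- planted_matrix(n = 40, d = 50, n_inf = 1, effect = 2.5,
                         seed = 600 + r)
    filters <- list(mad_scores(pm$X), mig_scores(pm$X, pm$y),
                    fisher_scores(pm$X, pm$y))
    ev <- function(mask) evaluate_subset(pm$X, pm$y, mask, k = 5, seed = r)
    vs <- vote_sweep(filters, ev)
    expect_equal(nrow(vs$table), 10L)
    expect_identical(vs$table$p, 1:10)
    if (vs$best$mask[1]) found <- found + 1
  }
  expect_gte(found, 17)
})

test_that("ensemble combination is a set union", {
  mk <- function(idx, d = 12) fnirsdx:::new_subset(seq_len(d) %in% idx, "t")
  a <- mk(1:3); b <- mk(4:7); c <- mk(8:12)
  expect_equal(subset_size(ensemble_combine(a, b, c)), 12L)
  expect_equal(ensemble_combine(a, a, a)$mask, a$mask)
  comb <- ensemble_combine(a, b)
  expect_true(all(comb$mask[a$mask]) && all(comb$mask[b$mask]))
  expect_error(ensemble_combine(a, mk(1, d = 5)), "different feature sets")
})

test_that("every filter ranks planted informative features highly", {
  # d = 100 with 5 informative columns, n = 40: each ranker should place at
  # least 3 of the 5 in its top 10 % in >= 90 % of runs
  ok <- c(mad = 0, mig = 0, fisher = 0)
  n_rep <- 20
  for (r in 1:n_rep) {
    pm <- planted_matrix(n = 40, d = 100, n_inf = 5, effect = 2.5,
                         seed = 700 + r)
    rankers <- list(mad = mad_scores(pm$X),
                    mig = mig_scores(pm$X, pm$y),
                    fisher = fisher_scores(pm$X, pm$y))
    for (nm in names(rankers)) {
      top <- top_p_set(rankers[[nm]], 10)
      if (sum(pm$informative %in% top) >= 3) ok[nm] <- ok[nm] + 1
    }
  }
  for (nm in names(ok)) expect_gte(ok[[nm]], 0.9 * n_rep)
})
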