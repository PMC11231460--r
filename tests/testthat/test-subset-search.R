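test_that("subset fitness is CV accuracy with the documented conventions", {
  y <- rep(c(0, 1), each = 20)
  withr::with_seed(2, X <- cbind(copy = y + 0, noise = rnorm(40)))
  expect_equal(evaluate_subset(X, y, 1, k = 5, seed = 1), 1.0)
  expect_equal(evaluate_subset(X, y, integer(0)), 0)
  expect_equal(evaluate_subset(X, y, logical(2)), 0)
})

test_that("fitness of pure-noise subsets is centred at chance", {
  fits <- vapply(1:50, function(r) {
    withr::with_seed(5000 + r, {
      y <- rep(c(0, 1), each = 20)
      X <- matrix(rnorm(40 * 3), 40, 3)
    })
    evaluate_subset(X, y, 1:3, k = 5, seed = r)
  }, 0)
  expect_lt(abs(mean(fits) - 0.5), 0.12)
})

test_that("the evaluator cache changes cost, never results", {
  pm <- planted_matrix(n = 20, d = 6, seed = 3)
  ev <- make_cv_evaluator(pm$X, pm$y, k = 5, seed = 9)
  m <- c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
  direct <- evaluate_subset(pm$X, pm$y, m, k = 5, seed = 9)
  expect_equal(ev(m), direct)
  expect_equal(ev(m), direct)   # cached second call
})

test_that("greedy searches equal the exhaustive optimum for modular fitness", {
  w <- c(0.30, -0.20, 0.15, 0.05, -0.10, 0.20, -0.05, 0.10)
  ev <- modular_evaluator(w)
  optimum <- which(w > 0)
  fw <- forward_wfss(evaluator = ev, n_features = 8)
  bw <- backward_wfss(evaluator = ev, n_features = 8)
  ex <- exhaustive_select(evaluator = ev, n_features = 8)
  expect_identical(sort(which(fw$subset$mask)), optimum)
  expect_identical(sort(which(bw$subset$mask)), optimum)
  expect_identical(sort(which(ex$subset$mask)), optimum)
  expect_equal(fw$fitness, sum(w[w > 0]))
  expect_equal(bw$fitness, ex$fitness)
})

test_that("wrapper searches honour their stopping rules", {
  # constant evaluator: no strict improvement, forward returns empty
  const_ev <- function(mask) 0.5
  expect_equal(subset_size(forward_wfss(evaluator = const_ev,
                                        n_features = 5)$subset), 0L)
  # a label-copy feature is chosen first and the search can stop at size 1
  y <- rep(c(0, 1), each = 20)
  withr::with_seed(4, X <- cbind(y + 0, matrix(rnorm(40 * 4), 40, 4)))
  fw <- forward_wfss(X, y, k = 5, seed = 2)
  expect_true(fw$subset$mask[1])
  expect_equal(fw$fitness, 1.0)
  expect_equal(fw$trace$feature[1], 1L)
  # single-feature boundary for backward elimination
  one_good <- backward_wfss(evaluator = modular_evaluator(0.4),
                            n_features = 1)
  expect_equal(which(one_good$subset$mask), 1L)
  one_bad <- backward_wfss(evaluator = modular_evaluator(-0.4),
                           n_features = 1)
  expect_equal(subset_size(one_bad$subset), 0L)
})

test_that("backward elimination keeps the only informative feature", {
  y <- rep(c(0, 1), each = 20)
  withr::with_seed(8, X <- cbind(matrix(rnorm(40 * 5), 40, 5), y + 0))
  bw <- backward_wfss(X, y, k = 5, seed = 3)
  expect_true(bw$subset$mask[6])
  expect_gte(bw$fitness, 0.9)
})

test_that("GA configuration defaults follow the published search settings", {
  cfg <- ga_config()
  expect_equal(cfg$population_size, 1000L)
  expect_equal(cfg$generations, 100L)
  expect_equal(cfg$crossover_probability, 0.05)
  expect_equal(cfg$mutation_probability, 0.03)
  expect_error(ga_config(population_size = 1), "population_size")
  expect_error(ga_config(mutation_probability = 1.5), "probabilities")
  expect_error(ga_config(elitism_count = 10, population_size = 5),
               "elitism")
})

test_that("GA search is deterministic, elitist-monotone, and finds optima", {
  pm <- planted_matrix(n = 40, d = 10, n_inf = 2, effect = 2, seed = 12)
  ev <- make_cv_evaluator(pm$X, pm$y, k = 5, seed = 12)
  cfg <- ga_config(population_size = 60, generations = 12, seed = 5)
  g1 <- ga_select(evaluator = ev, n_features = 10, config = cfg)
  g2 <- ga_select(evaluator = ev, n_features = 10, config = cfg)
  expect_identical(g1$subset$mask, g2$subset$mask)
  expect_equal(g1$fitness, g2$fitness)
  expect_true(all(diff(g1$trace$best_ever) >= 0))
  ex <- exhaustive_select(evaluator = ev, n_features = 10)
  expect_gte(ex$fitness, g1$fitness)   # GA can never beat the oracle
})

test_that("exhaustive search handles boundaries, ties and symmetry", {
  expect_equal(subset_size(exhaustive_select(
    evaluator = modular_evaluator(-0.2), n_features = 1)$subset), 0L)
  expect_equal(which(exhaustive_select(
    evaluator = modular_evaluator(0.2), n_features = 1)$subset$mask), 1L)

  # known best pair in a 3-feature toy: features 1 and 3 interact
  ev3 <- function(mask) {
    if (is.logical(mask)) mask <- which(mask)
    if (setequal(mask, c(1, 3))) return(0.9)
    if (length(mask)) 0.4 else 0
  }
  ex <- exhaustive_select(evaluator = ev3, n_features = 3)
  expect_identical(which(ex$subset$mask), c(1L, 3L))
  expect_equal(ex$fitness, 0.9)

  # tie-break: equal fitness everywhere -> empty set (smallest subset)
  ex_tie <- exhaustive_select(evaluator = function(m) 0, n_features = 4)
  expect_equal(subset_size(ex_tie$subset), 0L)

  # permutation symmetry up to relabeling
  w <- c(0.3, -0.1, 0.2)
  perm <- c(3, 1, 2)
  ex_a <- exhaustive_select(evaluator = modular_evaluator(w),
                            n_features = 3)
  ex_b <- exhaustive_select(evaluator = modular_evaluator(w[perm]),
                            n_features = 3)
  expect_equal(sort(perm[which(ex_b$subset$mask)]),
               sort(which(ex_a$subset$mask)))
  expect_error(exhaustive_select(evaluator = modular_evaluator(rep(1, 20)),
                                 n_features = 20), "refusing")
})

test_that("searches never fall below the empty-set baseline", {
  for (r in 1:5) {
    pm <- planted_matrix(n = 20, d = 6, n_inf = 1, effect = 1,
                         seed = 900 + r)
    ev <- make_cv_evaluator(pm$X, pm$y, k = 5, seed = r)
    expect_gte(forward_wfss(evaluator = ev, n_features = 6)$fitness, 0)
    expect_gte(backward_wfss(evaluator = ev, n_features = 6)$fitness, 0)
    g <- ga_select(evaluator = ev, n_features = 6,
                   config = ga_config(population_size = 20,
                                      generations = 5, seed = r))
    expect_gte(g$fitness, 0)
  }
})
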