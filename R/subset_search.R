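#' Cross-validated accuracy of a feature subset
#'
#' The fitness function driving wrapper and genetic subset search: mean
#' k-fold cross-validated accuracy of the logistic classifier restricted to
#' the masked columns. The empty mask scores 0 by convention. Deterministic
#' given `seed`.
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @param mask logical mask or integer column indices.
#' @param k folds (default 5).
#' @param seed fold seed.
#' @return fitness in [0, 1].
#' @export
evaluate_subset <- function(X, y, mask, k = 5, seed = 1L) {
  if (is.logical(mask)) mask <- which(mask)
  if (!length(mask)) return(0)
  y01 <- as01(y)
  fold <- make_folds(y01, k, seed = seed)
  Xs <- as.matrix(X)[, mask, drop = FALSE]
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    model <- fit_logistic(Xs[tr, , drop = FALSE], y01[tr])
    p <- predict(model, Xs[!tr, , drop = FALSE])
    acc[f] <- mean(as.integer(p >= 0.5) == y01[!tr])
  }
  mean(acc)
}

#' Build a cached subset evaluator
#'
#' Wraps [evaluate_subset()] in a mask-keyed cache; caching changes cost,
#' never results, because the evaluator is deterministic.
#'
#' @inheritParams evaluate_subset
#' @return `function(mask) -> fitness`.
#' @export
make_cv_evaluator <- function(X, y, k = 5, seed = 1L) {
  cache <- new.env(parent = emptyenv())
  function(mask) {
    if (is.logical(mask)) mask <- which(mask)
    key <- paste0("m", paste(mask, collapse = "-"))
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- evaluate_subset(X, y, mask, k = k, seed = seed)
    cache[[key]] <- val
    val
  }
}

resolve_evaluator <- function(X, y, evaluator, k, seed) {
  if (is.null(evaluator)) {
    if (is.null(X)) stop("supply `X`/`y` or an `evaluator`")
    make_cv_evaluator(X, y, k = k, seed = seed)
  } else evaluator
}

#' Forward wrapper feature subset selection
#'
#' Greedy forward search: starting from the empty set (whose fitness the
#' evaluator defines; 0 for the CV-accuracy evaluator), repeatedly
#' adds the feature whose addition most improves the evaluator, breaking ties
#' toward the lowest feature index, and stops when no addition strictly
#' improves fitness.
#'
#' @param X,y data for the default CV-accuracy evaluator (ignored when
#'   `evaluator` is supplied).
#' @param evaluator optional `function(mask) -> fitness`.
#' @param n_features feature-universe size (defaults to `ncol(X)`).
#' @param k,seed CV parameters for the default evaluator.
#' @return list with `subset` (an `fnirs_subset`), `fitness`, and `trace`
#'   (one row per accepted step).
#' @export
forward_wfss <- function(X = NULL, y = NULL, evaluator = NULL,
                         n_features = if (is.null(X)) NULL else ncol(X),
                         k = 5, seed = 1L) {
  evaluator <- resolve_evaluator(X, y, evaluator, k, seed)
  d <- n_features
  if (is.null(d) || d < 1) stop("need at least 1 feature")
  mask <- rep(FALSE, d)
  fitness <- evaluator(mask)   # empty-set baseline (0 for CV evaluators)
  trace <- list()
  repeat {
    cand <- which(!mask)
    if (!length(cand)) break
    fits <- vapply(cand, function(j) {
      m <- mask; m[j] <- TRUE; evaluator(m)
    }, 0)
    best <- which.max(fits)          # ties -> lowest index (first max)
    if (fits[best] > fitness) {
      mask[cand[best]] <- TRUE
      fitness <- fits[best]
      trace[[length(trace) + 1L]] <- data.frame(
        step = length(trace) + 1L, action = "add",
        feature = cand[best], fitness = fitness, size = sum(mask))
    } else break
  }
  list(subset = new_subset(mask, "forward_wfss"), fitness = fitness,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(step = integer(), action = character(),
                    feature = integer(), fitness = numeric(),
                    size = integer()))
}

#' Backward wrapper feature subset selection
#'
#' Greedy backward elimination: starting from the full set, repeatedly
#' removes the feature whose removal most improves (or least harms) the
#' evaluator, breaking ties toward the lowest feature index, and stops once
#' every possible removal would strictly decrease fitness.
#'
#' @inheritParams forward_wfss
#' @return list with `subset`, `fitness`, `trace`.
#' @export
backward_wfss <- function(X = NULL, y = NULL, evaluator = NULL,
                          n_features = if (is.null(X)) NULL else ncol(X),
                          k = 5, seed = 1L) {
  evaluator <- resolve_evaluator(X, y, evaluator, k, seed)
  d <- n_features
  if (is.null(d) || d < 1) stop("need at least 1 feature")
  mask <- rep(TRUE, d)
  fitness <- evaluator(mask)
  trace <- list()
  while (sum(mask) > 0) {
    cand <- which(mask)
    fits <- vapply(cand, function(j) {
      m <- mask; m[j] <- FALSE
      if (!any(m)) 0 else evaluator(m)
    }, 0)
    best <- which.max(fits)
    if (fits[best] >= fitness) {
      mask[cand[best]] <- FALSE
      fitness <- fits[best]
      trace[[length(trace) + 1L]] <- data.frame(
        step = length(trace) + 1L, action = "remove",
        feature = cand[best], fitness = fitness, size = sum(mask))
    } else break
  }
  list(subset = new_subset(mask, "backward_wfss"), fitness = fitness,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(step = integer(), action = character(),
                    feature = integer(), fitness = numeric(),
                    size = integer()))
}

#' Genetic-algorithm configuration
#'
#' Defaults follow the evolutionary search used for the diagnostic pipeline:
#' a population of 1000 feature subsets evolved for 100 generations with a
#' per-pair single-point crossover probability of 0.05 and a per-bit mutation
#' probability of 0.03, with classifier accuracy as the fitness. The
#' crossover probability is unusually low for a GA but is applied as stated.
#'
#' @param population_size number of individuals (>= 2).
#' @param generations number of generations (>= 1).
#' @param crossover_probability probability a selected parent pair is
#'   recombined by single-point crossover (otherwise copied unchanged).
#' @param mutation_probability per-bit flip probability applied to children.
#' @param elitism_count best individuals copied unchanged each generation
#'   (default 1; guarantees a non-decreasing best-fitness trace).
#' @param selection `"tournament"` (size 2, default) or `"roulette"`
#'   (fitness-proportional).
#' @param init_bit_probability probability a bit of an initial individual is
#'   set (default 0.5).
#' @param seed RNG seed for the whole search.
#' @return an object of class `ga_config`.
#' @export
ga_config <- function(population_size = 1000, generations = 100,
                      crossover_probability = 0.05,
                      mutation_probability = 0.03,
                      elitism_count = 1,
                      selection = c("tournament", "roulette"),
                      init_bit_probability = 0.5,
                      seed = 1L) {
  selection <- match.arg(selection)
  if (population_size < 2) stop("invalid GA config: population_size >= 2")
  if (generations < 1) stop("invalid GA config: generations >= 1")
  for (p in c(crossover_probability, mutation_probability,
              init_bit_probability))
    if (p < 0 || p > 1) stop("invalid GA config: probabilities must be in [0,1]")
  if (elitism_count < 0 || elitism_count >= population_size)
    stop("invalid GA config: elitism_count out of range")
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_probability = crossover_probability,
                 mutation_probability = mutation_probability,
                 elitism_count = as.integer(elitism_count),
                 selection = selection,
                 init_bit_probability = init_bit_probability,
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Genetic-algorithm feature subset selection
#'
#' Evolves binary feature masks (1 = feature present): random initial
#' population, parent selection by size-2 tournament (or roulette wheel),
#' single-point crossover applied per parent pair with
#' `crossover_probability`, per-bit mutation with `mutation_probability`, and
#' elitism. Fitness values are cached by mask, which changes cost only. The
#' best individual ever seen is returned; fully reproducible from
#' `config$seed`.
#'
#' @inheritParams forward_wfss
#' @param config a [ga_config()].
#' @return list with `subset`, `fitness`, and `trace` (per generation: best
#'   and mean fitness, best subset size).
#' @export
ga_select <- function(X = NULL, y = NULL, evaluator = NULL,
                      n_features = if (is.null(X)) NULL else ncol(X),
                      config = ga_config(), k = 5, seed = 1L) {
  stopifnot(inherits(config, "ga_config"))
  evaluator <- resolve_evaluator(X, y, evaluator, k, seed)
  d <- n_features
  if (is.null(d) || d < 1) stop("need at least 1 feature")
  cache <- new.env(parent = emptyenv())
  eval_mask <- function(m) {
    if (!any(m)) return(0)
    key <- paste(which(m), collapse = "-")
    if (is.null(cache[[key]])) cache[[key]] <- evaluator(m)
    cache[[key]]
  }
  np <- config$population_size
  trace <- vector("list", config$generations)
  best_mask <- rep(FALSE, d)
  best_fit <- 0
  withr::with_seed(config$seed, {
    pop <- matrix(stats::rbinom(np * d, 1, config$init_bit_probability) == 1,
                  nrow = np)
    for (gen in seq_len(config$generations)) {
      fits <- vapply(seq_len(np), function(i) eval_mask(pop[i, ]), 0)
      gi <- which.max(fits)
      if (fits[gi] > best_fit) {
        best_fit <- fits[gi]
        best_mask <- pop[gi, ]
      }
      trace[[gen]] <- data.frame(generation = gen, best = max(fits),
                                 mean = mean(fits),
                                 best_ever = best_fit,
                                 best_size = sum(pop[which.max(fits), ]))
      if (gen == config$generations) break
      elite_idx <- order(-fits, seq_len(np))[seq_len(config$elitism_count)]
      nxt <- matrix(FALSE, np, d)
      n_have <- config$elitism_count
      if (n_have > 0) nxt[seq_len(n_have), ] <- pop[elite_idx, , drop = FALSE]
      pick_parent <- switch(config$selection,
        tournament = function() {
          ij <- sample.int(np, 2, replace = TRUE)
          ij[which.max(fits[ij])]
        },
        roulette = function() {
          w <- fits + 1e-9
          sample.int(np, 1, prob = w / sum(w))
        })
      while (n_have < np) {
        p1 <- pop[pick_parent(), ]
        p2 <- pop[pick_parent(), ]
        if (d > 1 && stats::runif(1) < config$crossover_probability) {
          cut <- sample.int(d - 1L, 1)
          c1 <- c(p1[seq_len(cut)], p2[(cut + 1L):d])
          c2 <- c(p2[seq_len(cut)], p1[(cut + 1L):d])
        } else {
          c1 <- p1; c2 <- p2
        }
        for (child in list(c1, c2)) {
          if (n_have >= np) break
          flips <- stats::runif(d) < config$mutation_probability
          child <- xor(child, flips)
          n_have <- n_have + 1L
          nxt[n_have, ] <- child
        }
      }
      pop <- nxt
    }
  })
  list(subset = new_subset(best_mask, "ga_select"), fitness = best_fit,
       trace = do.call(rbind, trace))
}

#' Exhaustive feature subset search (test oracle)
#'
#' Evaluates every one of the `2^d` masks and returns the argmax; ties break
#' toward the smaller subset, then lexicographically (ascending binary code,
#' feature 1 = least significant bit). Refuses more than `max_features`
#' features — the cost is exponential, which is exactly why the heuristic
#' searches exist; this is their ground-truth check at toy sizes.
#'
#' @inheritParams forward_wfss
#' @param max_features hard cap on `n_features` (default 16).
#' @return list with `subset` and `fitness`.
#' @export
exhaustive_select <- function(X = NULL, y = NULL, evaluator = NULL,
                              n_features = if (is.null(X)) NULL else ncol(X),
                              max_features = 16, k = 5, seed = 1L) {
  evaluator <- resolve_evaluator(X, y, evaluator, k, seed)
  d <- n_features
  if (is.null(d) || d < 1) stop("need at least 1 feature")
  if (d > max_features)
    stop("refusing exhaustive search over ", d, " features (cap ",
         max_features, ")")
  best_mask <- rep(FALSE, d)
  best_fit <- 0
  best_size <- 0L
  for (code in seq_len(2^d) - 1L) {
    mask <- as.logical(bitwAnd(bitwShiftR(code, 0:(d - 1L)), 1L))
    f <- if (any(mask)) evaluator(mask) else 0
    size <- sum(mask)
    if (f > best_fit ||
        (f == best_fit && (size < best_size))) {
      best_fit <- f; best_mask <- mask; best_size <- size
    }
  }
  list(subset = new_subset(best_mask, "exhaustive_select"),
       fitness = best_fit)
}
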