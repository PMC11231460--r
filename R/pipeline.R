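#' Pipeline configuration
#'
#' Bundles every knob of the four-stage pipeline (condition, extract, select,
#' evaluate). Input is either a cohort directory written by [write_cohort()]
#' or a synthetic [cohort_spec()]. The two experimental settings mirror the
#' two ways of arriving at a final subset: setting A runs the filter-vote +
#' elastic-net + L1-SVM ensemble first and hands the combined subset to a
#' second-stage search (WFSS or GA); setting B runs the search directly on
#' all extracted features.
#'
#' @param setting one of `"A_ensemble_then_wfss"`, `"A_ensemble_then_ga"`,
#'   `"B_wfss_only"`, `"B_ga_only"`.
#' @param spec synthetic-input [cohort_spec()] (ignored when `cohort_path`
#'   is given).
#' @param model [signal_model()] for synthetic input.
#' @param cohort_path directory of an on-disk cohort (exclusive with
#'   synthetic input).
#' @param k cross-validation folds for the final evaluation (5 or 10).
#' @param ga a [ga_config()]; its seed is re-derived from the root seed.
#' @param leakage_mode `"pooled"` (the original protocol's order) fits standardization and runs selection once
#'   on the full cohort before CV (faithful to the original protocol);
#'   `"nested"` re-fits both inside every training fold, giving an unbiased
#'   estimate.
#' @param prune,quality_threshold channel pruning switch and threshold.
#' @param motion_correct apply [correct_motion()] before extraction.
#' @param p_grid vote-sweep percentages (default 1:10).
#' @param l1_ratio elastic-net mixing parameter.
#' @param out_dir optional output directory for the JSON report and CSVs.
#' @param seed root seed; every stage seed is derived from it.
#' @return an object of class `fnirs_pipeline_config`.
#' @export
pipeline_config <- function(setting = c("A_ensemble_then_ga",
                                        "A_ensemble_then_wfss",
                                        "B_wfss_only", "B_ga_only"),
                            spec = cohort_spec(),
                            model = signal_model(),
                            cohort_path = NULL,
                            k = 5,
                            ga = ga_config(),
                            leakage_mode = c("pooled", "nested"),
                            prune = TRUE,
                            quality_threshold = 0.7,
                            motion_correct = TRUE,
                            p_grid = 1:10,
                            l1_ratio = 0.5,
                            out_dir = NULL,
                            seed = 1L) {
  setting <- match.arg(setting)
  leakage_mode <- match.arg(leakage_mode)
  if (!is.null(cohort_path) && !dir.exists(cohort_path))
    stop("cohort_path does not exist: ", cohort_path)
  seed <- as.integer(seed)
  seeds <- list(root = seed,
                selection = derive_seed(seed, 11L),
                cv = derive_seed(seed, 12L),
                ga = derive_seed(seed, 13L))
  ga$seed <- seeds$ga
  structure(list(setting = setting, spec = spec, model = model,
                 cohort_path = cohort_path, k = k, ga = ga,
                 leakage_mode = leakage_mode, prune = prune,
                 quality_threshold = quality_threshold,
                 motion_correct = motion_correct, p_grid = p_grid,
                 l1_ratio = l1_ratio, out_dir = out_dir,
                 seed = seed, seeds = seeds),
            class = "fnirs_pipeline_config")
}

# Stage-A ensemble + stage-2 search (or stage-B direct search) on a
# standardized matrix. Returns the final mask over the full feature universe
# plus per-stage diagnostics.
select_features <- function(X, y, cfg) {
  sel_seed <- cfg$seeds$selection
  d <- ncol(X)
  details <- list()
  if (startsWith(cfg$setting, "A")) {
    filters <- list(mad_scores(X), mig_scores(X, y), fisher_scores(X, y))
    sweep_eval <- function(mask) evaluate_subset(X, y, mask, k = cfg$k,
                                                 seed = sel_seed)
    vs <- vote_sweep(filters, sweep_eval, p_grid = cfg$p_grid)
    enet <- elastic_net_subset(X, y, l1_ratio = cfg$l1_ratio,
                               seed = sel_seed)
    svm <- l1_svm_subset(X, y, seed = sel_seed)
    comb <- ensemble_combine(vs$best, enet, svm)
    details$vote <- vs$table
    details$vote_best_p <- vs$best_p
    details$sizes <- c(vote = subset_size(vs$best),
                       elastic_net = subset_size(enet),
                       l1_svm = subset_size(svm),
                       combined = subset_size(comb))
    universe <- which(comb$mask)
    X2 <- X[, universe, drop = FALSE]
    ev2 <- make_cv_evaluator(X2, y, k = cfg$k, seed = sel_seed)
    if (endsWith(cfg$setting, "ga")) {
      res <- ga_select(evaluator = ev2, n_features = length(universe),
                       config = cfg$ga)
    } else {
      res <- forward_wfss(evaluator = ev2, n_features = length(universe))
    }
    mask <- rep(FALSE, d)
    mask[universe[res$subset$mask]] <- TRUE
    details$search_trace <- res$trace
    details$search_fitness <- res$fitness
    list(mask = mask, details = details,
         provenance = paste0(cfg$setting, " over ", length(universe),
                             " combined candidates"))
  } else {
    ev <- make_cv_evaluator(X, y, k = cfg$k, seed = sel_seed)
    if (endsWith(cfg$setting, "ga_only")) {
      res <- ga_select(evaluator = ev, n_features = d, config = cfg$ga)
    } else {
      res <- forward_wfss(evaluator = ev, n_features = d)
    }
    details$search_trace <- res$trace
    details$search_fitness <- res$fitness
    list(mask = res$subset$mask, details = details,
         provenance = paste0(cfg$setting, " over all ", d, " features"))
  }
}

condition_cohort <- function(cohort, cfg) {
  prune_scores <- NULL
  for (i in seq_along(cohort$records)) {
    rec <- cohort$records[[i]]
    if (cfg$prune) {
      pr <- prune_channels(rec, cfg$quality_threshold)
      rec <- pr$record
      prune_scores <- rbind(prune_scores, pr$report$score)
    }
    if (cfg$motion_correct) {
      rec <- correct_motion(rec)$record
    }
    cohort$records[[i]] <- rec
  }
  list(cohort = cohort, prune_scores = prune_scores)
}

#' Run the full diagnostic pipeline
#'
#' Executes load/generate, channel pruning and motion correction, feature
#' extraction (12 features per channel and band), standardization, feature
#' selection per the configured setting, and stratified k-fold logistic
#' evaluation of the final subset. In `"nested"` leakage mode,
#' standardization and the whole selection stage are re-fitted inside every
#' training fold and the held-out folds alone produce the metrics.
#'
#' @param cfg a [pipeline_config()].
#' @return an object of class `fnirs_report` (a structured list); also
#'   written to `cfg$out_dir` as JSON + CSV when set.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "fnirs_pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cohort <- stage("input", {
    if (!is.null(cfg$cohort_path)) read_cohort(cfg$cohort_path)
    else generate_cohort(cfg$spec, cfg$model)
  })
  cond <- stage("condition", condition_cohort(cohort, cfg))
  fm <- stage("extract", extract_feature_matrix(cond$cohort))
  y <- fm$y
  report <- list(setting = cfg$setting, leakage_mode = cfg$leakage_mode,
                 n_subjects = nrow(fm$X), n_features = ncol(fm$X),
                 k = cfg$k, seeds = cfg$seeds)
  if (cfg$leakage_mode == "pooled") {
    std <- stage("standardize", standardize_features(fm))
    X <- std$features$X
    sel <- stage("select", select_features(X, y, cfg))
    if (!any(sel$mask)) stop("pipeline stage [select] returned no features")
    cv <- stage("evaluate",
                kfold_evaluate(X, y, which(sel$mask), k = cfg$k,
                               seed = cfg$seeds$cv))
    report$selection <- sel$details[setdiff(names(sel$details),
                                            "search_trace")]
    report$search_trace <- sel$details$search_trace
    report$final_subset <- list(
      size = sum(sel$mask),
      indices = which(sel$mask),
      names = colnames(fm$X)[sel$mask],
      provenance = sel$provenance)
    report$cv <- list(folds = cv$folds, aggregate = cv$aggregate)
    report$metrics <- cv$aggregate
  } else {
    fold <- make_folds(as01(y), cfg$k, seed = cfg$seeds$cv)
    y01 <- as01(y)
    pooled <- numeric(length(y01))
    rows <- list(); sizes <- integer(cfg$k)
    for (f in seq_len(cfg$k)) {
      tr <- which(fold != f); te <- which(fold == f)
      fm_tr <- fm; fm_tr$X <- fm$X[tr, , drop = FALSE]
      fm_tr$y <- y[tr]
      std <- standardize_features(fm_tr)
      Xtr <- std$features$X
      Xte <- sweep(sweep(fm$X[te, , drop = FALSE], 2, std$center), 2,
                   std$scale, "/")
      sel <- stage(sprintf("select(fold %d)", f),
                   select_features(Xtr, y[tr], cfg))
      if (!any(sel$mask)) stop("nested selection returned no features")
      sizes[f] <- sum(sel$mask)
      model <- fit_logistic(Xtr[, sel$mask, drop = FALSE], y01[tr])
      p <- predict(model, Xte[, sel$mask, drop = FALSE])
      pooled[te] <- p
      pred <- as.integer(p >= 0.5)
      tp <- sum(pred == 1 & y01[te] == 1); fp <- sum(pred == 1 & y01[te] == 0)
      tn <- sum(pred == 0 & y01[te] == 0); fn <- sum(pred == 0 & y01[te] == 1)
      m <- confusion_metrics(tp, fp, tn, fn)
      rows[[f]] <- data.frame(fold = f, n = length(te), tp = tp, fp = fp,
                              tn = tn, fn = fn, accuracy = m$accuracy,
                              precision = m$precision, recall = m$recall,
                              f1 = m$f1)
    }
    folds <- do.call(rbind, rows)
    report$cv <- list(folds = folds)
    report$metrics <- list(
      accuracy = mean(folds$accuracy),
      precision = mean(folds$precision, na.rm = TRUE),
      recall = mean(folds$recall, na.rm = TRUE),
      f1 = mean(folds$f1, na.rm = TRUE),
      auc_pooled = roc_auc(pooled, y01))
    report$final_subset <- list(size = mean(sizes),
                                fold_sizes = sizes,
                                provenance = "nested per-fold selection")
  }
  report$timing_s <- proc.time()[["elapsed"]] - t0
  class(report) <- "fnirs_report"
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ser <- unclass(report)
  jsonlite::write_json(ser, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", force = TRUE)
  if (!is.null(report$cv$folds))
    data.table::fwrite(report$cv$folds, file.path(out_dir, "cv_folds.csv"))
  if (!is.null(report$search_trace) && nrow(report$search_trace))
    data.table::fwrite(report$search_trace,
                       file.path(out_dir, "search_trace.csv"))
  invisible(out_dir)
}

#' @export
print.fnirs_report <- function(x, ...) {
  cat(sprintf("fNIRS pipeline report [%s, %s leakage]\n", x$setting,
              x$leakage_mode))
  cat(sprintf("  %d subjects x %d features; final subset size %s\n",
              x$n_subjects, x$n_features,
              format(x$final_subset$size)))
  m <- x$metrics
  cat(sprintf("  %d-fold CV: accuracy %.3f | precision %.3f | recall %.3f | F1 %.3f | AUC %.3f\n",
              x$k, m$accuracy, m$precision, m$recall, m$f1, m$auc_pooled))
  invisible(x)
}
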