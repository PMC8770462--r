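## Replicated experiments, feature-frequency rankings and the
## across-method comparison table.

#' Run one selector many times with derived seeds
#'
#' Repeats a selection method `n_runs` times; run `i` receives selector,
#' split and training seeds all derived deterministically from
#' `master_seed`, so runs differ in initialisation *and* in the 80/20 split
#' while the whole experiment stays reproducible. Collects each run's
#' operating-point accuracy, subset size and wall time, plus per-feature
#' selection counts over the operating-point masks. A failed run is
#' recorded and excluded with a warning.
#'
#' @param table,labels the cohort.
#' @param method `"nsga2"`, `"ga"`, `"aco"`, `"sa"` or `"pso"`.
#' @param eval_cfg an [eval_config()] template (seeds overwritten per run).
#' @param method_cfg optional method config template (seed overwritten).
#' @param n_runs number of replicates. Default 100.
#' @param master_seed seed all per-run seeds derive from.
#' @return List of class `replication_summary`: `method`, `n_runs`, `runs`
#'   (data.frame: seed, accuracy, size, seconds, failed), `mean_accuracy`,
#'   `sd_accuracy`, `mean_time`, `sd_time`, `selection_counts` (named
#'   integer vector over features), `n_failed`.
#' @export
run_replicated_experiment <- function(table, labels, method,
                                      eval_cfg = eval_config(),
                                      method_cfg = NULL, n_runs = 100L,
                                      master_seed = 1L) {
  stopifnot(inherits(table, "feature_table"), is_count(n_runs, 1L))
  labels <- cohort_labels(labels)
  p <- ncol(table$values)
  counts <- stats::setNames(integer(p), table$feature_names)
  runs <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    run_seed <- derive_seed(master_seed, i)
    cfg_i <- eval_cfg
    cfg_i$split$seed <- derive_seed(run_seed, 11L)
    cfg_i$train$seed <- derive_seed(run_seed, 12L)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      run_selector(method, table, labels, cfg_i, method_cfg, seed = run_seed),
      error = function(e) e)
    secs <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      warning(sprintf("run %d failed: %s", i, conditionMessage(res)),
              call. = FALSE)
      runs[[i]] <- data.frame(seed = run_seed, accuracy = NA_real_,
                              size = NA_integer_, seconds = secs,
                              failed = TRUE)
      next
    }
    if (inherits(res, "pareto_result")) {
      mask <- res$operating_point
      acc <- res$operating_accuracy
    } else {
      mask <- res$best_mask
      ## scalar fitness includes the size penalty; report pure accuracy
      acc <- 1 - evaluate_subset(table, labels, mask, cfg_i)$error
    }
    counts <- counts + as.integer(mask)
    runs[[i]] <- data.frame(seed = run_seed, accuracy = acc,
                            size = sum(mask), seconds = secs, failed = FALSE)
  }
  runs <- do.call(rbind, runs)
  ok <- !runs$failed
  structure(list(method = method, n_runs = as.integer(n_runs), runs = runs,
                 mean_accuracy = mean(runs$accuracy[ok]),
                 sd_accuracy = stats::sd(runs$accuracy[ok]),
                 mean_time = mean(runs$seconds[ok]),
                 sd_time = stats::sd(runs$seconds[ok]),
                 selection_counts = counts,
                 n_failed = sum(!ok)),
            class = "replication_summary")
}

#' @export
print.replication_summary <- function(x, ...) {
  cat(sprintf("<replication_summary> %s: %d runs, accuracy %.3f (SD %.3f)%s\n",
              x$method, x$n_runs, x$mean_accuracy, x$sd_accuracy,
              if (x$n_failed) sprintf(", %d failed", x$n_failed) else ""))
  invisible(x)
}

#' Most frequently selected features across replicates
#'
#' Ranks features by how often they appear in the replicates'
#' operating-point subsets (the "most indicative regions" table of a
#' replicated experiment). Ties are broken alphabetically for determinism.
#'
#' @param summary a [run_replicated_experiment()] result.
#' @param top_k how many features to return. Default 5.
#' @return Character vector of feature names, most frequent first.
#' @export
feature_frequency_ranking <- function(summary, top_k = 5L) {
  stopifnot(inherits(summary, "replication_summary"), is_count(top_k, 1L))
  counts <- summary$selection_counts
  if (top_k > length(counts)) {
    stop_named("evoselect_bad_k", "top_k exceeds the number of features")
  }
  ord <- order(-counts, names(counts))
  names(counts)[ord][seq_len(top_k)]
}

#' Per-method differences from the cross-method average
#'
#' For each method, reports the mean (SD) accuracy and wall-time and their
#' differences from the average over all supplied methods — the standard
#' way to display several near-equivalent optimisers side by side. Deltas
#' sum to zero across methods by construction.
#'
#' @param summaries list of `replication_summary` objects (`>= 2`).
#' @return `data.frame` of class `comparison_table`: `method`,
#'   `mean_accuracy`, `sd_accuracy`, `accuracy_delta`, `mean_time`,
#'   `sd_time`, `time_delta`.
#' @export
compare_methods <- function(summaries) {
  if (!is.list(summaries) || length(summaries) < 2L ||
      !all(vapply(summaries, inherits, logical(1), "replication_summary"))) {
    stop_named("evoselect_bad_input",
               "need a list of >= 2 replication summaries")
  }
  n_runs <- vapply(summaries, function(s) s$n_runs, integer(1))
  if (length(unique(n_runs)) > 1L) {
    warning("summaries have differing n_runs; comparison may be unbalanced",
            call. = FALSE)
  }
  acc <- vapply(summaries, function(s) s$mean_accuracy, numeric(1))
  tim <- vapply(summaries, function(s) s$mean_time, numeric(1))
  out <- data.frame(
    method = vapply(summaries, function(s) s$method, character(1)),
    mean_accuracy = acc,
    sd_accuracy = vapply(summaries, function(s) s$sd_accuracy, numeric(1)),
    accuracy_delta = acc - mean(acc),
    mean_time = tim,
    sd_time = vapply(summaries, function(s) s$sd_time, numeric(1)),
    time_delta = tim - mean(tim),
    stringsAsFactors = FALSE)
  class(out) <- c("comparison_table", "data.frame")
  out
}
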