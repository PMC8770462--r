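#' Configuration of the wrapper fitness evaluation
#'
#' Bundles everything needed to score a feature subset: the stratified
#' 80/20 split, the LM training schedule, the number of random restarts
#' (best network by training MSE is kept) and the decision threshold
#' applied to the sigmoid output.
#'
#' @param split a [split_spec()].
#' @param train a [train_config()].
#' @param n_restarts networks trained per evaluation, `>= 1`. Default 3.
#' @param decision_threshold classify as patient when output `>=` this.
#'   Default 0.5.
#' @return List of class `eval_config`.
#' @export
eval_config <- function(split = split_spec(), train = train_config(),
                        n_restarts = 3L, decision_threshold = 0.5) {
  stopifnot(inherits(split, "split_spec"), inherits(train, "train_config"),
            is_count(n_restarts, 1L), is_prob(decision_threshold))
  structure(list(split = split, train = train,
                 n_restarts = as.integer(n_restarts),
                 decision_threshold = decision_threshold),
            class = "eval_config")
}

fitness_record <- function(error, accuracy, size, train_mse = NA_real_) {
  structure(list(error = error, accuracy = accuracy, size = as.integer(size),
                 train_mse = train_mse),
            class = "fitness_record")
}

#' @export
print.fitness_record <- function(x, ...) {
  cat(sprintf("<fitness_record> error %.4f, accuracy %.4f, %d features\n",
              x$error, x$accuracy, x$size))
  invisible(x)
}

#' Score a feature subset with the MLP wrapper
#'
#' The fitness every selector optimises. Restricts the table to the masked
#' columns, standardizes on the training split only, trains `n_restarts`
#' LM networks (keeping the best by training MSE), classifies the held-out
#' validation subjects at the decision threshold and returns validation
#' accuracy, classification error `1 - accuracy` and subset size. Fully
#' determined by the inputs and the seeds inside `cfg`. The empty subset is
#' assigned the sentinel worst fitness (error 1, accuracy 0).
#'
#' @param table a [feature_table()].
#' @param labels a [cohort_labels()].
#' @param mask logical (or 0/1) vector over features.
#' @param cfg an [eval_config()].
#' @return A `fitness_record`.
#' @export
evaluate_subset <- function(table, labels, mask, cfg = eval_config()) {
  stopifnot(inherits(table, "feature_table"), inherits(cfg, "eval_config"))
  labels <- cohort_labels(labels)
  mask <- as.logical(mask)
  if (length(mask) != ncol(table$values) || anyNA(mask)) {
    stop_named("evoselect_bad_mask", "mask length must equal feature count")
  }
  k <- sum(mask)
  if (k == 0L) return(fitness_record(1, 0, 0L))
  split <- stratified_split(labels, cfg$split)
  sub <- feature_table(table$values[, mask, drop = FALSE],
                       table$subject_ids, table$feature_names[mask])
  std <- suppressWarnings(standardize(sub, split$train))
  x_tr <- std$values[split$train, , drop = FALSE]
  y_tr <- as.numeric(unclass(labels)[split$train])
  x_va <- std$values[split$validation, , drop = FALSE]
  y_va <- as.integer(unclass(labels)[split$validation])
  best <- NULL
  for (r in seq_len(cfg$n_restarts)) {
    net <- mlp_init(k, seed = derive_seed(cfg$train$seed, r))
    fit <- train_lmbp(net, x_tr, y_tr, cfg$train)
    if (is.null(best) || fit$mse < best$mse) best <- fit
  }
  out <- mlp_forward(best$state, x_va)$outputs
  pred <- as.integer(out >= cfg$decision_threshold)
  acc <- mean(pred == y_va)
  fitness_record(1 - acc, acc, k, best$mse)
}

#' Cached subset evaluator
#'
#' Closes over a cohort and an [eval_config()] and memoises
#' [evaluate_subset()] results by mask (the split and training seeds are
#' fixed by `cfg`), so evolutionary runs never retrain an already-scored
#' subset. Used internally by all selectors.
#'
#' @inheritParams evaluate_subset
#' @return A function `(mask) -> fitness_record` with attributes readable
#'   through [evaluator_stats()].
#' @export
make_subset_evaluator <- function(table, labels, cfg = eval_config()) {
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L; n_call <- 0L
  f <- function(mask) {
    key <- mask_key(mask)
    n_call <<- n_call + 1L
    if (!is.null(cache[[key]])) return(cache[[key]])
    n_eval <<- n_eval + 1L
    rec <- evaluate_subset(table, labels, mask, cfg)
    cache[[key]] <- rec
    rec
  }
  attr(f, "stats") <- function() list(evaluations = n_eval, calls = n_call)
  f
}

#' Evaluation counts of a cached evaluator
#' @param evaluator a [make_subset_evaluator()] closure.
#' @return List: `evaluations` (cache misses, i.e. networks trained) and
#'   `calls` (total fitness queries).
#' @export
evaluator_stats <- function(evaluator) attr(evaluator, "stats")()
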