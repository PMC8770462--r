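#' Two-sample Mann-Whitney rank-sum test
#'
#' The non-parametric two-sample location test used as the univariate
#' screen. For combined sample sizes up to `exact_max` the two-sided p-value
#' is computed by exact enumeration of all group assignments of the pooled
#' ranks (tie-safe); larger samples use the normal approximation with tie
#' correction and continuity correction. Two-sided p is
#' `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#'
#' @param group_a,group_b numeric vectors, each non-empty.
#' @param exact_max enumeration cutoff on the combined sample size.
#'   Default 12.
#' @return List of class `ranksum_result`: `statistic` (the Mann-Whitney U
#'   of `group_a`), `p_value`, `method` (`"exact"` or `"normal"`).
#' @examples
#' ranksum_test(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1
#' @export
ranksum_test <- function(group_a, group_b, exact_max = 12L) {
  if (length(group_a) < 1L || length(group_b) < 1L) {
    stop_named("evoselect_empty_group", "both groups must be non-empty")
  }
  if (anyNA(group_a) || anyNA(group_b)) {
    stop_named("evoselect_missing_values", "groups must not contain NA")
  }
  n1 <- length(group_a); n2 <- length(group_b); n <- n1 + n2
  r <- rank(c(group_a, group_b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n <= exact_max) {
    ## enumerate every assignment of n1 pooled ranks to group A
    combs <- utils::combn(n, n1)
    u_all <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p_lo <- mean(u_all <= u + eps)
    p_hi <- mean(u_all >= u - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      zd <- u - mu
      z <- (zd - sign(zd) * 0.5) / sqrt(sigma2)  # continuity correction
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  structure(list(statistic = u, p_value = p, method = method),
            class = "ranksum_result")
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up procedure at level `q`: sort p-values ascending, find the largest
#' `i` with `p_(i) <= (i/m) q`, declare the first `i` significant. Adjusted
#' p-values are the usual monotone BH values
#' `min_k>=i (m/k) p_(k)` capped at 1.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param q FDR level in `(0, 1)`. Default 0.05.
#' @return List: `significant` (logical mask), `adjusted` (numeric vector),
#'   `q`.
#' @export
fdr_adjust <- function(p_values, q = 0.05) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1) {
    stop_named("evoselect_bad_q", "q must lie strictly inside (0, 1)")
  }
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop_named("evoselect_bad_p", "p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  o <- order(p_values)
  ps <- p_values[o]
  thresholds <- q * seq_len(m) / m
  below <- which(ps <= thresholds)
  n_sig <- if (length(below)) max(below) else 0L
  significant <- logical(m)
  if (n_sig > 0L) significant[o[seq_len(n_sig)]] <- TRUE
  adj_sorted <- rev(cummin(rev(ps * m / seq_len(m))))
  adjusted <- numeric(m)
  adjusted[o] <- pmin(1, adj_sorted)
  list(significant = significant, adjusted = adjusted, q = q)
}

#' Per-feature rank-sum screen with FDR correction
#'
#' Applies [ranksum_test()] to every feature and [fdr_adjust()] across the
#' resulting p-value vector — the statistical comparison used to rank
#' features and to count group-discriminating parameters.
#'
#' @param table a [feature_table].
#' @param labels a [cohort_labels].
#' @param q FDR level. Default 0.05.
#' @return `data.frame` with columns `feature`, `statistic`, `p_value`,
#'   `adjusted_p`, `significant`; rows in original feature order.
#' @export
feature_screen <- function(table, labels, q = 0.05) {
  stopifnot(inherits(table, "feature_table"))
  labels <- cohort_labels(labels)
  a <- unclass(labels) == 0L
  res <- apply(table$values, 2, function(v) {
    t <- ranksum_test(v[a], v[!a])
    c(t$statistic, t$p_value)
  })
  fdr <- fdr_adjust(res[2, ], q = q)
  data.frame(feature = table$feature_names,
             statistic = res[1, ], p_value = res[2, ],
             adjusted_p = fdr$adjusted, significant = fdr$significant,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Accuracy of p-value-ranked feature panels
#'
#' The statistical baseline: features are sorted by ascending rank-sum
#' p-value (ties broken by original column order), and for each panel size
#' `k` the top-`k` panel is scored with the MLP wrapper evaluator
#' ([evaluate_subset()]), averaging validation accuracy over `n_repeats`
#' seeded splits.
#'
#' @param table a [feature_table].
#' @param labels a [cohort_labels].
#' @param k_values increasing vector of panel sizes, each `<= p`. Default
#'   `1:k_max` is obtained by passing `k_values = seq_len(k_max)`.
#' @param eval_cfg an [eval_config()]; its split/train seeds are re-derived
#'   per repeat from `seed`.
#' @param n_repeats number of repeated splits averaged per `k`. Default 5.
#' @param seed master seed for the repeats.
#' @return List of class `accuracy_curve`: `k_values`, `accuracy` (mean),
#'   `sd`, `n_repeats`, `ranking` (feature order used).
#' @export
pvalue_ranked_accuracy_curve <- function(table, labels, k_values,
                                         eval_cfg = eval_config(),
                                         n_repeats = 5L, seed = 1L) {
  stopifnot(inherits(table, "feature_table"), is_count(n_repeats, 1L))
  labels <- cohort_labels(labels)
  p <- ncol(table$values)
  k_values <- as.integer(k_values)
  if (any(k_values < 1L) || any(k_values > p) || is.unsorted(k_values)) {
    stop_named("evoselect_bad_k", "k_values must be increasing and within 1..p")
  }
  screen <- feature_screen(table, labels)
  ord <- order(screen$p_value)           # stable: ties keep column order
  acc <- matrix(NA_real_, length(k_values), n_repeats)
  for (r in seq_len(n_repeats)) {
    cfg_r <- eval_cfg
    cfg_r$split$seed <- derive_seed(seed, 1000L + r)
    cfg_r$train$seed <- derive_seed(seed, 2000L + r)
    for (i in seq_along(k_values)) {
      mask <- logical(p)
      mask[ord[seq_len(k_values[i])]] <- TRUE
      acc[i, r] <- evaluate_subset(table, labels, mask, cfg_r)$accuracy
    }
  }
  structure(list(k_values = k_values,
                 accuracy = rowMeans(acc),
                 sd = apply(acc, 1, stats::sd),
                 n_repeats = n_repeats,
                 ranking = table$feature_names[ord]),
            class = "accuracy_curve")
}

#' @export
print.accuracy_curve <- function(x, ...) {
  cat(sprintf("<accuracy_curve> %d panel sizes, best %.3f at k = %d (%d repeats)\n",
              length(x$k_values), max(x$accuracy),
              x$k_values[which.max(x$accuracy)], x$n_repeats))
  invisible(x)
}
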