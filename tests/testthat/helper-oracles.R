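## Independent oracles and fixture builders shared across tests.

## O(N^3) brute-force nondominated sorting: repeatedly strip the set of
## solutions not dominated by any survivor. Kept deliberately naive and
## separate from the package's Deb-style sweep.
oracle_nondominated_sort <- function(obj) {
  obj <- as.matrix(obj)
  remaining <- seq_len(nrow(obj))
  fronts <- list()
  while (length(remaining)) {
    nd <- remaining[vapply(remaining, function(i) {
      !any(vapply(remaining, function(j) {
        i != j && all(obj[j, ] <= obj[i, ]) && any(obj[j, ] < obj[i, ])
      }, logical(1)))
    }, logical(1))]
    fronts[[length(fronts) + 1L]] <- sort(nd)
    remaining <- setdiff(remaining, nd)
  }
  fronts
}

## Exact two-sided rank-sum p by explicit enumeration over value
## reassignments (not rank combinations) — an independent route from the
## package's combn-over-ranks implementation.
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  n <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx_sets <- utils::combn(n, n1)
  mu <- n1 * (n - n1) / 2
  us <- apply(idx_sets, 2, function(ix) sum(rank(pooled)[ix]) - n1 * (n1 + 1) / 2)
  eps <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
}

## Central finite-difference Jacobian of e(x) = targets - output(x).
oracle_fd_jacobian <- function(state, X, targets, h = 1e-6) {
  x0 <- mlp_get_params(state)
  vapply(seq_along(x0), function(j) {
    xp <- x0; xp[j] <- xp[j] + h
    xm <- x0; xm[j] <- xm[j] - h
    ep <- targets - mlp_forward(mlp_set_params(state, xp), X)$outputs
    em <- targets - mlp_forward(mlp_set_params(state, xm), X)$outputs
    (ep - em) / (2 * h)
  }, numeric(nrow(X)))
}

## Tiny cohort whose first feature separates the classes perfectly and
## whose remaining p - 1 features are pure noise.
make_separable_cohort <- function(n_per_class = 20L, p = 8L, seed = 42L,
                                  gap = 4) {
  withr_seed <- function(s, expr) { set.seed(s); expr }
  withr_seed(seed, {
    n <- 2L * n_per_class
    labels <- rep(c(0L, 1L), each = n_per_class)
    x <- matrix(rlnorm(n * p), n, p)
    x[, 1] <- exp(rnorm(n, mean = ifelse(labels == 1L, -gap / 2, gap / 2),
                        sd = 0.3))
    tab <- feature_table(x, feature_names = sprintf("f%02d", seq_len(p)))
    list(table = tab, labels = cohort_labels(labels))
  })
}

## Fast, deterministic eval config for toy problems.
toy_eval_cfg <- function(seed = 7L, iterations = 25L, restarts = 1L) {
  eval_config(split = split_spec(seed = derive_seed(seed, 1L)),
              train = train_config(max_iterations = iterations,
                                   seed = derive_seed(seed, 2L)),
              n_restarts = restarts)
}
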