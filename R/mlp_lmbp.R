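## Multilayer perceptron with Levenberg-Marquardt backpropagation.
##
## The network state keeps per-layer weight matrices/bias vectors plus a flat
## parameter view x (all weights and biases, layer by layer, weights
## column-major then biases). Training minimises the performance index
## F(x) = e'(x) e(x) over the per-case error vector e = target - output via
## damped Gauss-Newton steps x <- x - (J'J + mu I)^{-1} J'e, with the
## Jacobian assembled from sensitivities backpropagated layer to layer.

act_fun <- function(name) {
  switch(name,
         tanh = list(f = tanh, d = function(a, n) 1 - a^2),
         sigmoid = list(f = function(n) 1 / (1 + exp(-n)),
                        d = function(a, n) a * (1 - a)),
         linear = list(f = identity, d = function(a, n) rep(1, length(a))),
         stop_named("evoselect_bad_activation",
                    paste0("unknown activation: ", name)))
}

#' Initialize a multilayer perceptron for binary classification
#'
#' Default topology is `input_dim`-20-10-5-1: three fully-connected hidden
#' layers of 20, 10 and 5 tanh units and a single sigmoid output unit read
#' against a 0.5 threshold. Weights and biases are drawn uniformly in
#' `+-1/sqrt(fan-in)`, seeded.
#'
#' @param input_dim number of input features, `>= 1`.
#' @param hidden integer vector of hidden layer sizes. Default `c(20, 10, 5)`.
#' @param seed RNG seed for the weight draw.
#' @param hidden_activation,output_activation activation names among
#'   `"tanh"`, `"sigmoid"`, `"linear"`.
#' @return Object of class `mlp_state`: `layer_sizes`, weight list `W`,
#'   bias list `b`, activation names, and `n_params`.
#' @export
mlp_init <- function(input_dim, hidden = c(20L, 10L, 5L), seed = 1L,
                     hidden_activation = "tanh",
                     output_activation = "sigmoid") {
  if (!is_count(input_dim, 1L)) {
    stop_named("evoselect_bad_input_dim", "input_dim must be >= 1")
  }
  sizes <- c(as.integer(input_dim), as.integer(hidden), 1L)
  L <- length(sizes) - 1L
  acts <- c(rep(hidden_activation, L - 1L), output_activation)
  with_seed(seed, {
    W <- vector("list", L); b <- vector("list", L)
    for (m in seq_len(L)) {
      fan_in <- sizes[m]
      lim <- 1 / sqrt(fan_in)
      W[[m]] <- matrix(stats::runif(sizes[m + 1] * fan_in, -lim, lim),
                       sizes[m + 1], fan_in)
      b[[m]] <- stats::runif(sizes[m + 1], -lim, lim)
    }
    structure(list(layer_sizes = sizes, W = W, b = b, activations = acts,
                   n_params = sum(sizes[-1] * (sizes[-length(sizes)] + 1L))),
              class = "mlp_state")
  })
}

#' @export
print.mlp_state <- function(x, ...) {
  cat(sprintf("<mlp_state> %s (%d parameters)\n",
              paste(x$layer_sizes, collapse = "-"), x$n_params))
  invisible(x)
}

#' Flat parameter vector of a network
#'
#' Layer by layer: weights (column-major), then biases — the vector `x`
#' that the LM update acts on.
#' @param state an [mlp_init()] state.
#' @return Numeric vector of length `state$n_params`.
#' @export
mlp_get_params <- function(state) {
  unlist(lapply(seq_along(state$W),
                function(m) c(as.numeric(state$W[[m]]), state$b[[m]])),
         use.names = FALSE)
}

#' Replace a network's parameters from a flat vector
#' @param state an `mlp_state`.
#' @param x flat vector as produced by [mlp_get_params()].
#' @return The updated `mlp_state`.
#' @export
mlp_set_params <- function(state, x) {
  if (length(x) != state$n_params || !all(is.finite(x))) {
    stop_named("evoselect_bad_params",
               "parameter vector has wrong length or non-finite entries")
  }
  pos <- 0L
  for (m in seq_along(state$W)) {
    nw <- length(state$W[[m]]); nb <- length(state$b[[m]])
    state$W[[m]][] <- x[pos + seq_len(nw)]
    state$b[[m]] <- x[pos + nw + seq_len(nb)]
    pos <- pos + nw + nb
  }
  state
}

#' Forward pass with cached layer activations
#'
#' Propagates the input forward through the network, caching each layer's
#' net input `n_m` and activation `a_m` as needed for Jacobian assembly.
#'
#' @param state an `mlp_state`.
#' @param inputs cases-by-features numeric matrix (or vector for one case).
#' @return List: `outputs` (one value per case), `cache` (lists `A` of
#'   activations, index 1 = input, and `N` of net inputs).
#' @export
mlp_forward <- function(state, inputs) {
  if (is.vector(inputs)) inputs <- matrix(inputs, nrow = 1)
  if (ncol(inputs) != state$layer_sizes[1]) {
    stop_named("evoselect_dim_mismatch",
               sprintf("input width %d != network input size %d",
                       ncol(inputs), state$layer_sizes[1]))
  }
  L <- length(state$W)
  A <- vector("list", L + 1L); N <- vector("list", L)
  A[[1]] <- t(inputs)                       # features x cases
  for (m in seq_len(L)) {
    N[[m]] <- state$W[[m]] %*% A[[m]] + state$b[[m]]
    A[[m + 1L]] <- act_fun(state$activations[m])$f(N[[m]])
  }
  list(outputs = as.numeric(A[[L + 1L]]), cache = list(A = A, N = N))
}

#' Error vector and analytic Jacobian for the LM update
#'
#' For errors `e_i = target_i - output_i`, assembles the Jacobian
#' `J[i, j] = d e_i / d x_j` column-block by layer from the backpropagated
#' sensitivities `S^m = F'^m(n^m) (w^{m+1})' S^{m+1}` combined with the
#' previous layer's activations (`J = S^m a^{m-1}` blockwise).
#'
#' @param state an `mlp_state`.
#' @param fwd result of [mlp_forward()] on the training inputs.
#' @param targets numeric target vector, one per case.
#' @return List of class `lm_work`: `x` (current flat parameters), `J`
#'   (cases x n_params), `e`, `mu` (initialised to `NA`, set by the
#'   trainer).
#' @export
mlp_jacobian <- function(state, fwd, targets) {
  L <- length(state$W)
  A <- fwd$cache$A; N <- fwd$cache$N
  if (is.null(A) || length(fwd$outputs) != length(targets)) {
    stop_named("evoselect_stale_cache",
               "forward cache missing or does not match targets")
  }
  n_cases <- length(targets)
  e <- as.numeric(targets) - fwd$outputs
  ## output sensitivity d out / d n_L, then backward recursion
  S <- vector("list", L)
  dact <- act_fun(state$activations[L])$d
  S[[L]] <- matrix(dact(A[[L + 1L]], N[[L]]), 1L, n_cases)
  if (L > 1L) {
    for (m in seq(L - 1L, 1L)) {
      da <- act_fun(state$activations[m])$d(A[[m + 1L]], N[[m]])
      S[[m]] <- matrix(da, nrow(N[[m]]), n_cases) *
        (t(state$W[[m + 1L]]) %*% S[[m + 1L]])
    }
  }
  ## assemble J transposed (params x cases) into one preallocated matrix,
  ## then transpose once — cheaper than per-block cbind/t()
  Jt <- matrix(0, state$n_params, n_cases)
  pos <- 0L
  for (m in seq_len(L)) {
    U <- nrow(state$W[[m]]); V <- ncol(state$W[[m]])
    Sm <- S[[m]]
    ## weight block, column-major over (u, v): de/dW[u,v] = -S[u,] * A[v,]
    Jt[pos + seq_len(U * V), ] <-
      -(Sm[rep(seq_len(U), times = V), , drop = FALSE] *
          A[[m]][rep(seq_len(V), each = U), , drop = FALSE])
    Jt[pos + U * V + seq_len(U), ] <- -Sm   # bias block
    pos <- pos + U * V + U
  }
  structure(list(x = mlp_get_params(state), J = t(Jt),
                 e = e, mu = NA_real_),
            class = "lm_work")
}

#' One damped Gauss-Newton (Levenberg-Marquardt) parameter update
#'
#' Returns `x - (J'J + mu I)^{-1} J'e` via a stable linear solve. When
#' there are fewer error rows than parameters the algebraically identical
#' dual form `x - J'(JJ' + mu I)^{-1} e` is solved instead, which keeps the
#' system at cases-by-cases size.
#'
#' @param work an `lm_work` list with finite `x`, `J`, `e` and `mu > 0`.
#' @return Candidate flat parameter vector.
#' @export
lm_step <- function(work) {
  x <- work$x; J <- work$J; e <- work$e; mu <- work$mu
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0) {
    stop_named("evoselect_bad_mu", "mu must be a positive finite scalar")
  }
  if (!is.finite(sum(J)) || !is.finite(sum(e))) {
    stop_named("evoselect_nonfinite", "non-finite Jacobian or error vector")
  }
  n <- nrow(J); P <- ncol(J)
  step <- if (n >= P) {
    H <- crossprod(J)
    solve(H + diag(mu, P), crossprod(J, e))
  } else {
    crossprod(J, solve(tcrossprod(J) + diag(mu, n), e))
  }
  as.numeric(x - step)
}

#' Training configuration for Levenberg-Marquardt backpropagation
#'
#' The damping schedule is the canonical one: accept a step when the
#' performance index decreases (then `mu <- mu / mu_decrease`), otherwise
#' reject and retry with `mu <- mu * mu_increase`, giving up when `mu`
#' exceeds `mu_max`.
#'
#' @param max_iterations accepted-step budget. Default 100.
#' @param mu_init initial damping. Default 1e-3.
#' @param mu_increase,mu_decrease damping factors, both `> 1`. Default 10.
#' @param mu_max damping ceiling terminating training. Default 1e10.
#' @param goal_mse stop once training MSE falls to this level. Default 1e-8.
#' @param seed seed used by callers that re-initialise networks.
#' @return List of class `train_config`.
#' @export
train_config <- function(max_iterations = 100L, mu_init = 1e-3,
                         mu_increase = 10, mu_decrease = 10,
                         mu_max = 1e10, goal_mse = 1e-8, seed = 1L) {
  stopifnot(is_count(max_iterations, 0L), mu_init > 0,
            mu_increase > 1, mu_decrease > 1, mu_max > mu_init,
            goal_mse >= 0)
  structure(list(max_iterations = as.integer(max_iterations),
                 mu_init = mu_init, mu_increase = mu_increase,
                 mu_decrease = mu_decrease, mu_max = mu_max,
                 goal_mse = goal_mse, seed = as.integer(seed)),
            class = "train_config")
}

#' Train a network by Levenberg-Marquardt backpropagation
#'
#' Full LMBP loop: forward pass, backward sensitivity propagation to build
#' the Jacobian, damped Gauss-Newton update with accept/reject on the
#' performance index `F(x) = e'e`. The accepted-step `F` sequence is
#' strictly decreasing by construction. Terminates on `goal_mse`,
#' `max_iterations` accepted steps, or `mu > mu_max`.
#'
#' @param state an `mlp_state`.
#' @param inputs cases-by-features training matrix.
#' @param targets numeric targets (0/1 for classification), one per case.
#' @param cfg a [train_config()].
#' @return List: `state` (trained), `history` (data.frame: `iteration`,
#'   `mse`, `mu`, `accepted`), `mse` (final), `iterations` (accepted steps),
#'   `stopped` (one of `"goal"`, `"max_iterations"`, `"mu_max"`).
#' @export
train_lmbp <- function(state, inputs, targets, cfg = train_config()) {
  if (is.vector(inputs)) inputs <- matrix(inputs, ncol = state$layer_sizes[1])
  if (nrow(inputs) < 1L) {
    stop_named("evoselect_no_cases", "need at least one training case")
  }
  n <- nrow(inputs)
  fwd <- mlp_forward(state, inputs)
  e <- as.numeric(targets) - fwd$outputs
  F_cur <- sum(e^2)
  if (!is.finite(F_cur)) {
    stop_named("evoselect_nonfinite", "non-finite loss at initial point")
  }
  mu <- cfg$mu_init
  hist <- list()
  it <- 0L
  stopped <- "max_iterations"
  while (it < cfg$max_iterations) {
    if (F_cur / n <= cfg$goal_mse) { stopped <- "goal"; break }
    work <- mlp_jacobian(state, fwd, targets)
    ## hoist the Gram matrix out of the mu-retry loop; retries re-solve only
    J <- work$J; x_cur <- work$x; e_cur <- work$e
    n_rows <- nrow(J); P <- ncol(J)
    dual <- n_rows < P
    if (dual) {
      JJt <- tcrossprod(J)
    } else {
      H <- crossprod(J); G <- crossprod(J, e_cur)
    }
    accepted <- FALSE
    while (!accepted) {
      cand <- if (dual) {
        as.numeric(x_cur - crossprod(J, solve(JJt + diag(mu, n_rows), e_cur)))
      } else {
        as.numeric(x_cur - solve(H + diag(mu, P), G))
      }
      cand_state <- tryCatch(mlp_set_params(state, cand), error = function(e) NULL)
      if (!is.null(cand_state)) {
        fwd2 <- mlp_forward(cand_state, inputs)
        e2 <- as.numeric(targets) - fwd2$outputs
        F_new <- sum(e2^2)
      } else F_new <- Inf
      if (is.finite(F_new) && F_new < F_cur) {
        state <- cand_state; fwd <- fwd2; F_cur <- F_new
        mu <- mu / cfg$mu_decrease
        accepted <- TRUE
      } else {
        mu <- mu * cfg$mu_increase
        if (mu > cfg$mu_max) break
      }
    }
    if (!accepted) { stopped <- "mu_max"; break }
    it <- it + 1L
    hist[[it]] <- c(iteration = it, mse = F_cur / n, mu = mu, accepted = 1)
  }
  if (stopped == "max_iterations" && F_cur / n <= cfg$goal_mse) stopped <- "goal"
  history <- if (length(hist)) {
    as.data.frame(do.call(rbind, hist))
  } else {
    data.frame(iteration = numeric(0), mse = numeric(0), mu = numeric(0),
               accepted = numeric(0))
  }
  list(state = state, history = history, mse = F_cur / n,
       iterations = it, stopped = stopped)
}
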