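test_that("topology arithmetic, seeding and preconditions", {
  net <- mlp_init(10, seed = 1)
  ## (10*20+20)+(20*10+10)+(10*5+5)+(5*1+1)
  expect_equal(net$n_params, 491L)
  expect_length(mlp_get_params(net), 491L)
  expect_identical(mlp_get_params(mlp_init(10, seed = 1)),
                   mlp_get_params(net))
  expect_false(identical(mlp_get_params(mlp_init(10, seed = 2)),
                         mlp_get_params(net)))
  expect_error(mlp_init(0), class = "evoselect_bad_input_dim")
})

test_that("forward pass: zero network, affine neuron, dimension checks", {
  net <- mlp_init(3, hidden = c(4, 2), seed = 1)
  net <- mlp_set_params(net, rep(0, net$n_params))
  out <- mlp_forward(net, matrix(rnorm(15), 5, 3))$outputs
  expect_equal(out, rep(0.5, 5))   # sigmoid(0) through zeroed layers

  lin <- mlp_init(1, hidden = integer(0), output_activation = "linear",
                  seed = 1)
  lin <- mlp_set_params(lin, c(2, 1))    # weight 2, bias 1
  expect_equal(mlp_forward(lin, matrix(3, 1, 1))$outputs, 7)

  expect_error(mlp_forward(net, matrix(0, 2, 5)),
               class = "evoselect_dim_mismatch")
})

test_that("analytic Jacobian: hand case, FD oracle, zero-input structure", {
  ## single linear neuron, e = t - (w x + b): de/dw = -x, de/db = -1
  lin <- mlp_init(1, hidden = integer(0), output_activation = "linear",
                  seed = 3)
  fwd <- mlp_forward(lin, matrix(3, 1, 1))
  work <- mlp_jacobian(lin, fwd, targets = 10)
  expect_equal(unname(work$J), matrix(c(-3, -1), 1, 2))

  ## FD oracle on a random 5-3-2-1 network, 4 cases
  set.seed(13)
  net <- mlp_init(5, hidden = c(3, 2), seed = 13)
  X <- matrix(rnorm(20), 4, 5)
  y <- sample(0:1, 4, replace = TRUE)
  fwd <- mlp_forward(net, X)
  J <- mlp_jacobian(net, fwd, y)$J
  expect_lt(max(abs(J - oracle_fd_jacobian(net, X, y))), 1e-5)

  ## zero input: first-layer weight columns zero, bias columns not
  fwd0 <- mlp_forward(net, matrix(0, 1, 5))
  J0 <- mlp_jacobian(net, fwd0, 1)$J
  w1_cols <- seq_len(5 * 3)            # layer-1 weights come first
  b1_cols <- 5 * 3 + seq_len(3)
  expect_true(all(J0[, w1_cols] == 0))
  expect_true(all(J0[, b1_cols] != 0))

  expect_error(mlp_jacobian(net, list(outputs = 1, cache = NULL), c(1, 0)),
               class = "evoselect_stale_cache")
})

test_that("Jacobian matches finite differences over random small topologies (property)", {
  set.seed(14)
  worst <- 0
  for (i in 1:50) {
    d <- sample(2:5, 1)
    hidden <- sample(2:4, sample(1:2, 1), replace = TRUE)
    outact <- sample(c("sigmoid", "linear", "tanh"), 1)
    net <- mlp_init(d, hidden = hidden, seed = i, output_activation = outact)
    n_cases <- sample(1:5, 1)
    X <- matrix(rnorm(n_cases * d), n_cases, d)
    y <- runif(n_cases)
    J <- mlp_jacobian(net, mlp_forward(net, X), y)$J
    worst <- max(worst, max(abs(J - oracle_fd_jacobian(net, X, y))))
  }
  expect_lt(worst, 1e-4)
})

test_that("LM step: fixed point, closed-form limit, damped-gradient limit, dual path", {
  lin <- mlp_init(1, hidden = integer(0), output_activation = "linear",
                  seed = 5)
  X <- matrix(c(-1, 0, 1, 2), 4, 1)
  y <- 2 * X[, 1] + 1
  fwd <- mlp_forward(lin, X)
  work <- mlp_jacobian(lin, fwd, y)

  ## mu -> 0 is exact Gauss-Newton = least squares for a linear model
  work$mu <- 1e-12
  expect_equal(lm_step(work), c(2, 1), tolerance = 1e-6)

  ## e = 0: no movement
  solved <- mlp_set_params(lin, c(2, 1))
  w0 <- mlp_jacobian(solved, mlp_forward(solved, X), y)
  w0$mu <- 1
  expect_equal(lm_step(w0), c(2, 1), tolerance = 1e-12)

  ## mu huge: step tends to G / mu
  work$mu <- 1e9
  G <- crossprod(work$J, work$e)
  expect_equal(lm_step(work), as.numeric(work$x - G / 1e9),
               tolerance = 1e-3)

  ## dual (cases < params) and primal solves agree
  net <- mlp_init(4, hidden = c(3), seed = 6)
  Xw <- matrix(rnorm(8), 2, 4)        # 2 cases, 19 params -> dual route
  ww <- mlp_jacobian(net, mlp_forward(net, Xw), c(0, 1))
  ww$mu <- 0.37
  dual <- lm_step(ww)
  H <- crossprod(ww$J)
  primal <- as.numeric(ww$x - solve(H + diag(0.37, ncol(ww$J)),
                                    crossprod(ww$J, ww$e)))
  expect_equal(dual, primal, tolerance = 1e-8)

  work$mu <- -1
  expect_error(lm_step(work), class = "evoselect_bad_mu")
})

test_that("LMBP trainer: converged start, monotone accepted loss, history", {
  lin <- mlp_init(1, hidden = integer(0), output_activation = "linear",
                  seed = 5)
  X <- matrix(c(-1, 0, 1, 2), 4, 1)
  y <- 2 * X[, 1] + 1
  solved <- mlp_set_params(lin, c(2, 1))
  tr0 <- train_lmbp(solved, X, y, train_config(max_iterations = 50))
  expect_equal(tr0$iterations, 0L)
  expect_equal(tr0$stopped, "goal")

  set.seed(15)
  for (s in 1:5) {
    net <- mlp_init(3, hidden = c(4, 2), seed = s)
    Xs <- matrix(rnorm(30), 10, 3)
    ys <- as.numeric(runif(10) < 0.5)
    tr <- train_lmbp(net, Xs, ys, train_config(max_iterations = 30, seed = s))
    expect_true(all(diff(tr$history$mse) < 0))   # strictly decreasing
    if (tr$iterations > 0) expect_equal(tr$mse, tail(tr$history$mse, 1))
  }
})

test_that("evaluate_subset: sentinel, separable feature, determinism", {
  coh <- make_separable_cohort(n_per_class = 15L, p = 5L, seed = 16L)
  cfg <- toy_eval_cfg(9L)

  empty <- evaluate_subset(coh$table, coh$labels, rep(FALSE, 5), cfg)
  expect_equal(empty$error, 1)
  expect_equal(empty$size, 0L)

  mask <- c(TRUE, rep(FALSE, 4))
  rec <- evaluate_subset(coh$table, coh$labels, mask, cfg)
  expect_equal(rec$accuracy, 1.0)
  expect_equal(rec$size, 1L)
  expect_equal(rec$error + rec$accuracy, 1)

  rec2 <- evaluate_subset(coh$table, coh$labels, mask, cfg)
  expect_identical(rec, rec2)

  expect_error(evaluate_subset(coh$table, coh$labels, c(TRUE, FALSE), cfg),
               class = "evoselect_bad_mask")
})

test_that("cached evaluator never retrains a repeated mask", {
  coh <- make_separable_cohort(n_per_class = 10L, p = 4L, seed = 17L)
  ev <- make_subset_evaluator(coh$table, coh$labels, toy_eval_cfg(2L))
  m <- c(TRUE, TRUE, FALSE, FALSE)
  r1 <- ev(m); r2 <- ev(m); r3 <- ev(!m)
  expect_identical(r1, r2)
  st <- evaluator_stats(ev)
  expect_equal(st$calls, 3L)
  expect_equal(st$evaluations, 2L)
})
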