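## Shared toy problem: feature 1 separates perfectly, lambda = 0 reduces the
## scalar fitness to pure classification error.

toy <- make_separable_cohort(n_per_class = 12L, p = 6L, seed = 35L)

run_method <- function(method, seed, iterations, lambda = 0.01,
                       pop_size = 10L) {
  cfg <- metaheuristic_config(method, pop_size = pop_size,
                              iterations = iterations, lambda = lambda,
                              seed = seed)
  run_selector(method, toy$table, toy$labels, toy_eval_cfg(8L), cfg)
}

test_that("all four methods: monotone trajectory, determinism, budget bookkeeping", {
  for (method in c("ga", "aco", "sa", "pso")) {
    iters <- if (method == "sa") 40L else 4L
    r1 <- run_method(method, seed = 5L, iterations = iters)
    r2 <- run_method(method, seed = 5L, iterations = iters)
    expect_true(all(diff(r1$trajectory) <= 0), info = method)
    expect_equal(r1$best_fitness, tail(r1$trajectory, 1), info = method)
    expect_identical(r1$best_mask, r2$best_mask, info = method)
    expect_identical(r1$trajectory, r2$trajectory, info = method)
    ## total fitness queries match the configured budget
    expected_calls <- switch(method,
                             ga = 10L + 10L * iters,
                             aco = 10L * iters,
                             sa = 1L + iters,
                             pso = 10L + 10L * iters)
    expect_equal(r1$fitness_calls, expected_calls, info = method)
  }
})

test_that("GA finds the separating feature on the toy problem", {
  hits <- 0L
  for (s in 1:6) {
    r <- run_method("ga", seed = s, iterations = 6L, lambda = 0)
    if (r$best_fitness == 0) hits <- hits + 1L
  }
  expect_gte(hits, 5L)
})

test_that("GA with a degenerate identical population and one iteration returns that mask", {
  mask <- c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  cfg <- metaheuristic_config("ga", pop_size = 4L, iterations = 1L,
                              crossover_rate = 0, mutation_rate = 0,
                              lambda = 0.01, seed = 2L)
  r <- ga_run(toy$table, toy$labels, toy_eval_cfg(8L), cfg,
              init_population = rep(list(mask), 4L))
  expect_identical(r$best_mask, mask)
  rec <- evaluate_subset(toy$table, toy$labels, mask, toy_eval_cfg(8L))
  expect_equal(r$best_fitness, rec$error + 0.01 * 2 / 6)
})

test_that("ACO: pheromones clamped; separating feature accumulates pheromone", {
  r <- run_method("aco", seed = 3L, iterations = 8L, lambda = 0)
  expect_true(all(r$pheromones >= 0.05 & r$pheromones <= 0.95))

  above <- 0L
  for (s in 1:6) {
    r <- run_method("aco", seed = s, iterations = 8L, lambda = 0)
    if (r$pheromones[1] > mean(r$pheromones)) above <- above + 1L
  }
  expect_gte(above, 5L)
})

test_that("ACO identity dynamics: no evaporation and an empty colony leave pheromones unchanged", {
  cfg <- metaheuristic_config("aco", pop_size = 0L, iterations = 3L,
                              evaporation = 0, seed = 1L)
  r <- aco_run(toy$table, toy$labels, toy_eval_cfg(8L), cfg)
  expect_equal(r$pheromones, rep(0.5, 6))
  expect_equal(r$evaluation_count, 0L)
})

test_that("SA: zero temperature is strict hill-climbing; finds the optimum", {
  cfg <- metaheuristic_config("sa", iterations = 60L, t_init = 0,
                              cooling = 0, lambda = 0, seed = 4L)
  r <- sa_run(toy$table, toy$labels, toy_eval_cfg(8L), cfg)
  expect_true(all(diff(r$trajectory) <= 0))

  hits <- 0L
  for (s in 1:6) {
    r <- run_method("sa", seed = s, iterations = 120L, lambda = 0)
    if (r$best_fitness == 0) hits <- hits + 1L
  }
  expect_gte(hits, 5L)
})

test_that("PSO: velocity clamping and toy-problem success", {
  cfg <- metaheuristic_config("pso", pop_size = 8L, iterations = 6L,
                              v_max = 2, lambda = 0, seed = 6L)
  r <- pso_run(toy$table, toy$labels, toy_eval_cfg(8L), cfg)
  expect_true(all(abs(r$velocities) <= 2))

  hits <- 0L
  for (s in 1:6) {
    r <- run_method("pso", seed = s, iterations = 6L, lambda = 0)
    if (r$best_fitness == 0) hits <- hits + 1L
  }
  expect_gte(hits, 5L)
})

test_that("run_selector validates method/config pairing", {
  expect_error(run_selector("ga", toy$table, toy$labels, toy_eval_cfg(8L),
                            metaheuristic_config("sa")),
               class = "evoselect_bad_config")
})
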