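## Canonical binary GA / ACO / SA / PSO subset selectors sharing the wrapper
## fitness, scalarised as error + lambda * n_features / p.

#' Configuration of a single-objective metaheuristic selector
#'
#' All four comparison selectors minimise the scalar fitness
#' `error + lambda * n_features / p`: classification error plus a light
#' panel-size penalty making them comparable to the two-objective NSGA-II.
#' Only the fields relevant to `algorithm` are used.
#'
#' @param algorithm one of `"ga"`, `"aco"`, `"sa"`, `"pso"`.
#' @param pop_size population / colony / swarm size. Default 25.
#' @param iterations generations (GA, ACO, PSO) or single-solution steps
#'   (SA). Defaults give each method the shared 25 x 50 evaluation budget.
#' @param lambda panel-size penalty weight, `>= 0`. Default 0.01.
#' @param crossover_rate GA: probability a selected pair is crossed.
#'   Default 0.9.
#' @param mutation_rate GA per-bit flip rate (default 0.1); also the SA-free
#'   bit-flip intensity for mutated GA children.
#' @param evaporation ACO pheromone evaporation rate in `[0, 1]`.
#'   Default 0.2.
#' @param tau_min,tau_max ACO pheromone clamp. Defaults 0.05 / 0.95.
#' @param t_init,cooling SA initial temperature (default 0.1) and geometric
#'   cooling factor in `[0, 1)` applied per step (default 0.995).
#' @param inertia,c1,c2 PSO inertia (0.7) and cognitive/social acceleration
#'   coefficients (1.5, 1.5).
#' @param v_max PSO velocity clamp. Default 4.
#' @param seed RNG seed.
#' @return List of class `metaheuristic_config`.
#' @export
metaheuristic_config <- function(algorithm = c("ga", "aco", "sa", "pso"),
                                 pop_size = 25L, iterations = NULL,
                                 lambda = 0.01,
                                 crossover_rate = 0.9, mutation_rate = 0.1,
                                 evaporation = 0.2, tau_min = 0.05,
                                 tau_max = 0.95,
                                 t_init = 0.1, cooling = 0.995,
                                 inertia = 0.7, c1 = 1.5, c2 = 1.5,
                                 v_max = 4, seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (is.null(iterations)) {
    iterations <- if (algorithm == "sa") 1250L else 50L
  }
  stopifnot(is_count(pop_size, 0L), is_count(iterations, 1L), lambda >= 0,
            is_prob(crossover_rate), is_prob(mutation_rate),
            is_prob(evaporation), tau_min >= 0, tau_max <= 1,
            tau_min < tau_max, t_init >= 0, cooling >= 0, cooling < 1,
            v_max > 0)
  structure(list(algorithm = algorithm, pop_size = as.integer(pop_size),
                 iterations = as.integer(iterations), lambda = lambda,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 evaporation = evaporation, tau_min = tau_min,
                 tau_max = tau_max, t_init = t_init, cooling = cooling,
                 inertia = inertia, c1 = c1, c2 = c2, v_max = v_max,
                 seed = as.integer(seed)),
            class = "metaheuristic_config")
}

## shared scaffolding: scalar fitness closure + result assembly
scalar_fitness <- function(evaluator, lambda, p) {
  function(mask) {
    rec <- evaluator(mask)
    rec$error + lambda * rec$size / p
  }
}

best_subset_result <- function(best_mask, best_fitness, trajectory,
                               evaluator, seed, extra = list()) {
  st <- evaluator_stats(evaluator)
  structure(c(list(best_mask = best_mask, best_fitness = best_fitness,
                   trajectory = trajectory,
                   evaluation_count = st$evaluations,
                   fitness_calls = st$calls,
                   seed = seed), extra),
            class = "best_subset_result")
}

#' @export
print.best_subset_result <- function(x, ...) {
  cat(sprintf("<best_subset_result> fitness %.4f with %d features (%d evaluations)\n",
              x$best_fitness, sum(x$best_mask), x$evaluation_count))
  invisible(x)
}

#' Genetic algorithm subset selection
#'
#' Generational GA: binary tournament selection, uniform crossover with
#' probability `crossover_rate`, per-bit mutation at `mutation_rate`,
#' elitism of one.
#'
#' @param table,labels the cohort.
#' @param eval_cfg an [eval_config()].
#' @param cfg a [metaheuristic_config()] with `algorithm = "ga"`.
#' @param init_population optional list of `pop_size` starting masks
#'   (random when `NULL`).
#' @return A `best_subset_result`: `best_mask`, `best_fitness`,
#'   best-so-far `trajectory` per iteration, `evaluation_count` (networks
#'   actually trained), `fitness_calls` (total fitness queries, i.e. the
#'   configured budget), `seed`.
#' @export
ga_run <- function(table, labels, eval_cfg = eval_config(),
                   cfg = metaheuristic_config("ga"), init_population = NULL) {
  stopifnot(cfg$algorithm == "ga")
  labels <- cohort_labels(labels)
  p <- ncol(table$values)
  evaluator <- make_subset_evaluator(table, labels, eval_cfg)
  fit <- scalar_fitness(evaluator, cfg$lambda, p)
  with_seed(cfg$seed, {
    pop <- if (is.null(init_population)) {
      lapply(seq_len(cfg$pop_size), function(i) random_mask(p))
    } else {
      stopifnot(length(init_population) == cfg$pop_size)
      lapply(init_population, as.logical)
    }
    f <- vapply(pop, fit, numeric(1))
    traj <- numeric(cfg$iterations)
    for (it in seq_len(cfg$iterations)) {
      elite <- which.min(f)
      nxt <- list(pop[[elite]])
      while (length(nxt) < cfg$pop_size) {
        pick <- function() {
          c2 <- sample(cfg$pop_size, 2L, replace = TRUE)
          c2[which.min(f[c2])]
        }
        p1 <- pop[[pick()]]; p2 <- pop[[pick()]]
        kids <- if (stats::runif(1) < cfg$crossover_rate) {
          uniform_crossover(p1, p2)
        } else list(p1, p2)
        for (k in kids) {
          flip <- stats::runif(p) < cfg$mutation_rate
          k[flip] <- !k[flip]
          if (length(nxt) < cfg$pop_size) nxt <- c(nxt, list(k))
        }
      }
      pop <- nxt
      f <- vapply(pop, fit, numeric(1))
      traj[it] <- min(min(f), if (it > 1) traj[it - 1] else Inf)
    }
    best_overall <- which.min(f)
    ## trajectory is best-so-far, so the final best may be from earlier;
    ## retained masks always include it through elitism
    best_subset_result(pop[[best_overall]], traj[cfg$iterations], traj,
                       evaluator, cfg$seed)
  })
}

#' Ant colony optimisation subset selection
#'
#' Binary ACO: one pheromone value per feature acting as its inclusion
#' probability (clamped to `[tau_min, tau_max]`). Each iteration every ant
#' samples a mask from the pheromones; after evaluation the pheromones
#' evaporate and the iteration-best ant deposits proportionally to its
#' quality `max(0, 1 - fitness)`.
#'
#' @inheritParams ga_run
#' @param cfg a [metaheuristic_config()] with `algorithm = "aco"`.
#' @return A `best_subset_result` with extra element `pheromones`.
#' @export
aco_run <- function(table, labels, eval_cfg = eval_config(),
                    cfg = metaheuristic_config("aco")) {
  stopifnot(cfg$algorithm == "aco")
  labels <- cohort_labels(labels)
  p <- ncol(table$values)
  evaluator <- make_subset_evaluator(table, labels, eval_cfg)
  fit <- scalar_fitness(evaluator, cfg$lambda, p)
  with_seed(cfg$seed, {
    tau <- rep(0.5, p)
    best_mask <- NULL; best_f <- Inf
    traj <- numeric(cfg$iterations)
    for (it in seq_len(cfg$iterations)) {
      it_best_mask <- NULL; it_best_f <- Inf
      for (a in seq_len(cfg$pop_size)) {
        m <- stats::runif(p) < tau
        if (!any(m)) m[sample(p, 1L)] <- TRUE
        fa <- fit(m)
        if (fa < it_best_f) { it_best_f <- fa; it_best_mask <- m }
        if (fa < best_f) { best_f <- fa; best_mask <- m }
      }
      if (!is.null(it_best_mask)) {
        quality <- max(0, 1 - it_best_f)
        tau <- (1 - cfg$evaporation) * tau +
          cfg$evaporation * quality * as.numeric(it_best_mask)
      }
      tau <- pmin(pmax(tau, cfg$tau_min), cfg$tau_max)
      traj[it] <- best_f
    }
    best_subset_result(best_mask, best_f, traj, evaluator, cfg$seed,
                       extra = list(pheromones = tau))
  })
}

#' Simulated annealing subset selection
#'
#' Metropolis search over single-bit-flip neighbours: a worse move of size
#' `delta > 0` is accepted with probability `exp(-delta / T)`; `delta <= 0`
#' is always accepted. Temperature cools geometrically, `T <- cooling * T`,
#' each step. At `T = 0` the rule degenerates to strict hill-climbing.
#'
#' @inheritParams ga_run
#' @param cfg a [metaheuristic_config()] with `algorithm = "sa"`.
#' @return A `best_subset_result`.
#' @export
sa_run <- function(table, labels, eval_cfg = eval_config(),
                   cfg = metaheuristic_config("sa")) {
  stopifnot(cfg$algorithm == "sa")
  labels <- cohort_labels(labels)
  p <- ncol(table$values)
  evaluator <- make_subset_evaluator(table, labels, eval_cfg)
  fit <- scalar_fitness(evaluator, cfg$lambda, p)
  with_seed(cfg$seed, {
    cur <- random_mask(p)
    f_cur <- fit(cur)
    best_mask <- cur; best_f <- f_cur
    temp <- cfg$t_init
    traj <- numeric(cfg$iterations)
    for (it in seq_len(cfg$iterations)) {
      cand <- cur
      j <- sample(p, 1L)
      cand[j] <- !cand[j]
      f_cand <- fit(cand)
      delta <- f_cand - f_cur
      accept <- if (delta <= 0) TRUE
                else if (temp <= 0) FALSE
                else stats::runif(1) < exp(-delta / temp)
      if (accept) { cur <- cand; f_cur <- f_cand }
      if (f_cur < best_f) { best_f <- f_cur; best_mask <- cur }
      temp <- cfg$cooling * temp
      traj[it] <- best_f
    }
    best_subset_result(best_mask, best_f, traj, evaluator, cfg$seed)
  })
}

#' Binary particle swarm optimisation subset selection
#'
#' Kennedy-Eberhart binary PSO: real-valued velocities updated with inertia
#' and personal/global-best attraction, clamped to `[-v_max, v_max]`; each
#' bit is then resampled as 1 with probability `sigmoid(v)`.
#'
#' @inheritParams ga_run
#' @param cfg a [metaheuristic_config()] with `algorithm = "pso"`.
#' @return A `best_subset_result`.
#' @export
pso_run <- function(table, labels, eval_cfg = eval_config(),
                    cfg = metaheuristic_config("pso")) {
  stopifnot(cfg$algorithm == "pso")
  labels <- cohort_labels(labels)
  p <- ncol(table$values)
  evaluator <- make_subset_evaluator(table, labels, eval_cfg)
  fit <- scalar_fitness(evaluator, cfg$lambda, p)
  sigmoid <- function(v) 1 / (1 + exp(-v))
  with_seed(cfg$seed, {
    X <- matrix(stats::runif(cfg$pop_size * p) < 0.5, cfg$pop_size, p)
    V <- matrix(stats::runif(cfg$pop_size * p, -1, 1), cfg$pop_size, p)
    f <- apply(X, 1, fit)
    pbest <- X; pbest_f <- f
    g <- which.min(f)
    gbest <- X[g, ]; gbest_f <- f[g]
    traj <- numeric(cfg$iterations)
    for (it in seq_len(cfg$iterations)) {
      r1 <- matrix(stats::runif(cfg$pop_size * p), cfg$pop_size, p)
      r2 <- matrix(stats::runif(cfg$pop_size * p), cfg$pop_size, p)
      V <- cfg$inertia * V +
        cfg$c1 * r1 * (pbest - X) +
        cfg$c2 * r2 * (matrix(gbest, cfg$pop_size, p, byrow = TRUE) - X)
      V <- pmin(pmax(V, -cfg$v_max), cfg$v_max)
      X <- matrix(stats::runif(cfg$pop_size * p), cfg$pop_size, p) < sigmoid(V)
      f <- apply(X, 1, fit)
      improved <- f < pbest_f
      pbest[improved, ] <- X[improved, , drop = FALSE]
      pbest_f[improved] <- f[improved]
      g <- which.min(pbest_f)
      if (pbest_f[g] < gbest_f) { gbest_f <- pbest_f[g]; gbest <- pbest[g, ] }
      traj[it] <- gbest_f
    }
    best_subset_result(gbest, gbest_f, traj, evaluator, cfg$seed,
                       extra = list(velocities = V))
  })
}

#' Dispatch one selector by name
#'
#' Convenience front-end used by the harness and CLI: `"nsga2"` dispatches
#' to [nsga2_run()], the other four to their `*_run` functions.
#'
#' @param method `"nsga2"`, `"ga"`, `"aco"`, `"sa"` or `"pso"`.
#' @param table,labels the cohort.
#' @param eval_cfg an [eval_config()].
#' @param method_cfg an [nsga2_config()] or [metaheuristic_config()]
#'   matching `method`; defaults are built when `NULL`.
#' @param seed overrides the config seed when not `NULL`.
#' @return A `pareto_result` or `best_subset_result`.
#' @export
run_selector <- function(method, table, labels, eval_cfg = eval_config(),
                         method_cfg = NULL, seed = NULL) {
  method <- match.arg(method, c("nsga2", "ga", "aco", "sa", "pso"))
  if (method == "nsga2") {
    cfg <- if (is.null(method_cfg)) nsga2_config() else method_cfg
    if (!is.null(seed)) cfg$seed <- as.integer(seed)
    nsga2_run(table, labels, eval_cfg, cfg)
  } else {
    cfg <- if (is.null(method_cfg)) metaheuristic_config(method) else method_cfg
    if (cfg$algorithm != method) {
      stop_named("evoselect_bad_config", "method_cfg algorithm mismatch")
    }
    if (!is.null(seed)) cfg$seed <- as.integer(seed)
    switch(method,
           ga = ga_run(table, labels, eval_cfg, cfg),
           aco = aco_run(table, labels, eval_cfg, cfg),
           sa = sa_run(table, labels, eval_cfg, cfg),
           pso = pso_run(table, labels, eval_cfg, cfg))
  }
}
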