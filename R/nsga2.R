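## NSGA-II over binary feature-inclusion masks, minimising the pair
## (classification error, number of selected features).

#' Pareto domination between two objective pairs (minimisation)
#'
#' `a` dominates `b` iff `a` is no worse in every objective and strictly
#' better in at least one.
#'
#' @param a,b numeric objective vectors of equal length.
#' @return Logical flag.
#' @export
dominates <- function(a, b) {
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop_named("evoselect_nonfinite", "objectives must be finite")
  }
  all(a <= b) && any(a < b)
}

#' Fast nondominated sorting
#'
#' Deb's O(M N^2) sweep: front 1 is the maximal nondominated set; front
#' i + 1 is the nondominated set once fronts `<= i` are removed. The
#' returned fronts partition the input exhaustively and disjointly.
#'
#' @param objectives numeric matrix, one row per solution, one column per
#'   objective (minimised).
#' @return List of integer index vectors, one per front.
#' @export
fast_nondominated_sort <- function(objectives) {
  objectives <- as.matrix(objectives)
  n <- nrow(objectives)
  if (n == 0L) stop_named("evoselect_empty", "no solutions to sort")
  dominated_by <- vector("list", n)   # solutions that i dominates
  n_dominating <- integer(n)          # count of solutions dominating i
  for (i in seq_len(n)) {
    oi <- objectives[i, ]
    for (j in seq_len(n)) {
      if (i == j) next
      if (dominates(oi, objectives[j, ])) {
        dominated_by[[i]] <- c(dominated_by[[i]], j)
      } else if (dominates(objectives[j, ], oi)) {
        n_dominating[i] <- n_dominating[i] + 1L
      }
    }
  }
  fronts <- list()
  current <- which(n_dominating == 0L)
  while (length(current)) {
    fronts[[length(fronts) + 1L]] <- current
    nxt <- integer(0)
    for (i in current) {
      for (j in dominated_by[[i]]) {
        n_dominating[j] <- n_dominating[j] - 1L
        if (n_dominating[j] == 0L) nxt <- c(nxt, j)
      }
    }
    current <- sort(unique(nxt))
  }
  fronts
}

#' Crowding distance within one front
#'
#' Per objective, members are sorted; the two boundary members receive
#' infinite distance, interior members accumulate the normalised gap
#' `(next - previous) / (max - min)` between their neighbours. An objective
#' with zero range contributes nothing.
#'
#' @param front_objectives numeric matrix of the front's objective rows.
#' @return Numeric distance per member (same order as the rows).
#' @export
crowding_distance <- function(front_objectives) {
  front_objectives <- as.matrix(front_objectives)
  n <- nrow(front_objectives)
  if (n == 0L) stop_named("evoselect_empty", "front must be non-empty")
  d <- numeric(n)
  for (m in seq_len(ncol(front_objectives))) {
    o <- front_objectives[, m]
    ord <- order(o)
    rng <- o[ord[n]] - o[ord[1]]
    d[ord[c(1L, n)]] <- Inf
    if (n > 2L && rng > 0) {
      inner <- ord[2:(n - 1L)]
      d[inner] <- d[inner] + (o[ord[3:n]] - o[ord[1:(n - 2L)]]) / rng
    }
  }
  d
}

#' NSGA-II configuration
#'
#' Defaults follow the reference parameterisation of the study design this
#' package reproduces: population 25 equal to the mating pool size,
#' crossover applied to 14% of the pool, mutation applied to 40% of the
#' pool at a per-bit flip rate of 0.1.
#'
#' @param population_size N, `>= 2`. Default 25.
#' @param mating_pool_size parents drawn per generation. Default `= N`.
#' @param crossover_percentage fraction of the pool forming crossover
#'   pairings. Default 0.14.
#' @param mutation_percentage fraction of the pool undergoing mutation.
#'   Default 0.4.
#' @param mutation_rate per-bit flip probability. Default 0.1.
#' @param max_generations stop condition. Default 50.
#' @param seed RNG seed.
#' @return List of class `nsga2_config`.
#' @export
nsga2_config <- function(population_size = 25L,
                         mating_pool_size = population_size,
                         crossover_percentage = 0.14,
                         mutation_percentage = 0.4,
                         mutation_rate = 0.1,
                         max_generations = 50L, seed = 1L) {
  stopifnot(is_count(population_size, 2L), is_count(mating_pool_size, 2L),
            is_prob(crossover_percentage), is_prob(mutation_percentage),
            is_prob(mutation_rate), is_count(max_generations, 0L))
  structure(list(population_size = as.integer(population_size),
                 mating_pool_size = as.integer(mating_pool_size),
                 crossover_percentage = crossover_percentage,
                 mutation_percentage = mutation_percentage,
                 mutation_rate = mutation_rate,
                 max_generations = as.integer(max_generations),
                 seed = as.integer(seed)),
            class = "nsga2_config")
}

## rank (front index) and crowding distance for a population objective matrix
rank_and_crowding <- function(objectives) {
  fronts <- fast_nondominated_sort(objectives)
  rank <- integer(nrow(objectives)); crowd <- numeric(nrow(objectives))
  for (fi in seq_along(fronts)) {
    idx <- fronts[[fi]]
    rank[idx] <- fi
    crowd[idx] <- crowding_distance(objectives[idx, , drop = FALSE])
  }
  list(rank = rank, crowding = crowd, fronts = fronts)
}

## binary tournament by (rank asc, crowding desc); returns one index
tournament_pick <- function(rank, crowd) {
  c2 <- sample(length(rank), 2L, replace = TRUE)
  i <- c2[1]; j <- c2[2]
  if (rank[i] < rank[j]) i
  else if (rank[j] < rank[i]) j
  else if (crowd[i] > crowd[j]) i
  else if (crowd[j] > crowd[i]) j
  else i
}

uniform_crossover <- function(p1, p2) {
  take <- stats::runif(length(p1)) < 0.5
  c1 <- p1; c1[take] <- p2[take]
  c2 <- p2; c2[take] <- p1[take]
  list(c1, c2)
}

random_mask <- function(p) {
  repeat {
    m <- stats::runif(p) < 0.5
    if (any(m)) return(m)
  }
}

#' Run NSGA-II binary feature selection
#'
#' Evolves a population of feature-inclusion masks minimising the objective
#' pair (validation classification error, subset size). Each generation: a
#' mating pool is filled by binary tournament on (front rank, crowding);
#' `ceil(crossover_percentage * pool)` pairings undergo uniform crossover;
#' `ceil(mutation_percentage * pool)` pool members are mutated at
#' `mutation_rate` per bit; parents, offspring and mutants are merged,
#' sorted by nondomination rank then crowding and truncated back to N.
#' Fitness values are cached per mask, so duplicated masks cost nothing.
#'
#' @param table a [feature_table()].
#' @param labels a [cohort_labels()].
#' @param eval_cfg an [eval_config()] (fixed seeds make fitness
#'   deterministic within the run).
#' @param cfg an [nsga2_config()].
#' @return List of class `pareto_result`: `population` (mask matrix),
#'   `objectives` (error, n_features), `front` (indices of the final
#'   nondominated set), `front_objectives`, `operating_point` (mask chosen
#'   by [select_operating_point()]), `operating_accuracy`, `best_error_trace`
#'   per generation, `generations_run`, `evaluation_count`, `seed`.
#' @export
nsga2_run <- function(table, labels, eval_cfg = eval_config(),
                      cfg = nsga2_config()) {
  stopifnot(inherits(cfg, "nsga2_config"))
  labels <- cohort_labels(labels)
  p <- ncol(table$values)
  evaluator <- make_subset_evaluator(table, labels, eval_cfg)
  objective <- function(mask) {
    rec <- evaluator(mask)
    c(rec$error, rec$size)
  }
  with_seed(cfg$seed, {
    N <- cfg$population_size
    pop <- lapply(seq_len(N), function(i) random_mask(p))
    obj <- t(vapply(pop, objective, numeric(2)))
    trace <- numeric(0)
    gens <- 0L
    while (gens < cfg$max_generations) {
      rc <- rank_and_crowding(obj)
      pool_idx <- vapply(seq_len(cfg$mating_pool_size),
                         function(i) tournament_pick(rc$rank, rc$crowding),
                         integer(1))
      pool <- pop[pool_idx]
      n_pairs <- ceiling(cfg$crossover_percentage * length(pool))
      offspring <- list()
      if (n_pairs > 0) {
        for (k in seq_len(n_pairs)) {
          pr <- sample(length(pool), 2L, replace = length(pool) < 2L)
          kids <- uniform_crossover(pool[[pr[1]]], pool[[pr[2]]])
          offspring <- c(offspring, kids)
        }
      }
      n_mut <- ceiling(cfg$mutation_percentage * length(pool))
      mutants <- list()
      if (n_mut > 0) {
        midx <- sample(length(pool), n_mut, replace = n_mut > length(pool))
        for (k in midx) {
          m <- pool[[k]]
          flip <- stats::runif(p) < cfg$mutation_rate
          m[flip] <- !m[flip]
          mutants <- c(mutants, list(m))
        }
      }
      newcomers <- c(offspring, mutants)
      if (length(newcomers)) {
        new_obj <- t(vapply(newcomers, objective, numeric(2)))
        pop <- c(pop, newcomers)
        obj <- rbind(obj, new_obj)
      }
      ## environmental selection: (rank, crowding) truncation to N
      rc <- rank_and_crowding(obj)
      keep <- order(rc$rank, -rc$crowding)[seq_len(N)]
      pop <- pop[keep]
      obj <- obj[keep, , drop = FALSE]
      gens <- gens + 1L
      trace <- c(trace, min(obj[, 1]))
    }
    fronts <- fast_nondominated_sort(obj)
    front <- fronts[[1]]
    op <- select_operating_point(pop[front], obj[front, , drop = FALSE])
    pop_mat <- do.call(rbind, pop)
    colnames(pop_mat) <- table$feature_names
    structure(list(population = pop_mat,
                   objectives = obj,
                   front = front,
                   front_objectives = obj[front, , drop = FALSE],
                   operating_point = op$mask,
                   operating_objectives = op$objectives,
                   operating_accuracy = 1 - op$objectives[1],
                   best_error_trace = trace,
                   generations_run = gens,
                   evaluation_count = evaluator_stats(evaluator)$evaluations,
                   seed = cfg$seed),
              class = "pareto_result")
  })
}

#' Choose a single operating point from a Pareto front
#'
#' Every front member is an optimal trade-off; for reporting one subset we
#' take the minimum-error member, breaking ties by fewer features, then by
#' the lexicographically smallest mask.
#'
#' @param masks list (or matrix rows) of front masks.
#' @param objectives matrix of the front's (error, n_features) rows.
#' @return List: `mask`, `objectives`, `index` (position within the front).
#' @export
select_operating_point <- function(masks, objectives) {
  if (is.matrix(masks)) masks <- lapply(seq_len(nrow(masks)), function(i) masks[i, ])
  objectives <- as.matrix(objectives)
  if (length(masks) == 0L) stop_named("evoselect_empty", "front is empty")
  keys <- vapply(masks, mask_key, character(1))
  ord <- order(objectives[, 1], objectives[, 2], keys)
  i <- ord[1]
  list(mask = masks[[i]], objectives = objectives[i, ], index = i)
}

#' @export
print.pareto_result <- function(x, ...) {
  cat(sprintf(paste0("<pareto_result> front size %d, operating point: ",
                     "error %.4f with %d features (%d evaluations)\n"),
              length(x$front), x$operating_objectives[1],
              x$operating_objectives[2], x$evaluation_count))
  invisible(x)
}

#' Serialize a Pareto result to JSON
#'
#' Masks are written as bitstrings together with objectives, the chosen
#' operating point, evaluation counts and a config echo.
#'
#' @param result a `pareto_result`.
#' @param path output JSON path.
#' @param config optional config list echoed into the file.
#' @return `path`, invisibly.
#' @export
write_pareto_result <- function(result, path, config = NULL) {
  front_masks <- apply(result$population[result$front, , drop = FALSE], 1,
                       function(m) paste(as.integer(m), collapse = ""))
  obj <- result$front_objectives
  payload <- list(
    front = lapply(seq_along(front_masks), function(i) {
      list(mask = unname(front_masks[i]), error = unname(obj[i, 1]),
           n_features = unname(obj[i, 2]))
    }),
    operating_point = list(
      mask = paste(as.integer(result$operating_point), collapse = ""),
      error = unname(result$operating_objectives[1]),
      n_features = unname(result$operating_objectives[2])),
    generations_run = result$generations_run,
    evaluation_count = result$evaluation_count,
    seed = result$seed,
    config = config)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
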