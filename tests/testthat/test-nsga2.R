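test_that("domination relation on hand cases", {
  expect_true(dominates(c(0.10, 5), c(0.20, 7)))
  expect_false(dominates(c(0.10, 5), c(0.10, 5)))
  expect_false(dominates(c(0.10, 7), c(0.20, 5)))
  expect_false(dominates(c(0.20, 5), c(0.10, 7)))
  expect_error(dominates(c(Inf, 1), c(0, 0)), class = "evoselect_nonfinite")
})

test_that("fast nondominated sort: hand case and singleton", {
  obj <- rbind(c(1, 2), c(2, 1), c(2, 2), c(3, 3))
  fronts <- fast_nondominated_sort(obj)
  expect_equal(fronts, list(c(1L, 2L), 3L, 4L))
  expect_equal(fast_nondominated_sort(rbind(c(5, 5))), list(1L))
})

test_that("fast nondominated sort equals the brute-force oracle (property)", {
  set.seed(19)
  for (i in 1:40) {
    n <- sample(2:60, 1)
    obj <- cbind(round(runif(n), sample(1:3, 1)), sample(1:12, n, TRUE))
    got <- fast_nondominated_sort(obj)
    want <- oracle_nondominated_sort(obj)
    got <- lapply(got, sort)
    expect_equal(got, want, info = sprintf("instance %d (n=%d)", i, n))
    ## exhaustive + disjoint partition
    expect_setequal(unlist(got), seq_len(n))
    expect_equal(length(unlist(got)), n)
  }
})

test_that("crowding distance: boundaries infinite, interior normalized gaps", {
  two <- crowding_distance(rbind(c(1, 2), c(2, 1)))
  expect_equal(two, c(Inf, Inf))

  three <- crowding_distance(rbind(c(1, 3), c(2, 2), c(3, 1)))
  expect_equal(three, c(Inf, 2, Inf))

  same <- crowding_distance(rbind(c(1, 1), c(1, 1), c(1, 1)))
  expect_true(all(is.infinite(same[c(1, 3)])) || sum(is.infinite(same)) >= 2)
  expect_equal(sum(same[is.finite(same)]), 0)
})

test_that("operating point selection: minimum error, ties to fewer features", {
  masks <- list(c(TRUE, TRUE, FALSE), c(FALSE, FALSE, TRUE),
                c(TRUE, FALSE, FALSE))
  sel <- select_operating_point(masks, rbind(c(0.05, 12), c(0.07, 3),
                                             c(0.06, 1)))
  expect_equal(sel$objectives, c(0.05, 12))

  sel2 <- select_operating_point(masks[1:2], rbind(c(0.05, 12), c(0.05, 3)))
  expect_equal(sel2$objectives, c(0.05, 3))

  sel3 <- select_operating_point(masks[2], rbind(c(0.5, 1)))
  expect_equal(sel3$index, 1L)
  expect_error(select_operating_point(list(), matrix(0, 0, 2)),
               class = "evoselect_empty")
})

test_that("nsga2: zero generations returns the initial nondominated set; seeded runs reproduce", {
  coh <- make_separable_cohort(n_per_class = 12L, p = 6L, seed = 23L)
  cfg <- nsga2_config(population_size = 8L, max_generations = 0L, seed = 31L)
  res <- nsga2_run(coh$table, coh$labels, toy_eval_cfg(4L), cfg)
  expect_equal(res$generations_run, 0L)
  oracle_front <- oracle_nondominated_sort(res$objectives)[[1]]
  expect_setequal(res$front, oracle_front)

  res2 <- nsga2_run(coh$table, coh$labels, toy_eval_cfg(4L), cfg)
  expect_identical(res$objectives, res2$objectives)
  expect_identical(res$operating_point, res2$operating_point)
})

test_that("nsga2 front members are mutually nondominated and elitism holds", {
  coh <- make_separable_cohort(n_per_class = 12L, p = 6L, seed = 24L)
  res <- nsga2_run(coh$table, coh$labels, toy_eval_cfg(5L),
                   nsga2_config(population_size = 10L, max_generations = 6L,
                                seed = 7L))
  fo <- res$front_objectives
  for (i in seq_len(nrow(fo))) {
    for (j in seq_len(nrow(fo))) {
      if (i != j) expect_false(dominates(fo[i, ], fo[j, ]))
    }
  }
  ## best error never worsens across generations (cached deterministic fitness)
  expect_true(all(diff(res$best_error_trace) <= 0))
  ## operating point belongs to the front
  expect_true(any(apply(res$population[res$front, , drop = FALSE], 1,
                        function(m) identical(as.logical(m),
                                              as.logical(res$operating_point)))))
})

test_that("truncation preserves front 1 when it fits within N", {
  set.seed(26)
  obj <- cbind(runif(30), sample(1:10, 30, TRUE))
  rc <- evoselect:::rank_and_crowding(obj)
  keep <- order(rc$rank, -rc$crowding)[1:15]
  f1 <- which(rc$rank == 1L)
  if (length(f1) <= 15) expect_true(all(f1 %in% keep))
})

test_that("pareto result serializes round-trip to JSON", {
  coh <- make_separable_cohort(n_per_class = 10L, p = 5L, seed = 27L)
  res <- nsga2_run(coh$table, coh$labels, toy_eval_cfg(6L),
                   nsga2_config(population_size = 6L, max_generations = 2L,
                                seed = 3L))
  path <- tempfile(fileext = ".json")
  write_pareto_result(res, path, config = list(note = "test"))
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$operating_point$mask,
               paste(as.integer(res$operating_point), collapse = ""))
  expect_equal(back$evaluation_count, res$evaluation_count)
})
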