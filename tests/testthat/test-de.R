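pop_fit_for <- function(trees, params, phase) {
  n <- n_trees(trees)
  function(G) osmiaplace:::pop_fitness(osmiaplace:::genes_to_indices(G, n),
                                       trees, params, phase)
}

test_that("initialization draws integer genes in bounds, deterministically", {
  ts <- random_trees(30, seed = 2)
  params <- coverage_params(K = 200)
  cfg <- de_config(dim = 10, np = 100, ub = 30, seed = 5)
  fit <- pop_fit_for(ts, params, 1L)
  set.seed(cfg$seed); pop <- initialize_population(cfg, fit)
  expect_equal(dim(pop$genes), c(100L, 10L))
  expect_true(all(pop$genes == round(pop$genes)))
  expect_true(all(pop$genes >= 0 & pop$genes <= 30))
  expect_true(all(is.finite(pop$fitness)) && all(pop$fitness > 0))
  set.seed(cfg$seed); pop2 <- initialize_population(cfg, fit)
  expect_identical(pop, pop2)
})

test_that("greedy selection never lets the population best deteriorate", {
  ts <- random_trees(25, width = 150, height = 150, seed = 14)
  params <- coverage_params(K = 50)
  for (seed in 1:5) {
    cfg <- de_config(dim = 4, np = 20, g = 20, ub = 25, seed = seed)
    fit <- pop_fit_for(ts, params, if (seed %% 2) 1L else 2L)
    set.seed(seed)
    pop <- initialize_population(cfg, fit)
    best <- min(pop$fitness)
    for (s in 1:20) {
      pop <- evolve_generation(pop, cfg, fit)
      expect_lte(min(pop$fitness), best)
      best <- min(pop$fitness)
    }
  }
})

test_that("a fully converged population is a fixed point of evolution", {
  ts <- random_trees(10, seed = 3)
  cfg <- de_config(dim = 3, np = 8, ub = 10, seed = 1)
  fit <- pop_fit_for(ts, coverage_params(K = 500), 2L)
  G <- matrix(rep(c(2, 5, 9), each = 8), nrow = 8)
  pop <- structure(list(genes = G, fitness = fit(G), generation = 0L),
                   class = "de_population")
  out <- evolve_generation(pop, cfg, fit)
  # zero difference vectors: every trial equals its target
  expect_identical(out$genes, G)
  expect_identical(out$fitness, pop$fitness)
})

test_that("run_phase returns the trivial single-aid solution when K spans all", {
  ts <- random_trees(12, width = 40, height = 40, seed = 6)
  sol <- run_phase(ts, coverage_params(K = 100),
                   de_config(dim = 5, np = 20, g = 40, ub = 12, seed = 9),
                   phase = 1)
  expect_equal(sol$effective_count, 1L)
  expect_true(sol$feasible)
  expect_length(sol$history$best_fitness, 40L)
  expect_true(all(diff(sol$history$best_fitness) <= 0))
})

test_that("identical configuration and seed reproduce the whole solution", {
  ts <- random_trees(20, width = 120, height = 120, seed = 18)
  run <- function() lexicographic_solve(
    ts, coverage_params(K = 50),
    config1 = de_config(dim = 5, np = 16, g = 50, f = 0.9, ub = 20, seed = 4),
    config2 = de_config(dim = 1, np = 16, g = 50, f = 0.1, ub = 20, seed = 5))
  a <- run(); b <- run()
  expect_identical(a$aid_tree_ids, b$aid_tree_ids)
  expect_identical(a$total_distance, b$total_distance)
  expect_identical(a$phase1$history, b$phase1$history)
})

test_that("the two-stage solve matches the exact oracle on a small instance", {
  params <- coverage_params(K = 50)
  ts <- random_trees(14, width = 130, height = 130, seed = 26)
  truth1 <- exact_min_aids(ts, params)
  truth2 <- exact_p_median_capped(ts, truth1$p_star, params)
  best_p <- Inf; best_total <- Inf
  for (seed in 1:10) {
    sol <- lexicographic_solve(
      ts, params,
      config1 = de_config(dim = 5, np = 30, g = 120, f = 0.9, ub = 14,
                          seed = seed),
      config2 = de_config(dim = 1, np = 30, g = 120, f = 0.1, ub = 14,
                          seed = seed + 100))
    if (sol$p_star < best_p) best_p <- sol$p_star
    if (sol$p_star == truth1$p_star) {
      best_total <- min(best_total, sol$total_distance)
    }
  }
  expect_equal(best_p, truth1$p_star)
  expect_equal(best_total, truth2$total_distance, tolerance = 1e-12)
})

test_that("warm start seeds stage 2 without changing feasibility", {
  ts <- random_trees(16, width = 100, height = 100, seed = 44)
  sol <- lexicographic_solve(
    ts, coverage_params(K = 60),
    config1 = de_config(dim = 4, np = 16, g = 40, f = 0.9, ub = 16, seed = 2),
    config2 = de_config(dim = 1, np = 16, g = 40, f = 0.1, ub = 16, seed = 3),
    warm_start = TRUE)
  expect_length(sol$uncovered, 0)
  expect_equal(length(sol$aid_tree_ids), sol$p_star)
})

test_that("an uncoverable instance is flagged instead of answered", {
  # two clusters 5,000 m apart but only one gene: no placement can cover both
  ts <- tree_set(c(0, 5000), c(0, 0))
  expect_error(
    lexicographic_solve(ts, coverage_params(K = 50),
      config1 = de_config(dim = 1, np = 8, g = 10, ub = 2, seed = 1),
      config2 = de_config(dim = 1, np = 8, g = 10, ub = 2, seed = 2)),
    "infeasible")
})

test_that("solutions serialize with histories", {
  ts <- random_trees(12, width = 60, height = 60, seed = 9)
  sol <- lexicographic_solve(
    ts, coverage_params(K = 80),
    config1 = de_config(dim = 3, np = 12, g = 15, ub = 12, seed = 1),
    config2 = de_config(dim = 1, np = 12, g = 15, f = 0.1, ub = 12, seed = 2))
  js <- withr::local_tempfile(fileext = ".json")
  hist <- withr::local_tempfile(fileext = ".csv")
  write_solution(sol, js, history_csv = hist)
  got <- jsonlite::read_json(js)
  expect_equal(got$p_star, sol$p_star)
  expect_equal(got$total_distance_m, sol$total_distance, tolerance = 1e-12)
  h <- utils::read.csv(hist)
  expect_equal(nrow(h), 30L)
  expect_true(all(unlist(tapply(h$best_fitness, h$phase, diff)) <= 0))
})
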