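#' Differential-evolution control parameters
#'
#' Classic rand/1/bin differential evolution over integer-encoded
#' placements: each individual is a vector of `dim` genes, each gene the
#' serial number of the tree carrying a nesting aid. Genes are kept
#' integer by rounding after every variation step, and gene 0 (the
#' printed lower bound) maps to tree 1 at evaluation.
#'
#' Defaults follow the settings used for one-hectare orchards: `np = 100`,
#' `g = 1000`, `cr = 0.2`, with mutation constant `f = 0.9` for the
#' aid-count stage (wide exploration) and `f = 0.1` for the distance
#' stage (local refinement around the stage-1 solution).
#'
#' @param dim Genes per individual: the maximum number of aids (10 for
#'   stage 1; the stage-1 optimum for stage 2).
#' @param np Population size (at least 4).
#' @param g Number of generations; the only stopping criterion.
#' @param cr Crossover constant in (0, 1].
#' @param f Mutation constant in (0, 2].
#' @param lb,ub Gene bounds; `lb = 0` and `ub = n` (number of trees).
#' @param seed Integer RNG seed; every run is deterministic given it.
#' @param strategy Variation strategy; only `"rand1bin"` is implemented.
#' @return A `de_config` object.
#' @export
de_config <- function(dim, np = 100L, g = 1000L, cr = 0.2, f = 0.9,
                      lb = 0, ub, seed = 1L, strategy = "rand1bin") {
  stopifnot(dim >= 1L, np >= 4L, g >= 1L, cr > 0, cr <= 1,
            f > 0, f <= 2, lb < ub)
  strategy <- match.arg(strategy, "rand1bin")
  structure(list(dim = as.integer(dim), np = as.integer(np),
                 g = as.integer(g), cr = cr, f = f, lb = lb, ub = ub,
                 seed = as.integer(seed), strategy = strategy),
            class = "de_config")
}

genes_to_indices <- function(G, n) {
  storage.mode(G) <- "double"
  pmin(pmax(round(G), 1), n)
}

#' Initialize a DE population
#'
#' Genes are drawn uniformly on `[lb, ub]` and rounded to integers (aids
#' must sit on trees), then every individual is evaluated. Consumes the
#' current RNG stream; seed it via [run_phase()] or `set.seed()` for
#' reproducibility.
#'
#' @param config A [de_config()].
#' @param fitness_fn Population fitness function: takes an `np x dim` gene
#'   matrix, returns `np` fitness values (smaller is better).
#' @return A `de_population`: list with `genes`, `fitness`, `generation`.
#' @export
initialize_population <- function(config, fitness_fn) {
  G <- matrix(stats::runif(config$np * config$dim, config$lb, config$ub),
              nrow = config$np, ncol = config$dim)
  G <- round(G)
  structure(list(genes = G, fitness = fitness_fn(G), generation = 0L),
            class = "de_population")
}

#' Advance a DE population by one generation
#'
#' For every target individual: rand/1 mutation from three distinct other
#' members (`v = x_r1 + f (x_r2 - x_r3)`), binomial crossover at rate `cr`
#' with one guaranteed mutant gene, repair (round to integer, clamp to
#' `[lb, ub]`), and greedy one-to-one replacement when the trial's fitness
#' is less than or equal to the incumbent's. The population best can
#' therefore never get worse.
#'
#' @param pop A `de_population` from [initialize_population()].
#' @inheritParams initialize_population
#' @return The next `de_population`.
#' @export
evolve_generation <- function(pop, config, fitness_fn) {
  np <- config$np; d <- config$dim
  G <- pop$genes
  # three distinct partners per target, none equal to the target itself:
  # draw uniformly and redraw clashes until none remain
  r <- matrix(sample.int(np, 3L * np, replace = TRUE), np, 3L)
  repeat {
    clash <- r[, 1L] == seq_len(np) | r[, 2L] == seq_len(np) |
      r[, 3L] == seq_len(np) | r[, 1L] == r[, 2L] |
      r[, 1L] == r[, 3L] | r[, 2L] == r[, 3L]
    if (!any(clash)) break
    r[clash, ] <- matrix(sample.int(np, 3L * sum(clash), replace = TRUE),
                         ncol = 3L)
  }
  V <- G[r[, 1L], , drop = FALSE] +
    config$f * (G[r[, 2L], , drop = FALSE] - G[r[, 3L], , drop = FALSE])
  mask <- matrix(stats::runif(np * d) < config$cr, np, d)
  mask[cbind(seq_len(np), sample.int(d, np, replace = TRUE))] <- TRUE
  trial <- G
  trial[mask] <- V[mask]
  trial <- pmin(pmax(round(trial), config$lb), config$ub)
  tf <- fitness_fn(trial)
  acc <- tf <= pop$fitness
  G[acc, ] <- trial[acc, , drop = FALSE]
  fit <- pop$fitness
  fit[acc] <- tf[acc]
  structure(list(genes = G, fitness = fit,
                 generation = pop$generation + 1L),
            class = "de_population")
}

#' Run one priority level of the placement problem
#'
#' Runs the full DE loop for exactly `g` generations against the stage
#' fitness ([fitness_phase1()] semantics for `phase = 1`,
#' [fitness_phase2()] for `phase = 2`) and records the best fitness of
#' every generation in the history vector, which is non-increasing by
#' greedy selection.
#'
#' @param trees A [tree_set()].
#' @param params A [coverage_params()].
#' @param config A [de_config()]; `ub` is clamped to the number of trees
#'   at evaluation.
#' @param phase 1 (minimize effective aid count) or 2 (minimize total
#'   flight distance).
#' @param init Optional gene matrix used to seed the initial population
#'   (rows beyond `np` ignored, missing rows drawn at random).
#' @return A `phase_solution`: `aid_indices` (unique tree indices of the
#'   best individual), `effective_count`, `report` (its
#'   [nearest_assignment()]), `fitness`, `feasible` (full coverage at
#'   `K`), `history` (`best_fitness`, `best_genes`), `config`, `phase`.
#' @export
run_phase <- function(trees, params, config, phase,
                      init = NULL) {
  stopifnot(inherits(trees, "tree_set"), inherits(config, "de_config"),
            phase %in% c(1L, 2L))
  n <- n_trees(trees)
  fit_fn <- function(G) pop_fitness(genes_to_indices(G, n), trees, params,
                                    phase = as.integer(phase))
  set.seed(config$seed)
  pop <- initialize_population(config, fit_fn)
  if (!is.null(init)) {
    init <- matrix(as.numeric(init), ncol = config$dim)
    k <- min(nrow(init), config$np)
    pop$genes[seq_len(k), ] <- pmin(pmax(round(init[seq_len(k), , drop = FALSE]),
                                         config$lb), config$ub)
    pop$fitness <- fit_fn(pop$genes)
  }
  hist_fit <- numeric(config$g)
  hist_genes <- matrix(NA_real_, config$g, config$dim)
  for (s in seq_len(config$g)) {
    pop <- evolve_generation(pop, config, fit_fn)
    b <- which.min(pop$fitness)
    hist_fit[s] <- pop$fitness[b]
    hist_genes[s, ] <- pop$genes[b, ]
  }
  b <- which.min(pop$fitness)
  best_idx <- as.integer(genes_to_indices(pop$genes[b, , drop = FALSE], n))
  report <- nearest_assignment(trees, best_idx, params)
  structure(list(
    phase = as.integer(phase),
    best_genes = pop$genes[b, ],
    aid_indices = collapse_aids(best_idx),
    effective_count = report$effective_count,
    report = report,
    fitness = pop$fitness[b],
    feasible = length(report$uncovered) == 0L,
    history = list(best_fitness = hist_fit, best_genes = hist_genes),
    config = config
  ), class = "phase_solution")
}

#' Lexicographic two-stage solve
#'
#' The two objectives have strict priorities: first find the minimum
#' number of nesting aids covering every tree within the foraging range
#' `K` (stage 1), then, with the aid count fixed at that optimum `p*`,
#' find the placement minimizing the total flight distance from every
#' tree to its nearest aid (stage 2). Stage 2 runs with `dim = p*` and a
#' fresh uniformly-initialized population by default; `warm_start = TRUE`
#' seeds it with the stage-1 placement instead.
#'
#' @inheritParams run_phase
#' @param config1,config2 [de_config()]s for the two stages; by default
#'   `dim = 10`, `np = 100`, `g = 1000`, `cr = 0.2`, `ub = n`, with
#'   `f = 0.9` / `f = 0.1` and seeds `seed` / `seed + 1`. `config2$dim`
#'   is always overridden with the stage-1 optimum.
#' @param seed Seed used to build the default configs.
#' @param warm_start Seed the stage-2 population with the stage-1
#'   placement (default off).
#' @return A `placement_solution`: `p_star`, `aid_tree_ids`, `aid_coords`
#'   (data frame), `total_distance`, `max_distance`, `uncovered`,
#'   `phase1` and `phase2` (`phase_solution`s).
#' @examples
#' ts <- generate_grid(grid_spec(
#'   data.frame(xmin = 0, xmax = 12, ymin = 0, ymax = 8)))
#' sol <- lexicographic_solve(ts, coverage_params(K = 50),
#'   config1 = de_config(dim = 3, np = 20, g = 30, ub = n_trees(ts)),
#'   config2 = de_config(dim = 1, np = 20, g = 30, f = 0.1,
#'                       ub = n_trees(ts), seed = 2))
#' sol$p_star  # 1: a 50 m range covers this small block from any tree
#' @export
lexicographic_solve <- function(trees, params = coverage_params(),
                                config1 = NULL, config2 = NULL,
                                seed = 1L, warm_start = FALSE) {
  n <- n_trees(trees)
  if (is.null(config1)) {
    config1 <- de_config(dim = 10L, np = 100L, g = 1000L, cr = 0.2,
                         f = 0.9, lb = 0, ub = n, seed = seed)
  }
  phase1 <- run_phase(trees, params, config1, phase = 1L)
  if (!phase1$feasible) {
    stop(sprintf("coverage infeasible with %d aids at K = %g m (%d trees uncovered)",
                 config1$dim, params$K, length(phase1$report$uncovered)),
         call. = FALSE)
  }
  p_star <- phase1$effective_count
  if (is.null(config2)) {
    config2 <- de_config(dim = p_star, np = config1$np, g = config1$g,
                         cr = config1$cr, f = 0.1, lb = config1$lb,
                         ub = config1$ub, seed = config1$seed + 1L)
  } else {
    config2$dim <- p_star
  }
  init <- if (warm_start) matrix(phase1$aid_indices, nrow = 1L) else NULL
  phase2 <- run_phase(trees, params, config2, phase = 2L, init = init)
  rep <- phase2$report
  aid_ids <- sort(phase2$aid_indices)
  structure(list(
    p_star = p_star,
    aid_tree_ids = aid_ids,
    aid_coords = data.frame(id = aid_ids, x = trees$x[aid_ids],
                            y = trees$y[aid_ids]),
    total_distance = rep$total_distance,
    max_distance = rep$max_distance,
    uncovered = rep$uncovered,
    phase1 = phase1,
    phase2 = phase2
  ), class = "placement_solution")
}

#' @export
print.placement_solution <- function(x, ...) {
  cat(sprintf("<placement_solution> p* = %d aids, total %.2f m, max %.2f m\n",
              x$p_star, x$total_distance, x$max_distance))
  cat("aids on trees:", paste(x$aid_tree_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a placement solution
#'
#' @param sol A `placement_solution`.
#' @param path Output JSON path.
#' @param history_csv Optional path for the per-generation best-fitness
#'   history of both stages (columns `phase,generation,best_fitness`),
#'   suitable for a convergence plot.
#' @return `path`, invisibly.
#' @export
write_solution <- function(sol, path, history_csv = NULL) {
  stopifnot(inherits(sol, "placement_solution"))
  if (!is.null(history_csv)) {
    h1 <- sol$phase1$history$best_fitness
    h2 <- sol$phase2$history$best_fitness
    utils::write.csv(data.frame(
      phase = rep(c(1L, 2L), c(length(h1), length(h2))),
      generation = c(seq_along(h1), seq_along(h2)),
      best_fitness = c(h1, h2)
    ), history_csv, row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(list(
    p_star = sol$p_star,
    aid_tree_ids = as.integer(sol$aid_tree_ids),
    aid_coords = unname(apply(sol$aid_coords[, c("x", "y")], 1L, c,
                              simplify = FALSE)),
    total_distance_m = sol$total_distance,
    max_distance_m = sol$max_distance,
    uncovered = as.integer(sol$uncovered),
    seeds = c(sol$phase1$config$seed, sol$phase2$config$seed),
    history_csv_path = if (is.null(history_csv)) NULL else history_csv
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
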