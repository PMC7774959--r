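#' Coverage parameters
#'
#' @param K Maximum bee foraging range in meters (coverage radius). The
#'   default 50 m is a deliberately conservative ("worst-case") range for
#'   *Osmia cornuta*, ensuring pollination even in adverse weather; tagged
#'   females have been observed flying much farther on average.
#' @param penalty Fitness penalty per uncovered tree. Must dominate any
#'   achievable distance objective so that every feasible placement scores
#'   strictly below every infeasible one; the default 1e6 m exceeds
#'   n times the orchard diameter for all shipped layouts.
#' @return A `coverage_params` object.
#' @export
coverage_params <- function(K = 50, penalty = 1e6) {
  stopifnot(K > 0, penalty > 0)
  structure(list(K = K, penalty = penalty), class = "coverage_params")
}

# indices of unique aid positions keeping the lowest slot per position
collapse_aids <- function(aids) aids[!duplicated(aids)]

check_aids <- function(aids, n) {
  aids <- as.integer(aids)
  if (length(aids) == 0L) stop("aid placement is empty", call. = FALSE)
  if (any(aids < 1L | aids > n)) {
    stop("aid index outside 1..n", call. = FALSE)
  }
  aids
}

#' Assign every tree to its nearest nesting aid
#'
#' Computes the Euclidean nearest-aid assignment that realizes the
#' second-stage objective: the sum over trees of the distance to the
#' closest aid. Ties are broken by the lowest aid slot index; aids
#' occupying the same tree collapse onto the lowest slot, so duplicated
#' positions are never counted as serving trees.
#'
#' @param trees A [tree_set()].
#' @param aids Integer vector of tree indices carrying aids (an aid
#'   placement; at most one effective aid per tree).
#' @param params A [coverage_params()] used to flag uncovered trees.
#' @return A `coverage_report`: list with `assignment` (data frame of tree
#'   `id`, serving `aid_slot`, `aid_tree`, `distance`), `total_distance`,
#'   `max_distance`, `uncovered` (ids beyond `K`), `effective_count`
#'   (number of distinct aid positions serving at least one tree), `aids`
#'   and `K`.
#' @examples
#' ts <- tree_set(c(0, 30), c(0, 40))
#' nearest_assignment(ts, aids = 2)$assignment$distance  # 50, 0
#' @export
nearest_assignment <- function(trees, aids, params = coverage_params()) {
  stopifnot(inherits(trees, "tree_set"))
  aids <- check_aids(aids, n_trees(trees))
  n <- n_trees(trees)
  D2 <- outer(trees$x, trees$x[aids], "-")^2 +
        outer(trees$y, trees$y[aids], "-")^2
  # identical positions give bit-identical columns; "first" picks the lowest slot
  slot <- max.col(-D2, ties.method = "first")
  dist <- sqrt(D2[cbind(seq_len(n), slot)])
  rep <- list(
    assignment = data.frame(id = trees$id, aid_slot = slot,
                            aid_tree = aids[slot], distance = dist),
    total_distance = sum(dist),
    max_distance = max(dist),
    uncovered = trees$id[dist > params$K],
    effective_count = length(unique(slot)),
    aids = aids,
    K = params$K
  )
  structure(rep, class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf(paste0("<coverage_report> %d trees, %d effective aid(s), ",
                     "total %.2f m, max %.2f m, %d uncovered at K = %g m\n"),
              nrow(x$assignment), x$effective_count, x$total_distance,
              x$max_distance, length(x$uncovered), x$K))
  invisible(x)
}

#' Number of aid positions actually in use
#'
#' The first-stage objective: how many distinct aid positions serve at
#' least one tree under nearest assignment. Duplicated positions in the
#' placement vector collapse to one, which is what lets the evolutionary
#' search report fewer aids than its fixed vector length.
#'
#' @inheritParams nearest_assignment
#' @return Integer count.
#' @export
effective_aid_count <- function(trees, aids) {
  nearest_assignment(trees, aids)$effective_count
}

#' Trees beyond the foraging range
#'
#' @param report A `coverage_report` from [nearest_assignment()].
#' @param params A [coverage_params()]; coverage is boundary-inclusive
#'   (distance exactly `K` is covered).
#' @return Integer vector of uncovered tree ids (empty when the placement
#'   is feasible).
#' @export
check_coverage <- function(report, params = coverage_params()) {
  stopifnot(inherits(report, "coverage_report"))
  report$assignment$id[report$assignment$distance > params$K]
}

#' Placement fitness for the two priority levels
#'
#' Stage 1 minimizes the effective aid count, stage 2 the total flight
#' distance, each plus `penalty` for every tree left beyond the foraging
#' range so that feasibility always dominates the raw objective.
#'
#' @inheritParams nearest_assignment
#' @return A scalar fitness (smaller is better).
#' @export
fitness_phase1 <- function(aids, trees, params = coverage_params()) {
  aids <- check_aids(aids, n_trees(trees))
  pop_fitness(matrix(aids, nrow = 1L), trees, params, phase = 1L)
}

#' @rdname fitness_phase1
#' @export
fitness_phase2 <- function(aids, trees, params = coverage_params()) {
  aids <- check_aids(aids, n_trees(trees))
  pop_fitness(matrix(aids, nrow = 1L), trees, params, phase = 2L)
}

# Vectorized fitness of a whole population of placements.
# P: np x dim matrix of tree indices. Distances are kept squared until the
# row minima are known; the coverage test compares against K^2, which is
# exact for the boundary case. The whole population is scored with one
# max.col call by stacking the per-individual distance blocks.
pop_fitness <- function(P, trees, params, phase) {
  np <- nrow(P); d <- ncol(P); n <- n_trees(trees)
  K2 <- params$K^2
  ax <- trees$x[t(P)]                       # individual-major flattening
  ay <- trees$y[t(P)]
  D2 <- outer(trees$x, ax, "-")^2 + outer(trees$y, ay, "-")^2
  dim(D2) <- c(n, d, np)
  B <- aperm(D2, c(1L, 3L, 2L))             # (tree, individual, gene)
  dim(B) <- c(n * np, d)
  # identical positions give bit-identical columns; "first" = lowest slot
  slot <- max.col(-B, ties.method = "first")
  dmin2 <- B[cbind(seq_len(n * np), slot)]
  unc <- colSums(matrix(dmin2 > K2, n, np))
  if (phase == 1L) {
    ind <- rep(seq_len(np), each = n)
    key <- (ind - 1L) * d + slot            # (individual, used slot) pairs
    first <- !duplicated(key)
    eff <- tabulate(ind[first], nbins = np)
    eff + params$penalty * unc
  } else {
    colSums(matrix(sqrt(dmin2), n, np)) + params$penalty * unc
  }
}

#' Serialize a coverage report
#'
#' @param report A `coverage_report`.
#' @param csv_path Optional path for the per-tree assignment CSV
#'   (`id,aid_tree,distance`).
#' @param json_path Optional path for the summary JSON.
#' @return The report, invisibly.
#' @export
write_coverage_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "coverage_report"))
  if (!is.null(csv_path)) {
    utils::write.csv(report$assignment[, c("id", "aid_tree", "distance")],
                     csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      effective_count = report$effective_count,
      total_distance_m = report$total_distance,
      max_distance_m = report$max_distance,
      uncovered = as.integer(report$uncovered),
      K_m = report$K,
      aid_tree_ids = as.integer(collapse_aids(report$aids))
    ), json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
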