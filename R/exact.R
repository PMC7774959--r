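#' Exact small-instance solvers
#'
#' Provably optimal solutions of the two stages by exhaustive subset
#' enumeration, used as the ground-truth oracle when validating the
#' evolutionary solver. `exact_min_aids()` solves the set covering stage:
#' the smallest number of aid sites such that every tree is within `K`
#' meters of one. `exact_p_median_capped()` solves the second stage: among
#' all `p`-subsets respecting the coverage cap, the one minimizing the
#' total nearest-aid distance. Ties are broken by the lexicographically
#' smallest index tuple (the enumeration order of [utils::combn()]), so
#' results are deterministic.
#'
#' Enumeration cost grows as `choose(n, p)`; the `size_limit` guard
#' refuses instances beyond it rather than silently stalling.
#'
#' @param trees A [tree_set()].
#' @param params A [coverage_params()].
#' @param size_limit Maximum instance size accepted (default 30 trees).
#' @return An `exact_result`: list with `p_star`, `placement` (tree
#'   indices), `total_distance`, `feasible`, and `n_enumerated` (subsets
#'   examined, the optimality certificate of the enumeration).
#' @examples
#' ts <- tree_set(c(0, 3, 10), c(0, 0, 0))
#' exact_p_median_capped(ts, p = 1)$placement  # tree 2, total 10 m
#' @export
exact_min_aids <- function(trees, params = coverage_params(),
                           size_limit = 30L) {
  stopifnot(inherits(trees, "tree_set"))
  n <- n_trees(trees)
  if (n > size_limit) {
    stop(sprintf("exact enumeration refused: n = %d exceeds size_limit = %d",
                 n, size_limit), call. = FALSE)
  }
  cov <- covers_matrix(trees, params$K)   # cov[i, j]: aid at i covers tree j
  examined <- 0L
  for (p in seq_len(n)) {
    combos <- utils::combn(n, p)
    for (k in seq_len(ncol(combos))) {
      examined <- examined + 1L
      s <- combos[, k]
      if (all(colSums(cov[s, , drop = FALSE]) > 0L)) {
        rep <- nearest_assignment(trees, s, params)
        return(exact_result(p, s, rep$total_distance, TRUE, examined))
      }
    }
  }
  # unreachable: every tree covers itself at distance 0
  stop("no covering subset found; coverage matrix is inconsistent")
}

#' @rdname exact_min_aids
#' @param p Number of aids to place (at least the [exact_min_aids()]
#'   optimum for a feasible result).
#' @export
exact_p_median_capped <- function(trees, p, params = coverage_params(),
                                  size_limit = 30L) {
  stopifnot(inherits(trees, "tree_set"))
  n <- n_trees(trees)
  p <- as.integer(p)
  stopifnot(p >= 1L, p <= n)
  if (n > size_limit) {
    stop(sprintf("exact enumeration refused: n = %d exceeds size_limit = %d",
                 n, size_limit), call. = FALSE)
  }
  D2 <- outer(trees$x, trees$x, "-")^2 + outer(trees$y, trees$y, "-")^2
  K2 <- params$K^2
  combos <- utils::combn(n, p)
  best <- Inf
  best_s <- NULL
  for (k in seq_len(ncol(combos))) {
    s <- combos[, k]
    dmin2 <- do.call(pmin, as.data.frame(t(D2[s, , drop = FALSE])))
    if (any(dmin2 > K2)) next
    tot <- sum(sqrt(dmin2))
    if (tot < best) {        # strict <: first (lexicographic) subset wins ties
      best <- tot
      best_s <- s
    }
  }
  if (is.null(best_s)) {
    return(exact_result(p, integer(0), NA_real_, FALSE, ncol(combos)))
  }
  exact_result(p, best_s, best, TRUE, ncol(combos))
}

exact_result <- function(p_star, placement, total, feasible, examined) {
  structure(list(p_star = as.integer(p_star),
                 placement = as.integer(placement),
                 total_distance = total,
                 feasible = feasible,
                 n_enumerated = as.integer(examined)),
            class = "exact_result")
}

#' @export
print.exact_result <- function(x, ...) {
  if (x$feasible) {
    cat(sprintf("<exact_result> p = %d, aids at trees {%s}, total %.4f m\n",
                x$p_star, paste(x$placement, collapse = ", "),
                x$total_distance))
  } else {
    cat(sprintf("<exact_result> infeasible with p = %d aids\n", x$p_star))
  }
  invisible(x)
}

#' Serialize an exact result to JSON
#'
#' @param result An `exact_result`.
#' @param trees The [tree_set()] it was computed on.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exact_result <- function(result, trees, path) {
  stopifnot(inherits(result, "exact_result"))
  jsonlite::write_json(list(
    p_star = result$p_star,
    aid_tree_ids = result$placement,
    aid_coords = unname(lapply(result$placement, function(i) {
      c(trees$x[i], trees$y[i])
    })),
    total_distance_m = result$total_distance,
    feasible = result$feasible
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

covers_matrix <- function(trees, K) {
  D2 <- outer(trees$x, trees$x, "-")^2 + outer(trees$y, trees$y, "-")^2
  D2 <= K^2
}
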