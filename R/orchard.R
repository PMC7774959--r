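#' Regular-grid orchard specification
#'
#' Orchard layouts follow the planting pattern used in commercial fruit
#' growing: trees every `row_spacing` meters along a row (constant y) and
#' rows every `col_spacing` meters. The planted region is a union of
#' axis-aligned rectangles, which covers square, L-shaped and cross-shaped
#' orchards.
#'
#' @param rects A data frame or matrix with columns `xmin`, `xmax`, `ymin`,
#'   `ymax` (meters); one row per rectangle.
#' @param row_spacing Within-row tree spacing in meters (default 1.2).
#' @param col_spacing Between-row spacing in meters (default 4).
#' @param origin Grid origin, default `c(0, 0)`; grid points sit at
#'   `origin + (i * row_spacing, k * col_spacing)`.
#' @return A `grid_spec` object.
#' @seealso [generate_grid()], [orchard_shape()]
#' @export
grid_spec <- function(rects, row_spacing = 1.2, col_spacing = 4,
                      origin = c(0, 0)) {
  rects <- as.data.frame(rects)
  need <- c("xmin", "xmax", "ymin", "ymax")
  if (!all(need %in% names(rects))) {
    stop("rects needs columns xmin, xmax, ymin, ymax", call. = FALSE)
  }
  if (row_spacing <= 0 || col_spacing <= 0) {
    stop("spacings must be positive", call. = FALSE)
  }
  if (any(rects$xmax <= rects$xmin) || any(rects$ymax <= rects$ymin)) {
    stop("every rectangle must have positive area", call. = FALSE)
  }
  structure(list(rects = rects[, need], row_spacing = row_spacing,
                 col_spacing = col_spacing, origin = as.numeric(origin)),
            class = "grid_spec")
}

#' Built-in orchard shapes
#'
#' Three one-hectare (10,000 m2) reference layouts at the standard 1.2 m x
#' 4 m planting pattern. `"square"` is the 100 m x 100 m block (2,184
#' trees). `"L"` and `"X"` are the package's own synthetic rectangle-union
#' defaults with the same total area: the L is a 60 x 80 m block with a
#' long thin 325 x 16 m top arm, the X a 40 m wide vertical bar crossed by
#' a 20 m tall horizontal bar. Any other decomposition can be supplied
#' directly to [grid_spec()].
#'
#' @param shape One of `"square"`, `"L"`, `"X"`.
#' @return A [grid_spec()].
#' @export
orchard_shape <- function(shape = c("square", "L", "X")) {
  shape <- match.arg(shape)
  rects <- switch(shape,
    square = data.frame(xmin = 0, xmax = 100, ymin = 0, ymax = 100),
    # 60*80 + 325*16 = 10,000 m2
    L = data.frame(xmin = c(0, 60), xmax = c(60, 385),
                   ymin = c(0, 64), ymax = c(80, 80)),
    # 40*200 + 140*20 - 40*20 = 10,000 m2
    X = data.frame(xmin = c(50, 0), xmax = c(90, 140),
                   ymin = c(0, 90), ymax = c(200, 110))
  )
  grid_spec(rects)
}

#' Generate the trees of a regular-grid orchard
#'
#' Enumerates every grid point of the spec's lattice that falls inside the
#' rectangle union (boundary inclusive, absolute tolerance 1e-9 m) and
#' labels them row-major: ids increase along x within a row, rows ordered
#' by increasing y.
#'
#' @param spec A [grid_spec()].
#' @return A [tree_set()].
#' @examples
#' square <- generate_grid(orchard_shape("square"))
#' n_trees(square)  # 2184
#' @export
generate_grid <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  tol <- 1e-9
  r <- spec$rects
  ix <- 0:floor((max(r$xmax) - spec$origin[1] + tol) / spec$row_spacing)
  iy <- 0:floor((max(r$ymax) - spec$origin[2] + tol) / spec$col_spacing)
  xs <- spec$origin[1] + ix * spec$row_spacing
  ys <- spec$origin[2] + iy * spec$col_spacing
  pts <- expand.grid(x = xs, y = ys)  # varies x fastest: row-major
  inside <- rep(FALSE, nrow(pts))
  for (k in seq_len(nrow(r))) {
    inside <- inside |
      (pts$x >= r$xmin[k] - tol & pts$x <= r$xmax[k] + tol &
       pts$y >= r$ymin[k] - tol & pts$y <= r$ymax[k] + tol)
  }
  pts <- pts[inside, , drop = FALSE]
  if (nrow(pts) == 0L) {
    stop("no trees generated: shape too small for the grid spacing",
         call. = FALSE)
  }
  tree_set(pts$x, pts$y)
}

#' Random orchard specification and generator
#'
#' Emulates an irregular planting that still respects the grower's minimum
#' spacings: rows of trees at y-positions at least `min_col_gap` apart, and
#' within each row x-positions at least `min_row_gap` apart. Tree counts
#' are spread over the rows at random; positions are drawn uniformly
#' subject to the gap constraints. The draw is deterministic given `seed`.
#'
#' @param n_trees Number of trees to place.
#' @param width,height Orchard extent in meters.
#' @param min_row_gap Minimum within-row spacing in meters (default 1.2).
#' @param min_col_gap Minimum between-row spacing in meters (default 4).
#' @param seed Integer RNG seed.
#' @return `random_orchard_spec()` returns a spec object;
#'   `generate_random()` returns a [tree_set()] with ids row-major.
#' @examples
#' ts <- generate_random(random_orchard_spec(50, 100, 100, seed = 7))
#' @export
random_orchard_spec <- function(n_trees, width = 100, height = 100,
                                min_row_gap = 1.2, min_col_gap = 4,
                                seed = 1L) {
  stopifnot(n_trees >= 1, width > 0, height > 0,
            min_row_gap > 0, min_col_gap > 0)
  structure(list(n_trees = as.integer(n_trees), width = width,
                 height = height, min_row_gap = min_row_gap,
                 min_col_gap = min_col_gap, seed = as.integer(seed)),
            class = "random_orchard_spec")
}

#' @rdname random_orchard_spec
#' @param spec A `random_orchard_spec`.
#' @export
generate_random <- function(spec) {
  stopifnot(inherits(spec, "random_orchard_spec"))
  n <- spec$n_trees
  cap <- floor(spec$width / spec$min_row_gap) + 1L    # trees per row at most
  max_rows <- floor(spec$height / spec$min_col_gap) + 1L
  if (n > cap * max_rows) {
    stop(sprintf(
      "density infeasible: %d trees exceed capacity %d under the spacing gaps",
      n, cap * max_rows), call. = FALSE)
  }
  set.seed(spec$seed)
  nr <- min(max_rows, n)
  # spread trees over rows, then push any overflow into rows with slack
  counts <- tabulate(sample.int(nr, n, replace = TRUE), nbins = nr)
  while (any(counts > cap)) {
    over <- which.max(counts)
    under <- which(counts < cap)
    move <- min(counts[over] - cap, cap - counts[under[1L]])
    counts[over] <- counts[over] - move
    counts[under[1L]] <- counts[under[1L]] + move
  }
  # gap-respecting uniform positions: sorted uniforms plus cumulative gaps
  gap_positions <- function(k, extent, gap) {
    sort(stats::runif(k, 0, extent - (k - 1) * gap)) + (0:(k - 1)) * gap
  }
  row_y <- gap_positions(nr, spec$height, spec$min_col_gap)
  xs <- numeric(0); ys <- numeric(0)
  for (r in seq_len(nr)) {
    if (counts[r] == 0L) next
    rx <- gap_positions(counts[r], spec$width, spec$min_row_gap)
    xs <- c(xs, rx)
    ys <- c(ys, rep(row_y[r], counts[r]))
  }
  ord <- order(ys, xs)
  tree_set(xs[ord], ys[ord])
}

#' Variable counts of the placement formulations
#'
#' The full binary assignment formulation of the placement problem (one
#' site variable per tree plus one assignment variable per tree pair) has
#' `n^2 + n` variables, which is what makes a one-hectare orchard
#' intractable for exact solvers; the reduced tree-index encoding used by
#' the evolutionary solver has only `2p` variables for `p` aids.
#'
#' @param n Number of trees.
#' @param p Maximum number of aids.
#' @return Integer-valued variable count.
#' @examples
#' binary_model_size(2184)  # 4772040
#' @export
binary_model_size <- function(n) as.numeric(n)^2 + as.numeric(n)

#' @rdname binary_model_size
#' @export
reduced_model_size <- function(p) 2 * as.numeric(p)
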