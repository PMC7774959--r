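# Shared fixtures and independent oracles for the test suite.

# random point-set orchard without spacing structure, for oracle tests
random_trees <- function(n, width = 100, height = 100, seed = 1) {
  set.seed(seed)
  repeat {
    x <- round(runif(n, 0, width), 3)
    y <- round(runif(n, 0, height), 3)
    if (!anyDuplicated(cbind(x, y))) return(tree_set(x, y))
  }
}

# the four aid positions printed for the one-hectare square orchard
square_printed_aids <- function(trees) {
  match_tree(trees, list(c(24, 76), c(74.4, 76), c(24, 24), c(75.6, 24)))
}

match_tree <- function(trees, coords, tol = 1e-6) {
  vapply(coords, function(p) {
    d2 <- (trees$x - p[1])^2 + (trees$y - p[2])^2
    i <- which.min(d2)
    stopifnot(d2[i] <= tol^2)
    i
  }, integer(1))
}

# double-loop nearest-aid assignment, independent of the vectorized path
brute_assignment <- function(trees, aids) {
  n <- nrow(trees)
  slot <- integer(n)
  dist <- numeric(n)
  for (j in seq_len(n)) {
    best <- Inf; bs <- 0L
    for (k in seq_along(aids)) {
      d <- sqrt((trees$x[j] - trees$x[aids[k]])^2 +
                (trees$y[j] - trees$y[aids[k]])^2)
      if (d < best) { best <- d; bs <- k }   # strict <: lowest slot wins ties
    }
    slot[j] <- bs; dist[j] <- best
  }
  list(slot = slot, dist = dist, total = sum(dist))
}

# z_k marking: an aid slot is "used" iff it is the (lowest-slot) nearest
# aid of at least one tree
brute_effective_count <- function(trees, aids) {
  length(unique(brute_assignment(trees, aids)$slot))
}

# exact set covering by bitmask enumeration over all 2^n subsets,
# independent of the package's size-ordered combn enumeration
bitmask_min_aids <- function(trees, K) {
  n <- nrow(trees)
  stopifnot(n <= 16)
  D2 <- outer(trees$x, trees$x, "-")^2 + outer(trees$y, trees$y, "-")^2
  cov <- D2 <= K^2
  best <- n + 1L
  for (m in 1:(2^n - 1)) {
    s <- which(bitwAnd(m, 2^(0:(n - 1))) > 0)
    if (length(s) >= best) next
    if (all(colSums(cov[s, , drop = FALSE]) > 0)) best <- length(s)
  }
  best
}

# exact capped p-median by bitmask enumeration
bitmask_p_median <- function(trees, p, K) {
  n <- nrow(trees)
  stopifnot(n <= 16)
  best <- Inf
  for (m in 1:(2^n - 1)) {
    s <- which(bitwAnd(m, 2^(0:(n - 1))) > 0)
    if (length(s) != p) next
    a <- brute_assignment(trees, s)
    if (max(a$dist) > K) next
    if (a$total < best) best <- a$total
  }
  best
}
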