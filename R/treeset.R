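#' Tree coordinate sets
#'
#' A `tree_set` is the universe of the placement problem: every tree is both
#' a demand point (it must be pollinated) and a candidate site for a nesting
#' aid. It is a data frame with columns `id`, `x`, `y` (meters), where ids
#' are consecutive integers `1..n` and no two trees share coordinates.
#'
#' @param x,y Numeric vectors of planar coordinates in meters. Must be
#'   finite and non-negative.
#' @param ids Integer tree labels; defaults to `1..n` in input order and
#'   must be exactly the consecutive sequence `1..n` (in any order).
#' @return An object of class `tree_set` (also a `data.frame`), sorted by id.
#' @examples
#' ts <- tree_set(c(0, 3, 10), c(0, 0, 0))
#' n_trees(ts)
#' @export
tree_set <- function(x, y, ids = seq_along(x)) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  ids <- as.integer(ids)
  if (length(x) != length(y) || length(x) != length(ids)) {
    stop("x, y and ids must have equal length", call. = FALSE)
  }
  df <- data.frame(id = ids, x = x, y = y)
  df <- df[order(df$id), , drop = FALSE]
  rownames(df) <- NULL
  validate_tree_set(structure(df, class = c("tree_set", "data.frame")))
}

validate_tree_set <- function(ts) {
  n <- nrow(ts)
  if (n < 1L) stop("a tree_set needs at least one tree", call. = FALSE)
  if (!identical(as.integer(ts$id), seq_len(n))) {
    stop("tree ids must be unique and consecutive from 1", call. = FALSE)
  }
  if (!all(is.finite(ts$x)) || !all(is.finite(ts$y))) {
    bad <- which(!is.finite(ts$x) | !is.finite(ts$y))
    stop("non-finite coordinates at row(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(ts$x < 0) || any(ts$y < 0)) {
    stop("coordinates must be non-negative (meters from the orchard origin)",
         call. = FALSE)
  }
  if (anyDuplicated(ts[, c("x", "y")])) {
    stop("two trees share identical coordinates", call. = FALSE)
  }
  ts
}

#' @rdname tree_set
#' @param ts A `tree_set`.
#' @export
n_trees <- function(ts) nrow(ts)

#' @export
print.tree_set <- function(x, ...) {
  cat(sprintf("<tree_set> %d trees, extent [%.6g, %.6g] x [%.6g, %.6g] m\n",
              nrow(x), min(x$x), max(x$x), min(x$y), max(x$y)))
  invisible(x)
}

#' Read and write tree coordinate files
#'
#' CSV files use the header `id,x,y` (meters, "." decimal separator); a CSV
#' without an `id` column gets ids `1..n` assigned in file order. XLSX files
#' are read from the first sheet with the header row auto-detected, so the
#' coordinate supplements distributed with orchard studies can be loaded
#' directly (requires the readxl package).
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"xlsx"`.
#' @return `read_treeset()` returns a [tree_set()]; `write_treeset()`
#'   returns `path` invisibly. A CSV round trip preserves ids and
#'   coordinates bit-exactly.
#' @export
read_treeset <- function(path, format = c("auto", "csv", "xlsx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv"
  }
  df <- if (format == "csv") read_treeset_csv(path) else read_treeset_xlsx(path)
  tree_set(df$x, df$y, df$id)
}

read_treeset_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, fill = TRUE)
  nms <- tolower(names(raw))
  if (all(c("x", "y") %in% nms)) {
    xs <- raw[[match("x", nms)]]
    ys <- raw[[match("y", nms)]]
    ids <- if ("id" %in% nms) raw[[match("id", nms)]] else seq_along(xs)
  } else if (ncol(raw) >= 2L) {
    xs <- raw[[1L]]
    ys <- raw[[2L]]
    ids <- seq_along(xs)
  } else {
    stop("need columns id,x,y or at least two coordinate columns in ", path,
         call. = FALSE)
  }
  as_coord_frame(ids, xs, ys, path)
}

read_treeset_xlsx <- function(path) {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    stop("reading xlsx requires the 'readxl' package", call. = FALSE)
  }
  raw <- readxl::read_excel(path, sheet = 1L, col_names = FALSE,
                            col_types = "text", .name_repair = "minimal")
  raw <- as.data.frame(raw, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("need at least two columns in ", path, call. = FALSE)
  num <- function(v) suppressWarnings(as.numeric(v))
  # header rows hold labels, not numbers: skip until two numeric columns appear
  numeric_row <- function(i) sum(!is.na(num(unlist(raw[i, ])))) >= 2L
  first <- 1L
  while (first <= nrow(raw) && !numeric_row(first)) first <- first + 1L
  if (first > nrow(raw)) stop("no numeric coordinate rows found in ", path,
                              call. = FALSE)
  header <- if (first > 1L) tolower(as.character(unlist(raw[first - 1L, ]))) else character()
  body <- raw[first:nrow(raw), , drop = FALSE]
  pick <- function(label, fallback) {
    i <- match(label, header)
    if (is.na(i)) fallback else i
  }
  numeric_cols <- which(vapply(body, function(v) all(!is.na(num(v))), logical(1)))
  if (length(numeric_cols) < 2L) {
    stop("fewer than two fully numeric columns in ", path, call. = FALSE)
  }
  if (all(c("x", "y") %in% header)) {
    xi <- pick("x", numeric_cols[1L]); yi <- pick("y", numeric_cols[2L])
    idi <- pick("id", NA_integer_)
  } else if (length(numeric_cols) >= 3L) {
    idi <- numeric_cols[1L]; xi <- numeric_cols[2L]; yi <- numeric_cols[3L]
  } else {
    idi <- NA_integer_; xi <- numeric_cols[1L]; yi <- numeric_cols[2L]
  }
  xs <- num(body[[xi]]); ys <- num(body[[yi]])
  ids <- if (is.na(idi)) seq_along(xs) else num(body[[idi]])
  as_coord_frame(ids, xs, ys, path)
}

as_coord_frame <- function(ids, xs, ys, path) {
  to_num <- function(v) suppressWarnings(as.numeric(v))
  xs <- to_num(xs); ys <- to_num(ys); ids <- to_num(ids)
  bad <- which(is.na(xs) | is.na(ys) | is.na(ids))
  if (length(bad)) {
    stop(sprintf("non-numeric or missing values in %s at data row(s) %s",
                 path, paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate tree ids in %s (first at data row %d)",
                 path, which(duplicated(ids))[1L]), call. = FALSE)
  }
  data.frame(id = ids, x = xs, y = ys)
}

#' @rdname read_treeset
#' @param ts A [tree_set()] to write.
#' @export
write_treeset <- function(ts, path, format = c("csv")) {
  format <- match.arg(format)
  stopifnot(inherits(ts, "tree_set"))
  df <- data.frame(id = ts$id, x = ts$x, y = ts$y)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
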