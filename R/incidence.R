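#' Binary bipartite incidence matrix
#'
#' Construct an `incidence_matrix`, the central data structure of nestpack:
#' an N x M binary matrix `B` whose element `B[i, a]` is 1 ("filled") if
#' row-node `i` (e.g. a plant or a country) interacts with column-node `a`
#' (e.g. a pollinator or a product), and 0 ("empty") otherwise.
#'
#' @param x a numeric matrix; values are binarized with `x > threshold`.
#' @param row_labels,col_labels optional character labels; default to the
#'   dimnames of `x` or `r1..rN` / `c1..cM`. Must be unique within a side.
#' @param threshold binarization threshold: entries strictly greater than
#'   this become links. Default 0, so any positive interaction count is a
#'   link (web-of-life matrices often carry visit counts).
#'
#' @return an `incidence_matrix`: an integer matrix of 0/1 with unique
#'   dimnames and class `"incidence_matrix"`.
#' @seealso [fill_density()], [drop_empty()], [degree_ranking()],
#'   [temperature()]
#' @export
#' @examples
#' m <- incidence_matrix(matrix(c(3, 0, 0, 1), 2, 2))
#' fill_density(m)
incidence_matrix <- function(x, row_labels = NULL, col_labels = NULL,
                             threshold = 0) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop("incidence matrix needs at least one row and one column", call. = FALSE)
  }
  if (anyNA(x)) stop("incidence matrix entries must not be NA", call. = FALSE)
  if (is.null(row_labels)) {
    row_labels <- rownames(x)
    if (is.null(row_labels)) row_labels <- paste0("r", seq_len(nrow(x)))
  }
  if (is.null(col_labels)) {
    col_labels <- colnames(x)
    if (is.null(col_labels)) col_labels <- paste0("c", seq_len(ncol(x)))
  }
  row_labels <- as.character(row_labels)
  col_labels <- as.character(col_labels)
  if (length(row_labels) != nrow(x) || length(col_labels) != ncol(x)) {
    stop("label length does not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(row_labels)) stop("duplicate row labels", call. = FALSE)
  if (anyDuplicated(col_labels)) stop("duplicate column labels", call. = FALSE)
  b <- matrix(as.integer(x > threshold), nrow(x), ncol(x),
              dimnames = list(row_labels, col_labels))
  class(b) <- c("incidence_matrix", class(b))
  b
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat(sprintf("incidence_matrix: %d x %d, L = %d, fill = %.4f\n",
              nrow(x), ncol(x), sum(x), fill_density(x)))
  y <- unclass(x)
  if (nrow(y) > 12L) y <- y[seq_len(12L), , drop = FALSE]
  if (ncol(y) > 16L) y <- y[, seq_len(16L), drop = FALSE]
  print(y, ...)
  if (nrow(x) > 12L || ncol(x) > 16L) cat("...\n")
  invisible(x)
}

stopifnot_incidence <- function(m) {
  if (!inherits(m, "incidence_matrix")) {
    stop("expected an `incidence_matrix`; see incidence_matrix() or read_incidence()",
         call. = FALSE)
  }
  invisible(m)
}

#' Fill (density) of an incidence matrix
#'
#' The fraction of realized links, `Phi = L / (N * M)` where `L` is the
#' number of 1-entries.
#'
#' @param m an [incidence_matrix()].
#' @return a number in `[0, 1]`.
#' @export
fill_density <- function(m) {
  stopifnot_incidence(m)
  sum(m) / (nrow(m) * ncol(m))
}

#' Read an incidence matrix from a file
#'
#' Two dialects are supported. `"matrix-csv"` is the labelled-matrix export
#' used by the web-of-life.es project: first row = column labels, first
#' column = row labels, numeric cells. `"edge-list"` is a TSV with columns
#' `row_label`, `col_label` and an optional `weight` (missing weight = 1).
#'
#' @param path path to the file.
#' @param dialect `"matrix-csv"` (default) or `"edge-list"`.
#' @param threshold binarization threshold passed to [incidence_matrix()].
#' @param transpose if `TRUE`, swap rows and columns after reading. Whether
#'   a file stores plants as rows or as columns varies between datasets, so
#'   this is an explicit flag rather than a guess.
#' @param sep field separator for `matrix-csv` (default `","`).
#' @return an [incidence_matrix()].
#' @export
read_incidence <- function(path, dialect = c("matrix-csv", "edge-list"),
                           threshold = 0, transpose = FALSE, sep = ",") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "matrix-csv") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 2L) {
      stop("parse error: need a header row and at least one data row in ", path,
           call. = FALSE)
    }
    parts <- strsplit(lines, sep, fixed = TRUE)
    header <- trimws(parts[[1L]])
    # tolerate both an empty and a named top-left header cell
    col_labels <- if (length(header) == length(parts[[2L]])) header[-1L] else header
    body <- parts[-1L]
    widths <- lengths(body)
    if (any(widths != length(col_labels) + 1L)) {
      stop("format error: ragged rows in ", path, call. = FALSE)
    }
    row_labels <- trimws(vapply(body, `[[`, "", 1L))
    cells <- suppressWarnings(
      vapply(body, function(p) as.numeric(trimws(p[-1L])),
             numeric(length(col_labels)))
    )
    if (anyNA(cells)) stop("parse error: non-numeric cell in ", path, call. = FALSE)
    raw <- t(matrix(cells, nrow = length(col_labels)))
  } else {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("row", "col", "weight")[
                              seq_len(max(count_edge_list_cols(path), 2L))],
                            colClasses = NA, stringsAsFactors = FALSE)
    if (nrow(df) == 0L) stop("parse error: empty edge list ", path, call. = FALSE)
    w <- if ("weight" %in% names(df)) as.numeric(df$weight) else rep(1, nrow(df))
    if (anyNA(w)) stop("parse error: non-numeric weight in ", path, call. = FALSE)
    row_labels <- unique(as.character(df$row))
    col_labels <- unique(as.character(df$col))
    raw <- matrix(0, length(row_labels), length(col_labels))
    i <- match(as.character(df$row), row_labels)
    j <- match(as.character(df$col), col_labels)
    raw[cbind(i, j)] <- raw[cbind(i, j)] + w
  }
  if (transpose) {
    raw <- t(raw)
    tmp <- row_labels; row_labels <- col_labels; col_labels <- tmp
  }
  incidence_matrix(raw, row_labels, col_labels, threshold = threshold)
}

count_edge_list_cols <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!length(first)) 0L else length(strsplit(first, "\t", fixed = TRUE)[[1L]])
}

#' Write an incidence matrix in matrix-csv dialect
#'
#' @param m an [incidence_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_incidence <- function(m, path) {
  stopifnot_incidence(m)
  header <- paste(c("", colnames(m)), collapse = ",")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], m[i, ]), collapse = ",")
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Strip empty rows and columns
#'
#' Removes all-zero rows and columns. Zero-degree nodes break both the
#' isocline construction (every line must hold at least one link) and the
#' fitness-complexity iteration (scores collapse), so they are stripped
#' before ranking and re-appended at the worst ranks when reporting.
#'
#' @param m an [incidence_matrix()].
#' @return a list with elements `matrix` (the stripped
#'   [incidence_matrix()]), `dropped_rows` and `dropped_cols` (character
#'   labels, possibly empty).
#' @export
drop_empty <- function(m) {
  stopifnot_incidence(m)
  if (sum(m) == 0L) stop("empty network: matrix has no links", call. = FALSE)
  keep_r <- rowSums(m) > 0L
  keep_c <- colSums(m) > 0L
  out <- incidence_matrix(unclass(m)[keep_r, keep_c, drop = FALSE])
  list(matrix = out,
       dropped_rows = rownames(m)[!keep_r],
       dropped_cols = colnames(m)[!keep_c])
}

#' Row/column ranking of a bipartite matrix
#'
#' A ranking assigns a rank position to every row and every column; rank 1
#' is the most generalist node, drawn top-left of the packed matrix.
#'
#' @param rows integer vector, `rows[i]` = rank position of input row `i`;
#'   must be a permutation of `1..N`.
#' @param cols integer vector for columns, a permutation of `1..M`.
#' @return an object of class `"ranking"`.
#' @export
ranking <- function(rows, cols) {
  rows <- as.integer(rows)
  cols <- as.integer(cols)
  if (!is_permutation(rows) || !is_permutation(cols)) {
    stop("rows and cols must each be a permutation of 1..N and 1..M",
         call. = FALSE)
  }
  structure(list(rows = rows, cols = cols), class = "ranking")
}

is_permutation <- function(x) {
  length(x) >= 1L && !anyNA(x) && all(sort(x) == seq_along(x))
}

#' @export
print.ranking <- function(x, ...) {
  cat(sprintf("ranking: %d rows, %d columns (rank 1 = most generalist)\n",
              length(x$rows), length(x$cols)))
  invisible(x)
}

#' Identity ranking for a matrix
#'
#' @param m an [incidence_matrix()].
#' @return a [ranking()] leaving the matrix in input order.
#' @export
identity_ranking <- function(m) {
  stopifnot_incidence(m)
  ranking(seq_len(nrow(m)), seq_len(ncol(m)))
}

#' Reorder a matrix according to a ranking
#'
#' @param x an [incidence_matrix()].
#' @param r a [ranking()] with matching dimensions.
#' @param ... unused.
#' @return the reordered [incidence_matrix()]; rank-1 row on top, rank-1
#'   column on the left. Fill and degree multisets are unchanged.
#' @export
reorder.incidence_matrix <- function(x, r, ...) {
  stopifnot_incidence(x)
  if (!inherits(r, "ranking")) stop("`r` must be a ranking", call. = FALSE)
  if (length(r$rows) != nrow(x) || length(r$cols) != ncol(x)) {
    stop("ranking dimensions do not match matrix", call. = FALSE)
  }
  out <- unclass(x)[order(r$rows), order(r$cols), drop = FALSE]
  incidence_matrix(out)
}

#' Rank rows and columns by degree
#'
#' Rows are ranked by decreasing row degree and columns by decreasing
#' column degree; ties are broken by original input index, so the result
#' is deterministic.
#'
#' @param m an [incidence_matrix()].
#' @return a [ranking()].
#' @export
degree_ranking <- function(m) {
  stopifnot_incidence(m)
  ranks_of <- function(deg) {
    idx <- order(-deg, seq_along(deg))
    r <- integer(length(deg))
    r[idx] <- seq_along(deg)
    r
  }
  ranking(ranks_of(rowSums(m)), ranks_of(colSums(m)))
}

#' Invert a ranking
#'
#' @param r a [ranking()].
#' @return the [ranking()] that undoes `r` when applied to the reordered
#'   matrix.
#' @export
invert_ranking <- function(r) {
  if (!inherits(r, "ranking")) stop("`r` must be a ranking", call. = FALSE)
  inv <- function(p) { q <- integer(length(p)); q[p] <- seq_along(p); q }
  # applying r puts input node i at position r[i]; the inverse ranking must
  # send position r[i] back to rank i, i.e. its rank vector is r^{-1}
  ranking(inv(r$rows), inv(r$cols))
}
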