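# Cache of per-geometry temperature grids. The isocline, the cell
# coordinates, the expected-fill mask and the per-cell (d/D)^2 weights
# depend only on (N, M, L), never on the ranking, so they are computed
# once per geometry and reused across the many evaluations a GA performs.
.grid_cache <- new.env(parent = emptyenv())

temperature_grid <- function(N, M, L, clip = FALSE) {
  key <- paste(N, M, L, clip, sep = "_")
  got <- .grid_cache[[key]]
  if (!is.null(got)) return(got)
  iso <- solve_isocline(N, M, L / (N * M))
  grid <- expand.grid(row_rank = seq_len(N), col_rank = seq_len(M))
  co <- cell_coordinates(grid$row_rank, grid$col_rank, N, M)
  expected_filled <- expected_filled_mask(iso, N, M)
  dd <- cell_distances(co$x, co$y, iso, clip = clip)
  weight <- matrix((dd$d / dd$D)^2, N, M)
  out <- list(iso = iso, expected_filled = expected_filled, weight = weight)
  .grid_cache[[key]] <- out
  out
}

# U for an already-reordered 0/1 matrix given its geometry grid
unexpectedness_ranked <- function(ranked, grid) {
  unexpected <- xor(ranked == 1L, grid$expected_filled)
  sum(grid$weight[unexpected]) / length(ranked)
}

#' Nestedness temperature of a ranked matrix
#'
#' Computes the unexpectedness
#' \deqn{U = \frac{1}{NM} \sum_{(i,\alpha) \in \mathcal{U}}
#'   \left(\frac{d_{i\alpha}}{D_{i\alpha}}\right)^2}
#' over the unexpected cells of the matrix reordered by `r`, and the
#' temperature `T = 100 * U / Umax` with `Umax = 0.04145`. `T` is 0 for a
#' perfectly nested ranked matrix and grows with disorder; it is not
#' clamped at 100.
#'
#' @param m an [incidence_matrix()] without empty rows or columns (use
#'   [drop_empty()] first) and with fill strictly between 0 and 1.
#' @param r a [ranking()]; defaults to [degree_ranking()] of `m`.
#' @param u_max normalization constant, fixed at 0.04145 by convention;
#'   configurable for research use only.
#' @param clip passed to [cell_distances()].
#' @return an object of class `"temperature_result"`: a list with `U`,
#'   `T`, `n_unexpected`, `p` (isocline shape parameter), `ranking`, and
#'   `unexpected` (the [classify_cells()] table augmented with `d`, `D`).
#' @export
#' @examples
#' m <- perfect_nested(nested_spec(8, 10, 0.4))
#' temperature(m)$T
temperature <- function(m, r = degree_ranking(m), u_max = 0.04145,
                        clip = FALSE) {
  stopifnot_incidence(m)
  if (any(rowSums(m) == 0L) || any(colSums(m) == 0L)) {
    stop("matrix has empty rows or columns; apply drop_empty() first",
         call. = FALSE)
  }
  N <- nrow(m); M <- ncol(m); L <- sum(m)
  if (L == N * M) stop("fully filled matrix has no isocline (fill = 1)",
                       call. = FALSE)
  grid <- temperature_grid(N, M, L, clip = clip)
  ranked <- reorder(m, r)
  unexpected <- xor(unclass(ranked) == 1L, grid$expected_filled)
  U <- sum(grid$weight[unexpected]) / (N * M)
  cells <- classify_cells(m, r, grid$iso)
  dd <- cell_distances(cells$x, cells$y, grid$iso, clip = clip)
  cells$d <- dd$d
  cells$D <- dd$D
  structure(list(U = U, T = 100 * U / u_max,
                 n_unexpected = sum(unexpected), p = grid$iso$p,
                 ranking = r, unexpected = cells),
            class = "temperature_result")
}

#' @export
print.temperature_result <- function(x, ...) {
  cat(sprintf("temperature: T = %.4f (U = %.6g, %d unexpected cells, p = %.4g)\n",
              x$T, x$U, x$n_unexpected, x$p))
  invisible(x)
}

#' Exact minimum temperature by exhaustive search
#'
#' Enumerates all `N! * M!` row/column ranking pairs; usable only on tiny
#' matrices and intended as an oracle for the heuristic rankers. Ties are
#' broken by lexicographic order of (row ranks, column ranks).
#'
#' @param m an [incidence_matrix()] without empty lines; guarded by
#'   `N! * M! <= 1e6`.
#' @return a list with `ranking` (the optimal [ranking()]) and `T`.
#' @export
brute_force_min_temperature <- function(m) {
  stopifnot_incidence(m)
  N <- nrow(m); M <- ncol(m)
  if (factorial(N) * factorial(M) > 1e6) {
    stop("search space exceeds 1e6 ranking pairs", call. = FALSE)
  }
  if (any(rowSums(m) == 0L) || any(colSums(m) == 0L)) {
    stop("matrix has empty rows or columns; apply drop_empty() first",
         call. = FALSE)
  }
  grid <- temperature_grid(N, M, sum(m))
  b <- unclass(m)
  row_perms <- all_permutations(N)
  col_perms <- all_permutations(M)
  best_u <- Inf
  best <- NULL
  for (i in seq_len(nrow(row_perms))) {
    pr <- row_perms[i, ]
    br <- b[pr, , drop = FALSE]
    for (j in seq_len(nrow(col_perms))) {
      pc <- col_perms[j, ]
      u <- unexpectedness_ranked(br[, pc, drop = FALSE], grid)
      if (u < best_u - 1e-15) {
        best_u <- u
        best <- list(pr = pr, pc = pc)
      }
    }
  }
  # perms list rows in rank order; convert to rank vectors
  rows <- integer(N); rows[best$pr] <- seq_len(N)
  cols <- integer(M); cols[best$pc] <- seq_len(M)
  list(ranking = ranking(rows, cols), T = 100 * best_u / 0.04145)
}

# all permutations of 1..n in lexicographic order, one per matrix row
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  k <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    idx <- k:(k + nrow(sub) - 1L)
    out[idx, 1L] <- first
    out[idx, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    k <- k + nrow(sub)
  }
  out
}
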