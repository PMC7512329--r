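#' Line of perfect nestedness (isocline)
#'
#' The ranked matrix is mapped onto the unit square (see
#' [cell_coordinates()]); a matrix of the same size and fill that is
#' perfectly nested is separated into a filled and an empty region by the
#' isocline
#' \deqn{f(x;p) = \frac{0.5}{N} + \frac{N-1}{N}\,
#'   \left[1 - \left(1 - \frac{Mx - 0.5}{M - 1}\right)^p\right]^{1/p}}
#' for `x` in the band `[0.5/M, (M-0.5)/M]`, extended flat to the edges of
#' the unit square. The single shape parameter `p > 0` is calibrated so
#' that the area *above* the curve (the expected-filled region, holding
#' the generalist corner at top-left) equals the fill `Phi`.
#'
#' @param N,M matrix dimensions, both at least 2 (the shape function has
#'   `M - 1` in a denominator).
#' @param fill target fill `Phi`, strictly between 0 and 1 and within the
#'   range attainable at this size (a 2 x 2 matrix, for instance, cannot
#'   have an isocline area of 0.05).
#' @param tol area-matching tolerance (default 1e-8).
#' @return an object of class `"isocline"` with fields `p`, `n_rows`,
#'   `n_cols`, `fill` (the calibrated area) and `target_fill`.
#' @export
#' @examples
#' iso <- solve_isocline(10, 10, 0.3)
#' iso$p
solve_isocline <- function(N, M, fill, tol = 1e-8) {
  if (N < 2 || M < 2) {
    stop("isocline requires N >= 2 and M >= 2 (shape function undefined below)",
         call. = FALSE)
  }
  if (!(fill > 0 && fill < 1)) stop("fill must be in (0, 1)", call. = FALSE)
  area <- function(p) isocline_area(N, M, p)
  lo <- 1e-4; hi <- 1e4
  # area above the curve is strictly decreasing in p: expand geometrically
  # if the target fill is not bracketed at the default bracket
  for (k in 1:4) {
    if (area(lo) >= fill && area(hi) <= fill) break
    lo <- lo / 100; hi <- hi * 100
  }
  a_lo <- area(lo); a_hi <- area(hi)
  if (!(a_lo >= fill && a_hi <= fill)) {
    stop(sprintf(paste0("fill %.4f not attainable for a %d x %d isocline ",
                        "(attainable range approximately [%.4f, %.4f])"),
                 fill, N, M, a_hi, a_lo), call. = FALSE)
  }
  root <- stats::uniroot(function(p) area(p) - fill, c(lo, hi),
                         tol = 1e-12, maxiter = 2000L)
  p <- root$root
  a <- area(p)
  if (abs(a - fill) > tol) {
    # uniroot's x-tolerance occasionally leaves residual area error where
    # the area curve is flat; polish with a few bisection steps on area
    plo <- p / 2; phi <- p * 2
    while (area(plo) < fill) plo <- plo / 2
    while (area(phi) > fill) phi <- phi * 2
    for (k in 1:200) {
      p <- sqrt(plo * phi)
      a <- area(p)
      if (abs(a - fill) <= tol) break
      if (a > fill) plo <- p else phi <- p
    }
  }
  structure(list(p = p, n_rows = as.integer(N), n_cols = as.integer(M),
                 fill = a, target_fill = fill),
            class = "isocline")
}

#' @export
print.isocline <- function(x, ...) {
  cat(sprintf("isocline: N = %d, M = %d, fill = %.6f, p = %.6g\n",
              x$n_rows, x$n_cols, x$fill, x$p))
  invisible(x)
}

# area of the unit square above the endpoint-extended shape function
isocline_area <- function(N, M, p) {
  x_lo <- 0.5 / M
  x_hi <- (M - 0.5) / M
  f_lo <- 0.5 / N
  f_hi <- (N - 0.5) / N
  band <- stats::integrate(function(x) shape_fn(x, N, M, p),
                           x_lo, x_hi, rel.tol = 1e-11, abs.tol = 1e-12,
                           subdivisions = 1000L)$value
  below <- x_lo * f_lo + band + (1 - x_hi) * f_hi
  1 - below
}

# raw shape function on the band [0.5/M, (M-0.5)/M]; vectorized in x
shape_fn <- function(x, N, M, p) {
  u <- (M * x - 0.5) / (M - 1)
  u <- pmin(pmax(u, 0), 1)
  # [1 - (1-u)^p]^(1/p) computed in log space to survive extreme p
  inner <- -expm1(p * log1p(-u))      # 1 - (1-u)^p, in [0,1]
  g <- ifelse(inner <= 0, 0, exp(log(inner) / p))
  0.5 / N + (N - 1) / N * g
}

#' Evaluate the isocline at x
#'
#' Returns `f(x; p)` on the band `[0.5/M, (M-0.5)/M]` and the constant
#' endpoint value outside it (flat extension to the unit-square edges).
#'
#' @param iso an [solve_isocline()] result.
#' @param x numeric vector in `[0, 1]`.
#' @return `f(x)`, same length as `x`.
#' @export
isocline_value <- function(iso, x) {
  stopifnot(inherits(iso, "isocline"))
  N <- iso$n_rows; M <- iso$n_cols
  xc <- pmin(pmax(x, 0.5 / M), (M - 0.5) / M)
  shape_fn(xc, N, M, iso$p)
}

#' Unit-square coordinates of a ranked cell
#'
#' Rescales rank positions to cell centers in the unit square: the column
#' ranks run left to right (`x = (col_rank - 0.5)/M`, generalist column at
#' the left edge) and row ranks top to bottom in Cartesian orientation
#' (`y = (N - row_rank + 0.5)/N`, generalist row at the top, largest `y`).
#'
#' @param row_rank,col_rank rank positions (1 = most generalist); vectors
#'   are recycled against each other.
#' @param N,M matrix dimensions.
#' @return a list with numeric vectors `x` and `y`, strictly inside (0,1).
#' @export
cell_coordinates <- function(row_rank, col_rank, N, M) {
  if (any(row_rank < 1L | row_rank > N) || any(col_rank < 1L | col_rank > M)) {
    stop("rank out of range", call. = FALSE)
  }
  list(x = (col_rank - 0.5) / M, y = (N - row_rank + 0.5) / N)
}

#' Distances entering the unexpectedness statistic
#'
#' For a cell center `(x, y)`, a probe line of slope -1 is drawn through
#' the cell. `D` is the length between the probe line's intercepts with
#' the x- and y-axes, `sqrt(2) * (x + y)` -- taken literally from the axis
#' intercepts even when they fall outside the unit square (set
#' `clip = TRUE` to clip the probe segment at the unit square instead).
#' `d` is the distance from the cell to the intersection of the probe
#' line with the endpoint-extended isocline, located by bisection to
#' 1e-10; the isocline plus the probe coordinate is strictly increasing
#' along the line, so the intersection is unique.
#'
#' @param x,y numeric vectors of cell-center coordinates (same length).
#' @param iso an [solve_isocline()] result.
#' @param clip if `TRUE`, `D` is the probe-line chord inside the unit
#'   square rather than the literal axis-intercept distance. Default
#'   `FALSE`.
#' @return a list with numeric vectors `d` and `D`.
#' @export
cell_distances <- function(x, y, iso, clip = FALSE) {
  stopifnot(inherits(iso, "isocline"))
  if (length(x) == 0L) return(list(d = numeric(0), D = numeric(0)))
  s <- x + y
  D <- if (clip) sqrt(2) * (pmin(s, 1) - pmax(s - 1, 0)) else sqrt(2) * s
  # find u in [0, min(1, s)] with f_ext(u) + u = s; g is strictly increasing
  lo <- rep(0, length(x))
  hi <- pmin(1, s)
  g_lo <- isocline_value(iso, lo) + lo - s
  g_hi <- isocline_value(iso, hi) + hi - s
  if (any(g_lo > 1e-12) || any(g_hi < -1e-12)) {
    stop("probe line fails to intersect the extended isocline: calibration bug",
         call. = FALSE)
  }
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    g <- isocline_value(iso, mid) + mid - s
    below <- g < 0
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
    if (max(hi - lo) < 1e-12) break
  }
  u <- (lo + hi) / 2
  list(d = sqrt(2) * abs(x - u), D = D)
}

# expected-filled mask for all N x M cell centers; the comparison carries
# a small tolerance so that centers exactly on the line (the curve's two
# endpoint cells always are) land on the expected-filled side regardless
# of floating-point rounding -- their d is 0, so the choice cannot change
# the temperature
expected_filled_mask <- function(iso, N, M) {
  co <- cell_coordinates(rep(seq_len(N), M), rep(seq_len(M), each = N), N, M)
  matrix(co$y >= isocline_value(iso, co$x) - 1e-9, N, M)
}

#' Classify the unexpected cells of a ranked matrix
#'
#' A cell is expected-filled iff its center satisfies `y >= f(x)` (the
#' generalist-corner side of the isocline; centers exactly on the line
#' count as expected-filled and have `d = 0`, so the convention cannot
#' change the temperature). Unexpected cells are empty cells in the
#' expected-filled region and filled cells in the expected-empty region.
#'
#' @param m an [incidence_matrix()] (no empty rows/columns).
#' @param r a [ranking()] for `m`.
#' @param iso an isocline calibrated to this matrix's `N`, `M` and fill.
#' @return a data.frame with columns `row_rank`, `col_rank`, `kind`
#'   (`"absence-in-filled-region"` or `"presence-in-empty-region"`), `x`,
#'   `y`; zero rows if the ranked matrix is perfectly nested.
#' @export
classify_cells <- function(m, r, iso) {
  stopifnot_incidence(m)
  stopifnot(inherits(iso, "isocline"))
  if (iso$n_rows != nrow(m) || iso$n_cols != ncol(m) ||
      abs(iso$target_fill - fill_density(m)) > 1e-9) {
    stop("isocline was not calibrated for this matrix's size and fill",
         call. = FALSE)
  }
  ranked <- reorder(m, r)
  N <- nrow(m); M <- ncol(m)
  grid <- expand.grid(row_rank = seq_len(N), col_rank = seq_len(M))
  co <- cell_coordinates(grid$row_rank, grid$col_rank, N, M)
  expected_filled <- as.vector(expected_filled_mask(iso, N, M))
  filled <- ranked[cbind(grid$row_rank, grid$col_rank)] == 1L
  unexpected <- xor(filled, expected_filled)
  out <- grid[unexpected, , drop = FALSE]
  out$kind <- ifelse(filled[unexpected],
                     "presence-in-empty-region", "absence-in-filled-region")
  out$x <- co$x[unexpected]
  out$y <- co$y[unexpected]
  rownames(out) <- NULL
  out
}
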