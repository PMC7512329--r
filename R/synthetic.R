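#' Specification of a synthetic nested matrix
#'
#' @param n_rows,n_cols matrix dimensions, both >= 2.
#' @param fill target fill in (0, 1).
#' @param noise fraction `eta` in `[0, 1)` of links moved by fill-swaps
#'   in [noisy_nested()].
#' @param seed RNG seed (only [noisy_nested()] uses randomness).
#' @return a list of class `"nested_spec"`.
#' @export
nested_spec <- function(n_rows, n_cols, fill, noise = 0, seed = 1L) {
  if (n_rows < 2L || n_cols < 2L) stop("need n_rows, n_cols >= 2", call. = FALSE)
  if (!(fill > 0 && fill < 1)) stop("fill must be in (0, 1)", call. = FALSE)
  if (noise < 0 || noise >= 1) stop("noise must be in [0, 1)", call. = FALSE)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 fill = fill, noise = noise, seed = as.integer(seed)),
            class = "nested_spec")
}

#' Perfectly nested matrix consistent with the isocline
#'
#' Solves the isocline for (N, M, fill) and fills exactly the cells whose
#' centers lie in the expected-filled region (`y >= f(x)`), so the matrix
#' has zero temperature under the degree ranking by construction. Because
#' the temperature of a matrix is always judged against the isocline of
#' its *own* fill, the pattern must be a fixed point: its link count L
#' must reproduce itself when the curve is re-solved at L/(N*M). The
#' generator searches for the self-consistent link count nearest the
#' target, so the realized fill (attribute `"realized_fill"`) can deviate
#' from the target -- noticeably so at sparse fills and small sizes,
#' where fixed points are sparse. Row neighborhoods are nested: every
#' row's partner set is a subset of any higher-degree row's.
#'
#' @param spec a [nested_spec()].
#' @return an [incidence_matrix()].
#' @export
#' @examples
#' m <- perfect_nested(nested_spec(10, 15, 0.3))
#' temperature(m, degree_ranking(m))$T  # 0
.perfect_cache <- new.env(parent = emptyenv())

perfect_nested <- function(spec) {
  stopifnot(inherits(spec, "nested_spec"))
  N <- spec$n_rows; M <- spec$n_cols
  cache_key <- sprintf("%d_%d_%.12g", N, M, spec$fill)
  cached <- .perfect_cache[[cache_key]]
  if (!is.null(cached)) return(cached)
  count_filled <- function(fill) {
    if (!(fill > 0 && fill < 1)) return(NA_integer_)
    iso <- tryCatch(solve_isocline(N, M, fill), error = function(e) NULL)
    if (is.null(iso)) return(NA_integer_)
    sum(expected_filled_mask(iso, N, M))
  }
  # The matrix must be a fixed point of its own fill: the temperature of a
  # matrix with L links is judged against the isocline calibrated to
  # L/(N*M), so the link count k must reproduce itself when the curve is
  # re-solved at k/(N*M). Scan outward from the target for the nearest
  # self-consistent count.
  k_target <- max(1L, round(spec$fill * N * M))
  L <- NA_integer_
  count_cache <- new.env(parent = emptyenv())
  g <- function(k) {  # count(k) - k; crosses zero at a self-consistent count
    key <- as.character(k)
    got <- count_cache[[key]]
    if (is.null(got)) {
      got <- count_filled(k / (N * M))
      count_cache[[key]] <- got
    }
    if (is.na(got)) NA_integer_ else got - k
  }
  if (isTRUE(g(k_target) == 0L)) {
    L <- k_target
  } else {
    # count(k) grows with k at slope ~1, so g drifts slowly; bracket the
    # zero crossing by geometric expansion, close in by bisection, then
    # scan the remaining gap outward from the nearest candidate
    lo <- hi <- k_target
    step <- 8L
    while (isTRUE(g(lo) > 0L) && lo > 1L) { lo <- max(1L, lo - step); step <- step * 2L }
    step <- 8L
    while (isTRUE(g(hi) < 0L) && hi < N * M - 1L) { hi <- min(N * M - 1L, hi + step); step <- step * 2L }
    while (hi - lo > 32L) {
      mid <- (lo + hi) %/% 2L
      gm <- g(mid)
      if (is.na(gm)) break
      if (gm > 0L) lo <- mid else if (gm < 0L) hi <- mid else { L <- mid; break }
    }
    if (is.na(L)) {
      center <- (lo + hi) %/% 2L
      for (delta in 0:(N * M)) {
        for (cand in unique(c(center + delta, center - delta))) {
          if (cand >= 1L && cand < N * M && isTRUE(g(cand) == 0L)) {
            L <- cand
            break
          }
        }
        if (!is.na(L)) break
      }
    }
  }
  if (is.na(L)) {
    stop(sprintf(paste0("no self-consistent perfectly nested fill pattern ",
                        "exists for a %d x %d matrix (fills attainable by ",
                        "the isocline do not meet an integer link count); ",
                        "try a larger matrix"), N, M), call. = FALSE)
  }
  grid <- temperature_grid(N, M, L)
  m <- incidence_matrix(grid$expected_filled * 1L)
  attr(m, "realized_fill") <- L / (N * M)
  .perfect_cache[[cache_key]] <- m
  m
}

#' Noise-corrupted nested matrix at fixed fill
#'
#' Starts from [perfect_nested()] and performs `ceiling(noise * L)`
#' random fill-swaps, each moving one randomly chosen link to a randomly
#' chosen empty cell. The number of links L (hence the fill and the
#' isocline) is conserved exactly, so noise levels differ only in
#' ordering difficulty, not in fill.
#'
#' @param spec a [nested_spec()] with `noise > 0` (noise 0 returns the
#'   perfect matrix unchanged).
#' @return an [incidence_matrix()]; may contain empty rows/columns once
#'   noise moves the last link of a specialist (use [drop_empty()]
#'   downstream).
#' @export
noisy_nested <- function(spec) {
  stopifnot(inherits(spec, "nested_spec"))
  m <- perfect_nested(spec)
  L <- sum(m)
  n_swaps <- ceiling(spec$noise * L)
  if (n_swaps == 0L) return(m)
  if (L == length(m)) stop("no empty cells available for a swap", call. = FALSE)
  b <- unclass(m)
  withr::with_seed(spec$seed, {
    for (s in seq_len(n_swaps)) {
      ones <- which(b == 1L)
      zeros <- which(b == 0L)
      b[ones[sample.int(length(ones), 1L)]] <- 0L
      b[zeros[sample.int(length(zeros), 1L)]] <- 1L
    }
  })
  out <- incidence_matrix(b)
  attr(out, "realized_fill") <- attr(m, "realized_fill")
  out
}

#' Uniform random binary matrix at fixed fill
#'
#' Places exactly `round(fill * N * M)` links uniformly at random without
#' replacement; draws with empty rows or columns are rejected and redrawn
#' (bounded retries), so the result is always rankable.
#'
#' @param n_rows,n_cols dimensions.
#' @param fill target fill in (0, 1).
#' @param seed RNG seed.
#' @param max_retries redraw budget (default 1000).
#' @return an [incidence_matrix()] with `L = round(fill * N * M)`.
#' @export
random_matrix <- function(n_rows, n_cols, fill, seed = 1L, max_retries = 1000L) {
  if (!(fill > 0 && fill < 1)) stop("fill must be in (0, 1)", call. = FALSE)
  L <- round(fill * n_rows * n_cols)
  if (L < 1L) stop("fill too low: no links after rounding", call. = FALSE)
  withr::with_seed(seed, {
    for (try in seq_len(max_retries)) {
      b <- matrix(0L, n_rows, n_cols)
      b[sample.int(n_rows * n_cols, L)] <- 1L
      if (all(rowSums(b) > 0L) && all(colSums(b) > 0L)) {
        return(incidence_matrix(b))
      }
    }
  })
  stop("could not draw a matrix without empty lines in ", max_retries,
       " attempts; raise the fill", call. = FALSE)
}

#' Synthetic trade table with a nested capability structure
#'
#' Emulates a country-product export volume table whose underlying
#' capability mask is perfectly nested: `w[i, a] = c_i * p_a * exp(eps) *
#' mask[i, a]` with heavy-tailed (log-normal) country sizes `c_i` and
#' product sizes `p_a` and log-normal volume noise `eps` of the given
#' dispersion. Country sizes are sorted so that diversified countries are
#' large, and product sizes so that rare (sophisticated) products are
#' expensive, mirroring the empirical correlations. Off-mask volumes are
#' exactly zero, so RCA binarization can never create a link outside the
#' mask; on-mask links are approximately recovered. The
#' generalist-country x ubiquitous-product corner is systematically the
#' hardest to recover -- with product-form weights the top corner cell
#' always has RCA below 1 -- exactly as in real RCA matrices.
#'
#' @param n_rows,n_cols numbers of countries and products.
#' @param fill target fill of the capability mask.
#' @param dispersion standard deviation of the log-normal noise `eps`
#'   (default 0.25).
#' @param seed RNG seed.
#' @param size_sd standard deviation of the log-normal country size
#'   factors (default 1).
#' @param product_size_sd standard deviation of the log-normal product
#'   size factors (default 2; the heavier product tail concentrates trade
#'   value on rare products, which keeps RCA above 1 on most of the
#'   mask).
#' @return a [trade_matrix()]; the capability mask is attached as
#'   attribute `"mask"`.
#' @export
nested_trade_table <- function(n_rows, n_cols, fill, dispersion = 0.25,
                               seed = 1L, size_sd = 1, product_size_sd = 2) {
  # the capability mask is a one-shot nested pattern at the target fill;
  # unlike perfect_nested() it needs no fill fixed point, because the
  # binarized trade network is recalibrated to its own realized fill
  # whenever a temperature is computed
  iso <- solve_isocline(n_rows, n_cols, fill)
  mask <- incidence_matrix(expected_filled_mask(iso, n_rows, n_cols) * 1L)
  withr::with_seed(seed, {
    ci <- stats::rlnorm(n_rows, meanlog = 0, sdlog = size_sd)
    pa <- stats::rlnorm(n_cols, meanlog = 0, sdlog = product_size_sd)
    # diversified countries get the larger sizes, rare products the
    # higher values
    ci <- sort(ci, decreasing = TRUE)[rank(-rowSums(mask),
                                           ties.method = "first")]
    pa <- sort(pa)[rank(-colSums(mask), ties.method = "first")]
    eps <- matrix(stats::rnorm(n_rows * n_cols, 0, dispersion),
                  n_rows, n_cols)
    w <- outer(ci, pa) * exp(eps) * unclass(mask)
  })
  out <- trade_matrix(w)
  attr(out, "mask") <- mask
  out
}

#' Write a trade matrix as a long TSV
#'
#' Emits (country, product, value) rows for the non-zero volumes, the
#' format [read_trade_table()] reads back.
#'
#' @param t a [trade_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trade_table <- function(t, path) {
  stopifnot(inherits(t, "trade_matrix"))
  idx <- which(unclass(t) > 0, arr.ind = TRUE)
  df <- data.frame(country = rownames(t)[idx[, 1]],
                   product = colnames(t)[idx[, 2]],
                   value = t[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
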