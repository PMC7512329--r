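#' Weighted country-product trade matrix
#'
#' @param x a numeric matrix of non-negative export volumes (US dollars);
#'   rows are countries, columns are products.
#' @param row_labels,col_labels optional labels, as in
#'   [incidence_matrix()].
#' @return an object of class `"trade_matrix"`.
#' @export
trade_matrix <- function(x, row_labels = NULL, col_labels = NULL) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(x) || any(x < 0)) {
    stop("export volumes must be non-negative and not NA", call. = FALSE)
  }
  if (sum(x) <= 0) stop("total trade volume must be positive", call. = FALSE)
  if (is.null(row_labels)) {
    row_labels <- rownames(x) %||% paste0("country", seq_len(nrow(x)))
  }
  if (is.null(col_labels)) {
    col_labels <- colnames(x) %||% paste0("product", seq_len(ncol(x)))
  }
  if (anyDuplicated(row_labels) || anyDuplicated(col_labels)) {
    stop("duplicate labels", call. = FALSE)
  }
  dimnames(x) <- list(as.character(row_labels), as.character(col_labels))
  structure(x, class = c("trade_matrix", class(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a long-format trade table
#'
#' Accepts TSV with columns (country, product, value) or
#' (year, country, product, value); rows are aggregated by sum over any
#' remaining dimensions (e.g. importers), which is how per-destination
#' export records collapse to the country-product volume `w[i, a]`.
#'
#' @param path TSV path, no header.
#' @param year optional year filter (only for 4-column files).
#' @return a [trade_matrix()].
#' @export
read_trade_table <- function(path, year = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) == 4L) {
    names(df) <- c("year", "country", "product", "value")
    if (!is.null(year)) df <- df[df$year == year, , drop = FALSE]
  } else if (ncol(df) == 3L) {
    names(df) <- c("country", "product", "value")
  } else {
    stop("expected 3 or 4 tab-separated columns", call. = FALSE)
  }
  if (nrow(df) == 0L) stop("no records (after the year filter)", call. = FALSE)
  df$value <- as.numeric(df$value)
  if (anyNA(df$value)) stop("non-numeric trade value", call. = FALSE)
  countries <- unique(as.character(df$country))
  products <- unique(as.character(df$product))
  w <- matrix(0, length(countries), length(products),
              dimnames = list(countries, products))
  agg <- stats::aggregate(df$value,
                          by = list(country = as.character(df$country),
                                    product = as.character(df$product)),
                          FUN = sum)
  w[cbind(agg$country, agg$product)] <- agg$x
  trade_matrix(w)
}

#' Revealed comparative advantage
#'
#' `R[i, a] = w[i, a] * W / (w_i * w_a)`: the observed export volume of
#' product `a` by country `i` relative to the volume expected from the
#' country's total exports `w_i`, the product's world total `w_a`, and
#' the grand total `W`. Countries or products with zero total volume are
#' dropped (with a message) before the division.
#'
#' @param t a [trade_matrix()].
#' @return a numeric matrix of RCA values with the (possibly reduced)
#'   labels of `t`.
#' @export
rca <- function(t) {
  stopifnot(inherits(t, "trade_matrix"))
  w <- unclass(t)
  keep_r <- rowSums(w) > 0
  keep_c <- colSums(w) > 0
  if (!all(keep_r) || !all(keep_c)) {
    message(sprintf("dropping %d zero-volume countries and %d zero-volume products",
                    sum(!keep_r), sum(!keep_c)))
    w <- w[keep_r, keep_c, drop = FALSE]
  }
  W <- sum(w)
  wi <- rowSums(w)
  wa <- colSums(w)
  w * W / outer(wi, wa)
}

#' Binarize a trade matrix by revealed comparative advantage
#'
#' Keeps the link (i, a) iff `R[i, a] >= threshold` (inclusive, default
#' 1: the export volume at least matches its expectation), then strips
#' rows and columns left empty.
#'
#' @param t a [trade_matrix()].
#' @param threshold RCA threshold (default 1).
#' @return an [incidence_matrix()]; dropped labels are attached as
#'   attributes `"dropped_rows"` / `"dropped_cols"`.
#' @export
rca_binarize <- function(t, threshold = 1) {
  r <- rca(t)
  m <- incidence_matrix((r >= threshold) * 1L,
                        row_labels = rownames(r), col_labels = colnames(r))
  cleaned <- drop_empty(m)
  out <- cleaned$matrix
  attr(out, "dropped_rows") <- cleaned$dropped_rows
  attr(out, "dropped_cols") <- cleaned$dropped_cols
  out
}
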