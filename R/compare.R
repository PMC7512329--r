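#' Compare the ranking methods on one matrix
#'
#' Runs the degree ranking, the fitness-complexity algorithm and the
#' genetic algorithm on one matrix and records the temperature achieved
#' by each, the FCA/GA temperature ratio, and the Spearman correlations
#' between the FCA and GA rank vectors per side. `T_ga` is the minimum
#' over `ga_reps` independently seeded GA runs, since the GA is
#' stochastic and its per-run optimum varies.
#'
#' @param m an [incidence_matrix()]; empty rows/columns are stripped
#'   first.
#' @param id identifier recorded in the output row.
#' @param ga_reps number of GA repetitions (default 3).
#' @param seed base seed; GA repetition `k` runs with `seed + k - 1`.
#' @param delta_n FCA look-ahead window (default 10).
#' @param ga_control a [ga_config()] used as template for the GA runs
#'   (its `seed` field is overridden per repetition).
#' @return a one-row `data.frame` with columns `id`, `n_rows`, `n_cols`,
#'   `links`, `fill`, `t_degree`, `t_fca`, `n_star`, `t_ga`, `ratio`
#'   (`t_fca / t_ga`; defined as 1 when both are 0), `rho_rows`,
#'   `rho_cols`.
#' @export
compare_methods <- function(m, id = "matrix", ga_reps = 3L, seed = 1L,
                            delta_n = 10L, ga_control = ga_config()) {
  stopifnot_incidence(m)
  m <- drop_empty(m)$matrix
  t_degree <- temperature(m, degree_ranking(m))$T
  fca_r <- rank_by_fca(m, delta_n = delta_n)
  t_fca <- temperature(m, fca_r)$T
  n_star <- attr(fca_r, "state")$n_star
  best_ga <- NULL
  t_ga <- Inf
  for (k in seq_len(ga_reps)) {
    cfg <- ga_control
    cfg$seed <- as.integer(seed + k - 1L)
    fit <- ga_minimize(m, cfg)
    if (fit$result$T < t_ga) {
      t_ga <- fit$result$T
      best_ga <- fit$ranking
    }
  }
  ratio <- if (t_fca == 0 && t_ga == 0) 1 else t_fca / t_ga
  data.frame(id = id, n_rows = nrow(m), n_cols = ncol(m), links = sum(m),
             fill = fill_density(m), t_degree = t_degree, t_fca = t_fca,
             n_star = n_star, t_ga = t_ga, ratio = ratio,
             rho_rows = spearman_rho(fca_r$rows, best_ga$rows),
             rho_cols = spearman_rho(fca_r$cols, best_ga$cols),
             stringsAsFactors = FALSE)
}

#' Batch comparison over a directory or list of matrices
#'
#' Applies [compare_methods()] to every matrix and summarizes: the
#' fraction of matrices where the fitness-complexity temperature is at or
#' below the genetic-algorithm optimum, and the mean temperature ratio.
#'
#' @param x either a directory of matrix-csv files or a (optionally
#'   named) list of [incidence_matrix()] objects.
#' @param ga_reps,seed,delta_n,ga_control passed to [compare_methods()];
#'   matrix `k` uses base seed `seed + 1000 * (k - 1)`.
#' @param verbose print a progress line per matrix.
#' @return an object of class `"comparison_report"`: a list with
#'   `records` (row-bound [compare_methods()] output), `summary` (list
#'   with `n`, `fraction_fca_le_ga`, `fraction_fca_lt_ga`, `mean_ratio`)
#'   and `errors` (named character vector of per-matrix failures, if
#'   any).
#' @export
batch_compare <- function(x, ga_reps = 3L, seed = 1L, delta_n = 10L,
                          ga_control = ga_config(), verbose = FALSE) {
  if (is.character(x) && length(x) == 1L && dir.exists(x)) {
    paths <- list.files(x, pattern = "\\.(csv|txt)$", full.names = TRUE)
    mats <- list()
    for (p in paths) {
      m <- tryCatch(read_incidence(p), error = function(e) e)
      if (inherits(m, "error")) {
        warning("skipping unreadable file ", p, ": ", conditionMessage(m),
                call. = FALSE)
      } else {
        mats[[tools::file_path_sans_ext(basename(p))]] <- m
      }
    }
  } else if (is.list(x)) {
    mats <- x
    if (is.null(names(mats))) {
      names(mats) <- paste0("matrix", seq_along(mats))
    }
  } else {
    stop("`x` must be a directory path or a list of incidence matrices",
         call. = FALSE)
  }
  records <- list()
  errors <- character(0)
  for (k in seq_along(mats)) {
    id <- names(mats)[k]
    t0 <- Sys.time()
    rec <- tryCatch(
      compare_methods(mats[[k]], id = id, ga_reps = ga_reps,
                      seed = seed + 1000L * (k - 1L), delta_n = delta_n,
                      ga_control = ga_control),
      error = function(e) e)
    if (inherits(rec, "error")) {
      errors[id] <- conditionMessage(rec)
      warning("comparison failed for ", id, ": ", conditionMessage(rec),
              call. = FALSE)
    } else {
      records[[length(records) + 1L]] <- rec
      if (verbose) {
        message(sprintf("%s: T_deg=%.3f T_fca=%.3f T_ga=%.3f (%.2fs)",
                        id, rec$t_degree, rec$t_fca, rec$t_ga,
                        as.numeric(Sys.time() - t0, units = "secs")))
      }
    }
  }
  records <- if (length(records)) do.call(rbind, records) else
    data.frame()
  summary <- if (nrow(records)) {
    list(n = nrow(records),
         fraction_fca_le_ga = mean(records$t_fca <= records$t_ga),
         fraction_fca_lt_ga = mean(records$t_fca < records$t_ga),
         mean_ratio = mean(records$ratio))
  } else {
    list(n = 0L, fraction_fca_le_ga = NA_real_,
         fraction_fca_lt_ga = NA_real_, mean_ratio = NA_real_)
  }
  structure(list(records = records, summary = summary, errors = errors),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison_report: %d matrices\n", x$summary$n))
  if (x$summary$n > 0) {
    cat(sprintf("  fraction T_fca <= T_ga: %.4f\n", x$summary$fraction_fca_le_ga))
    cat(sprintf("  fraction T_fca <  T_ga: %.4f\n", x$summary$fraction_fca_lt_ga))
    cat(sprintf("  mean T_fca / T_ga ratio: %.4f\n", x$summary$mean_ratio))
  }
  if (length(x$errors)) {
    cat(sprintf("  %d matrices failed\n", length(x$errors)))
  }
  invisible(x)
}

#' Write a comparison report to CSV + JSON
#'
#' @param report a [batch_compare()] result.
#' @param prefix output path prefix; writes `<prefix>.csv` (records) and
#'   `<prefix>.json` (records + summary).
#' @return the two paths, invisibly.
#' @export
write_report <- function(report, prefix) {
  stopifnot(inherits(report, "comparison_report"))
  csv <- paste0(prefix, ".csv")
  json <- paste0(prefix, ".json")
  utils::write.csv(report$records, csv, row.names = FALSE)
  jsonlite::write_json(list(records = report$records,
                            summary = report$summary),
                       json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = json))
}
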