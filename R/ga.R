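#' Genetic-algorithm configuration
#'
#' Defaults for the BINMATNEST-style permutation GA: a steady-state,
#' elitist scheme whose chromosomes are row/column ranking pairs and
#' whose fitness is the negative nestedness temperature.
#'
#' @param population_size number of chromosomes (default 30, >= 2).
#' @param max_generations generation budget (default 500).
#' @param stagnation_limit stop after this many generations without
#'   improvement of the best temperature (default 100).
#' @param mutation_probability probability that an offspring side
#'   undergoes the cyclic-slice mutation (default 0.1).
#' @param copy_probability probability that crossover returns a plain
#'   copy of the well-performing parent (fixed at 1/2 by the algorithm's
#'   definition; exposed for completeness).
#' @param seed RNG seed for the whole run.
#' @param seeding character subset of `c("degree", "fca", "random")`:
#'   which rankings seed the initial population (the rest is filled with
#'   random permutations). The default, degree + random, keeps the GA
#'   independent of the fitness-complexity algorithm so that the two
#'   methods can be compared; add `"fca"` to warm-start the search when
#'   only the final packing matters.
#' @return a list of class `"ga_config"`.
#' @export
ga_config <- function(population_size = 30L, max_generations = 500L,
                      stagnation_limit = 100L, mutation_probability = 0.1,
                      copy_probability = 0.5, seed = 1L,
                      seeding = c("degree", "random")) {
  if (population_size < 2L) stop("population_size must be >= 2", call. = FALSE)
  if (!all(seeding %in% c("degree", "fca", "random")) || !length(seeding)) {
    stop("seeding must be a non-empty subset of degree/fca/random",
         call. = FALSE)
  }
  if (mutation_probability < 0 || mutation_probability > 1 ||
      copy_probability < 0 || copy_probability > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(population_size = as.integer(population_size),
                 max_generations = as.integer(max_generations),
                 stagnation_limit = as.integer(stagnation_limit),
                 mutation_probability = mutation_probability,
                 copy_probability = copy_probability,
                 seed = as.integer(seed), seeding = seeding),
            class = "ga_config")
}

#' Order-based crossover of two permutation sides
#'
#' With probability `copy_probability` the offspring is a plain copy of
#' the well-performing parent `w`. Otherwise a cut point `k` is drawn
#' uniformly from `1..N`; positions `1..k` are copied from `w`; each
#' later position takes its value from the partner `p` unless that value
#' already appeared in `w[1..k]`; the remaining positions are repaired,
#' in increasing position order, with the unused values in increasing
#' value order. The result is always a valid permutation.
#'
#' @param w,p integer permutations of the same length (well-performing
#'   and partner parent).
#' @param copy_probability probability of the plain-copy branch
#'   (default 0.5).
#' @return an integer permutation.
#' @export
ga_crossover <- function(w, p, copy_probability = 0.5) {
  n <- length(w)
  if (length(p) != n) stop("parent length mismatch", call. = FALSE)
  if (stats::runif(1) < copy_probability) return(w)
  k <- sample.int(n, 1L)
  o <- integer(n)
  o[seq_len(k)] <- w[seq_len(k)]
  head_vals <- w[seq_len(k)]
  if (k < n) {
    tail_idx <- (k + 1L):n
    take <- !(p[tail_idx] %in% head_vals)
    o[tail_idx[take]] <- p[tail_idx[take]]
    # setdiff keeps the increasing order of seq_len(n): repairs are the
    # unused values in increasing value order, at the open positions in
    # increasing position order
    o[tail_idx[!take]] <- setdiff(seq_len(n), o)
  }
  o
}

#' Cyclic-slice mutation of a permutation side
#'
#' With the given probability, draws `k1 < k2` uniformly and cyclically
#' permutes the slice `o[k1..k2]` (rotated by one position).
#'
#' @param o integer permutation.
#' @param probability mutation probability (default 0.1).
#' @return an integer permutation.
#' @export
ga_mutate <- function(o, probability = 0.1) {
  if (stats::runif(1) >= probability) return(o)
  n <- length(o)
  if (n < 2L) return(o)
  ks <- sample.int(n, 2L)
  if (ks[1L] > ks[2L]) ks <- ks[c(2L, 1L)]
  idx <- ks[1L]:ks[2L]
  o[idx] <- o[c(idx[length(idx)], idx[-length(idx)])]
  o
}

#' Minimize nestedness temperature with a genetic algorithm
#'
#' Evolves a population of ranking pairs. The initial population holds
#' the seed rankings named by `config$seeding` (degree by default; the
#' fitness-complexity ranking on request) plus random permutations up to
#' `population_size`. A generation is a population's
#' worth of reproduction events, each of which selects a well-performing
#' parent with linear rank weighting (lower temperature, higher weight)
#' and a uniform partner, applies [ga_crossover()] independently to the
#' row and column sides, then [ga_mutate()] to each side; the offspring
#' replaces the current worst chromosome if strictly better and not a
#' duplicate of a resident chromosome (elitist steady state with a
#' no-twins rule, which keeps the recombination pool diverse). Stops at
#' `max_generations` or after `stagnation_limit` generations without
#' improvement of the best temperature.
#'
#' @param m an [incidence_matrix()] without empty rows or columns.
#' @param config a [ga_config()].
#' @return a list with `ranking` (best-ever [ranking()]), `result` (its
#'   `temperature_result`), and `history` (numeric vector of best
#'   temperature after each generation; non-increasing).
#' @export
ga_minimize <- function(m, config = ga_config()) {
  stopifnot_incidence(m)
  stopifnot(inherits(config, "ga_config"))
  if (any(rowSums(m) == 0L) || any(colSums(m) == 0L)) {
    stop("matrix has empty rows or columns; apply drop_empty() first",
         call. = FALSE)
  }
  N <- nrow(m); M <- ncol(m)
  grid <- temperature_grid(N, M, sum(m))
  b <- unclass(m)
  # U * N * M = sum(w * E) + sum over links of w * (1 - 2E) at the link's
  # ranked position: only the L filled cells move with the ranking, so an
  # evaluation costs O(L) instead of O(N * M)
  u_const <- sum(grid$weight[grid$expected_filled])
  u_link <- grid$weight * (1 - 2 * grid$expected_filled)
  links <- which(b == 1L, arr.ind = TRUE)
  li <- links[, 1L]; la <- links[, 2L]
  nm <- N * M
  eval_u <- function(rows, cols) {
    (u_const + sum(u_link[cbind(rows[li], cols[la])])) / nm
  }
  withr::with_seed(config$seed, {
    pop_rows <- list()
    pop_cols <- list()
    if ("degree" %in% config$seeding) {
      deg_seed <- degree_ranking(m)
      pop_rows <- c(pop_rows, list(deg_seed$rows))
      pop_cols <- c(pop_cols, list(deg_seed$cols))
    }
    if ("fca" %in% config$seeding) {
      fca_seed <- rank_by_fca(m)
      pop_rows <- c(pop_rows, list(fca_seed$rows))
      pop_cols <- c(pop_cols, list(fca_seed$cols))
    }
    while (length(pop_rows) < config$population_size) {
      pop_rows[[length(pop_rows) + 1L]] <- sample.int(N)
      pop_cols[[length(pop_cols) + 1L]] <- sample.int(M)
    }
    u <- mapply(eval_u, pop_rows, pop_cols)
    chrom_key <- function(rows, cols) paste(c(rows, cols), collapse = ",")
    pop_keys <- mapply(chrom_key, pop_rows, pop_cols)
    best_idx <- which.min(u)
    best <- list(rows = pop_rows[[best_idx]], cols = pop_cols[[best_idx]],
                 u = u[best_idx])
    history <- numeric(0)
    stagnant <- 0L
    pop_size <- length(u)
    # linear rank weighting: best chromosome gets weight pop_size, worst 1;
    # the cumulative weights are refreshed only when the population changes
    weight_cdf <- function(u) {
      o <- order(u)
      weight <- integer(pop_size)
      weight[o] <- rev(seq_len(pop_size))
      cumsum(weight)
    }
    cdf <- weight_cdf(u)
    for (gen in seq_len(config$max_generations)) {
      improved <- FALSE
      # one generation = a population's worth of reproduction events,
      # each inserted steady-state
      for (rep in seq_len(config$population_size)) {
        w_idx <- findInterval(stats::runif(1) * cdf[pop_size], cdf) + 1L
        p_idx <- sample.int(pop_size, 1L)
        child_rows <- ga_mutate(
          ga_crossover(pop_rows[[w_idx]], pop_rows[[p_idx]],
                       config$copy_probability),
          config$mutation_probability)
        child_cols <- ga_mutate(
          ga_crossover(pop_cols[[w_idx]], pop_cols[[p_idx]],
                       config$copy_probability),
          config$mutation_probability)
        # no-twins rule: an offspring identical to a resident chromosome
        # would waste its evaluation (the copy branch of the crossover
        # produces many), so duplicates are replaced by random immigrants,
        # which keeps the recombination pool diverse
        child_key <- chrom_key(child_rows, child_cols)
        if (child_key %in% pop_keys) {
          child_rows <- sample.int(N)
          child_cols <- sample.int(M)
          child_key <- chrom_key(child_rows, child_cols)
        }
        child_u <- eval_u(child_rows, child_cols)
        worst <- which.max(u)
        if (child_u < u[worst]) {
          pop_rows[[worst]] <- child_rows
          pop_cols[[worst]] <- child_cols
          u[worst] <- child_u
          pop_keys[worst] <- child_key
          cdf <- weight_cdf(u)
        }
        if (child_u < best$u) {
          best <- list(rows = child_rows, cols = child_cols, u = child_u)
          improved <- TRUE
        }
      }
      stagnant <- if (improved) 0L else stagnant + 1L
      history <- c(history, 100 * best$u / 0.04145)
      if (stagnant >= config$stagnation_limit) break
    }
  })
  r <- ranking(best$rows, best$cols)
  list(ranking = r, result = temperature(m, r), history = history)
}

#' Genetic-algorithm ranking in one call
#'
#' @inheritParams ga_minimize
#' @return the best [ranking()] found; its `temperature_result` is
#'   attached as attribute `"result"`.
#' @export
rank_by_ga <- function(m, config = ga_config()) {
  fit <- ga_minimize(m, config)
  r <- fit$ranking
  attr(r, "result") <- fit$result
  r
}
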