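test_that("spearman correlation matches its definition", {
  expect_equal(spearman_rho(1:5, 1:5), 1)
  expect_equal(spearman_rho(1:5, 5:1), -1)
  expect_equal(spearman_rho(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_true(is.na(spearman_rho(c(1, 1, 1), c(1, 2, 3))))
  expect_error(spearman_rho(1:3, 1:4), "length")
  # ties use average ranks, as in the standard definition
  expect_equal(spearman_rho(c(1, 1, 2), c(1, 2, 3)),
               stats::cor(c(1, 1, 2), c(1, 2, 3), method = "spearman"))
})

test_that("the all-ones matrix is a fixed point of the iteration", {
  m <- incidence_matrix(matrix(1, 4, 6))
  s <- fca_step(m)
  expect_equal(unname(s$F), rep(1, 4))
  expect_equal(unname(s$Q), rep(1, 6))
})

test_that("one step from uniform scores reproduces the hand computation", {
  # B = {{1,1},{1,0}}: F~ = (2, 1) with mean 3/2; Q~ = (1/2, 1) with mean 3/4
  m <- im(1, 1,
          1, 0, nrow = 2)
  s <- fca_step(m)
  expect_equal(unname(s$F), c(4 / 3, 2 / 3), tolerance = 1e-12)
  expect_equal(unname(s$Q), c(2 / 3, 4 / 3), tolerance = 1e-12)
  expect_equal(s$n, 1L)
})

test_that("scores stay mean-normalized and non-negative along the run", {
  m <- drop_empty(noisy_nested(nested_spec(12, 9, 0.35, noise = 0.15,
                                           seed = 4)))$matrix
  s <- fca_init(m)
  for (k in 1:40) {
    s <- fca_step(m, s)
    expect_equal(mean(s$F), 1, tolerance = 1e-12)
    expect_equal(mean(s$Q), 1, tolerance = 1e-12)
    expect_true(all(s$F >= 0) && all(s$Q >= 0))
  }
})

test_that("the iteration is deterministic and scale-consistent", {
  m <- drop_empty(noisy_nested(nested_spec(10, 8, 0.3, noise = 0.1,
                                           seed = 9)))$matrix
  a <- fca_converge(m, delta_n = 10)
  b <- fca_converge(m, delta_n = 10)
  expect_identical(a$F, b$F)
  expect_identical(a$n_star, b$n_star)
  # renormalizing an already-normalized state changes nothing downstream
  s <- fca_iterate(m, 5)
  s_renorm <- s
  s_renorm$F <- s$F / mean(s$F)
  s_renorm$Q <- s$Q / mean(s$Q)
  expect_equal(fca_step(m, s)$F, fca_step(m, s_renorm)$F, tolerance = 1e-14)
})

test_that("convergence fires immediately on the all-ones matrix", {
  m <- incidence_matrix(matrix(1, 5, 5))
  s <- fca_converge(m, delta_n = 10)
  expect_true(s$converged)
  expect_equal(s$n_star, 1L)
})

test_that("the final ranking is stable across look-ahead windows", {
  m <- drop_empty(noisy_nested(nested_spec(20, 15, 0.3, noise = 0.1,
                                           seed = 12)))$matrix
  r10 <- rank_by_fca(m, delta_n = 10)
  r20 <- rank_by_fca(m, delta_n = 20)
  r30 <- rank_by_fca(m, delta_n = 30)
  expect_gt(spearman_rho(r10$rows, r20$rows), 0.99)
  expect_gt(spearman_rho(r10$rows, r30$rows), 0.99)
  expect_gt(spearman_rho(r10$cols, r30$cols), 0.99)
})

test_that("unconverged runs raise with the last correlations attached", {
  m <- drop_empty(noisy_nested(nested_spec(15, 12, 0.3, noise = 0.2,
                                           seed = 2)))$matrix
  expect_error(fca_converge(m, delta_n = 10, max_iter = 3), "converge")
})

test_that("on a strictly nested matrix the FCA ranking equals degree order", {
  m <- perfect_nested(nested_spec(20, 15, 0.3))
  keep <- drop_empty(m)$matrix
  # strictly decreasing degrees outside ties: compare reordered matrices
  fca_r <- rank_by_fca(keep)
  deg_r <- degree_ranking(keep)
  expect_identical(unname(unclass(reorder(keep, fca_r))),
                   unname(unclass(reorder(keep, deg_r))))
  expect_identical(temperature(keep, fca_r)$T, 0)
})

test_that("fca ranking orders by fitness with degree tie-breaks", {
  m <- staircase(5, 5)
  s <- fca_converge(m)
  r <- fca_ranking(s, m)
  expect_equal(r$rows, order(-s$F))
  # identical rows tie and keep input order
  b <- rbind(c(1L, 1L, 0L), c(1L, 1L, 0L), c(1L, 1L, 1L))
  m2 <- incidence_matrix(b)
  s2 <- fca_converge(m2)
  r2 <- fca_ranking(s2, m2)
  expect_equal(r2$rows[3], 1L)      # the full row is fittest
  expect_lt(r2$rows[1], r2$rows[2]) # tied rows keep input order
})

test_that("fca packs noisy-nested matrices colder than degree on balance", {
  t_f <- t_d <- numeric(50)
  for (s in 1:50) {
    m <- drop_empty(noisy_nested(nested_spec(30, 20, 0.25, noise = 0.1,
                                             seed = 200 + s)))$matrix
    t_f[s] <- temperature(m, rank_by_fca(m))$T
    t_d[s] <- temperature(m, degree_ranking(m))$T
  }
  expect_lt(mean(t_f), mean(t_d))
  # and on a clear majority of individual instances
  expect_gte(sum(t_f <= t_d + 1e-12), 30L)
})
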