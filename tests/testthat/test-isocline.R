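test_that("cell coordinates follow the unit-square convention", {
  co <- cell_coordinates(1, 1, 10, 10)
  expect_equal(co$x, 0.05)
  expect_equal(co$y, 0.95)
  co2 <- cell_coordinates(7, 5, 7, 5)
  expect_equal(co2$x, 1 - 0.5 / 5)
  expect_equal(co2$y, 0.5 / 7)
  co3 <- cell_coordinates(1, 1, 1, 1)
  expect_equal(co3$x, 0.5)
  expect_equal(co3$y, 0.5)
  expect_error(cell_coordinates(0, 1, 3, 3), "out of range")
})

test_that("shape function hits its fixed endpoints for any p", {
  for (p in c(0.01, 0.5, 1, 3, 50)) {
    iso <- structure(list(p = p, n_rows = 8L, n_cols = 11L,
                          fill = NA, target_fill = NA), class = "isocline")
    expect_equal(isocline_value(iso, 0.5 / 11), 0.5 / 8, tolerance = 1e-12)
    expect_equal(isocline_value(iso, 10.5 / 11), 7.5 / 8, tolerance = 1e-12)
    # flat extension beyond the band
    expect_equal(isocline_value(iso, 0), 0.5 / 8, tolerance = 1e-12)
    expect_equal(isocline_value(iso, 1), 7.5 / 8, tolerance = 1e-12)
    # monotone non-decreasing on a grid
    xs <- seq(0, 1, length.out = 201)
    expect_true(all(diff(isocline_value(iso, xs)) >= -1e-12))
  }
})

test_that("p = 1 shape values match direct substitution", {
  N <- 6; M <- 6
  iso <- structure(list(p = 1, n_rows = N, n_cols = M,
                        fill = NA, target_fill = NA), class = "isocline")
  x_mid <- (0.5 / M + (M - 0.5) / M) / 2
  # with p = 1 the bracketed term collapses to (Mx - 0.5)/(M - 1)
  by_hand <- 0.5 / N + (N - 1) / N * (M * x_mid - 0.5) / (M - 1)
  expect_equal(isocline_value(iso, x_mid), by_hand, tolerance = 1e-12)
})

test_that("solver recovers p = 1 from the p = 1 area", {
  N <- 9; M <- 13
  phi_p1 <- nestpack:::isocline_area(N, M, 1)
  iso <- solve_isocline(N, M, phi_p1)
  expect_equal(iso$p, 1, tolerance = 1e-6)
})

test_that("calibrated area matches the requested fill", {
  for (N in c(2, 5, 40)) {
    for (M in c(2, 7, 60)) {
      for (phi in c(0.15, 0.4, 0.65)) {
        iso <- tryCatch(solve_isocline(N, M, phi), error = function(e) e)
        if (inherits(iso, "error")) {
          expect_match(conditionMessage(iso), "attainable")
        } else {
          expect_lt(abs(nestpack:::isocline_area(N, M, iso$p) - phi), 1e-8)
        }
      }
    }
  }
})

test_that("p decreases as the fill grows (area above the curve shrinks in p)", {
  fills <- c(0.15, 0.3, 0.45, 0.6)
  ps <- vapply(fills, function(f) solve_isocline(25, 25, f)$p, 0)
  expect_true(all(diff(ps) < 0))
})

test_that("unattainable fills report the attainable range", {
  expect_error(solve_isocline(2, 2, 0.05), "attainable range")
  expect_error(solve_isocline(3, 3, 0.05), "attainable")
  expect_error(solve_isocline(1, 5, 0.5), "N >= 2")
})

test_that("D is the literal axis-intercept distance", {
  iso <- solve_isocline(10, 10, 0.3)
  dd <- cell_distances(0.3, 0.2, iso)
  expect_equal(dd$D, sqrt(2) * 0.5, tolerance = 1e-12)
  # beyond the unit square the literal value keeps growing, the clipped
  # variant saturates at the square's diagonal chord
  dd2 <- cell_distances(0.9, 0.8, iso)
  expect_equal(dd2$D, sqrt(2) * 1.7, tolerance = 1e-12)
  dd2c <- cell_distances(0.9, 0.8, iso, clip = TRUE)
  expect_equal(dd2c$D, sqrt(2) * 0.3, tolerance = 1e-12)
})

test_that("d agrees with a dense-sampling oracle on random cells", {
  iso <- solve_isocline(12, 17, 0.35)
  set.seed(7)
  xs <- runif(100, 0.02, 0.98)
  ys <- runif(100, 0.02, 0.98)
  dd <- cell_distances(xs, ys, iso)
  for (k in seq_len(100)) {
    s <- xs[k] + ys[k]
    u <- seq(0, min(1, s), length.out = 1e6)
    gap <- abs(isocline_value(iso, u) - (s - u))
    d_oracle <- sqrt(2) * abs(xs[k] - u[which.min(gap)])
    expect_lt(abs(dd$d[k] - d_oracle), 2e-6)
  }
  # a point sitting on the isocline has d = 0
  x0 <- 0.4
  y0 <- isocline_value(iso, x0)
  expect_lt(cell_distances(x0, y0, iso)$d, 1e-9)
})

test_that("classification flags exactly the disagreeing cells", {
  m <- perfect_nested(nested_spec(8, 9, 0.35))
  iso <- solve_isocline(8, 9, fill_density(m))
  r <- identity_ranking(m)
  expect_equal(nrow(classify_cells(m, r, iso)), 0L)

  flipped <- unclass(m)
  flipped[8, 9] <- 1L - flipped[8, 9]
  mf <- incidence_matrix(flipped)
  iso_f <- solve_isocline(8, 9, fill_density(mf))
  cells <- classify_cells(mf, identity_ranking(mf), iso_f)
  expect_gte(nrow(cells), 1L)
  expect_true(any(cells$row_rank == 8 & cells$col_rank == 9))
})

test_that("the complement of a perfect matrix is unexpected everywhere", {
  m <- perfect_nested(nested_spec(6, 7, 0.4))
  comp <- incidence_matrix(1L - unclass(m))
  # complement fill = 1 - fill; classify against an isocline solved for
  # the complement's own fill but with the original's expected region
  iso <- solve_isocline(6, 7, fill_density(m))
  cells_m <- classify_cells(m, identity_ranking(m), iso)
  expect_equal(nrow(cells_m), 0L)
  # against the same isocline, every cell of the complement disagrees
  grid_mask <- nestpack:::expected_filled_mask(iso, 6, 7)
  expect_true(all(xor(unclass(comp) == 1L, grid_mask)))
})
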