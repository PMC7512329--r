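---
title: "Nestedness temperature minimization: models, rankers and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nestedness temperature minimization: models, rankers and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestpack)
```

## The problem

A bipartite network -- plants and their pollinators, countries and the
products they export -- is *nested* when the partners of a specialist
node form a subset of the partners of more generalist nodes. Under a
suitable ordering of rows and columns the incidence matrix `B` then
looks triangular: a filled block hugging the top-left corner, separated
from an empty region by a smooth boundary. nestpack quantifies how far a
matrix is from that ideal with the classical *nestedness temperature*
`T`, and searches for the row/column ordering that minimizes it.

Temperature depends on the ordering, which is what makes the problem
interesting: the *nestedness temperature minimization* (NTM) problem is
to find, among all `N! * M!` row/column permutation pairs, the one whose
ranked matrix is coldest. Exhaustive search is hopeless beyond toy
sizes, so practical work relies on heuristic rankers. The package
implements three and a comparison pipeline between them.

## Temperature of a ranked matrix

The ranked matrix is mapped onto the unit square: column ranks run left
to right, `x = (a - 0.5)/M`, and row ranks top to bottom in Cartesian
orientation, `y = (N - i + 0.5)/N`, so the most generalist row sits at
the top. The *line of perfect nestedness* (isocline) is the one-parameter
curve

$$f(x; p) = \frac{0.5}{N} + \frac{N-1}{N}\left[1 -
  \left(1 - \frac{Mx - 0.5}{M-1}\right)^p\right]^{1/p},$$

defined on the band `[0.5/M, (M-0.5)/M]` and extended flat to the edges.
Its endpoints are pinned for every `p`: the curve always passes through
the centers of the top-right and bottom-left corner cells. The shape
parameter `p > 0` is calibrated so that the area of the unit square
*above* the curve equals the matrix fill `Phi = L/(N M)`. Because `f` is
pointwise increasing in `p`, that area is strictly decreasing in `p`:
sparse matrices get large `p` (a curve hugging the top-left corner),
dense matrices a small one. Note the pinned endpoints bound the
attainable area: a 2 x 2 matrix, for instance, only admits isoclines
with fill between 0.375 and 0.625, and `solve_isocline()` reports the
attainable range when asked for a fill outside it.

A cell is *expected-filled* when its center lies on or above the curve;
*unexpected* cells are empty cells in the expected-filled region and
filled cells in the expected-empty region. Through each unexpected cell
a probe line of slope -1 is drawn; `d` is the distance from the cell to
the point where the probe line crosses the (extended) isocline, and `D`
is the distance between the probe line's two axis intercepts,
`sqrt(2)(x + y)`. The unexpectedness and temperature are

$$U = \frac{1}{NM} \sum_{(i,\alpha) \in \mathcal{U}}
      \left(\frac{d_{i\alpha}}{D_{i\alpha}}\right)^2,
  \qquad T = 100\,\frac{U}{U_{max}}, \quad U_{max} = 0.04145.$$

`T` is zero exactly when no cell is unexpected and is not clamped at
100.

### Numerical choices

* **Calibration.** The area above the curve is computed by adaptive
  quadrature (`integrate`, relative tolerance 1e-11) and `p` found by
  root bracketing on `[1e-4, 1e4]` (expanded geometrically when needed)
  to an area tolerance of 1e-8, with a bisection polish if the root
  finder's x-tolerance leaves residual area error.
* **Boundary ties.** Centers exactly on the curve count as
  expected-filled. The comparison carries a 1e-9 tolerance because the
  two pinned corner cells sit exactly on the curve for every `p` and
  would otherwise land on either side depending on rounding; their
  `d` is 0, so the convention cannot affect `T`.
* **`D` policy.** The axis-intercept distance is taken literally even
  when the intercepts fall outside the unit square (`x + y > 1`). A
  `clip = TRUE` switch restricts the probe segment to the square for
  sensitivity analyses; the default reproduces the stated geometric
  construction.
* **Finding `d`.** Along the probe line the function
  `f(u) + u - (x + y)` is strictly increasing, so the crossing is unique
  and a vectorized bisection to 1e-10 suffices.
* **Caching.** Everything that depends only on the geometry `(N, M, L)`
  -- the isocline, the expected-fill mask, the per-cell `(d/D)^2`
  weights -- is cached and shared across the thousands of evaluations a
  search performs. An evaluation then only needs the `L` filled-cell
  positions of the candidate ordering.

## The three rankers

**Degree.** Rows by decreasing row degree, columns by decreasing column
degree, ties broken by input order. Cheap, deterministic, and the
conventional baseline.

**Fitness-complexity (FCA).** The iterative map

$$\tilde F_i^{(n)} = \sum_\alpha B_{i\alpha} Q_\alpha^{(n-1)}, \qquad
  \tilde Q_\alpha^{(n)} = \frac{1}{\sum_i B_{i\alpha} / F_i^{(n-1)}},$$

with both vectors renormalized to unit mean after every step, starting
from all scores equal to 1. The harmonic form makes a column's score
collapse if any low-fitness row links to it, which is precisely what
drives triangular packing: columns are effectively sorted by the
generality of their least-fit partner. Raw scores can drift towards
zero without the *rankings* changing, so iteration stops at the first
`n*` where the Spearman correlation between the rankings at `n*` and
`n* + delta_n` exceeds `1 - 1e-3` on both sides (`delta_n = 10` by
default; 20, 30 and a fixed 100-step run are provided as robustness
variants). Reported scores are those at `n* + delta_n`, the more
converged endpoint. Scores are floored at 1e-280 before the reciprocal
as an underflow guard; the stop rule normally fires long before the
floor can matter. Rows are ranked by decreasing fitness, columns by
increasing complexity, ties by decreasing degree then input order.

**Genetic algorithm.** A BINMATNEST-style search over permutation
pairs; a chromosome is a (row ranking, column ranking) pair and its
fitness is `-T`. Crossover copies the well-performing parent outright
with probability 1/2, otherwise splices a prefix of it with the
partner's suffix, repairing clashes with the unused rank values in
increasing order; mutation (probability 0.1 per side) rotates a random
contiguous slice by one position. The surrounding scheme is not pinned
down by the operator definitions, and the package's choices are:

* a *generation* is a population-sized sweep of steady-state
  reproduction events (selection by linear rank weighting, partner
  uniform, offspring replacing the current worst if strictly better);
* a *no-twins* rule: an offspring identical to a resident chromosome
  would waste its evaluation -- the copy branch produces many -- so it
  is replaced by a random immigrant. Without this the population
  collapses to clones of the incumbent within a few dozen events and
  recombination stops exploring; with it the search reliably recovers
  the exhaustive optimum on every 4 x 4 and 4 x 3 test instance;
* stopping after 500 generations or 100 generations without
  improvement of the best temperature;
* seeding with the degree ranking plus random permutations. The FCA
  ranking is *deliberately not* a default seed: an elitist GA seeded
  with the FCA can never end hotter than the FCA, which would make any
  comparison between the two methods vacuous. `ga_config(seeding =)`
  adds it back when only the final packing matters, not the
  comparison.

`brute_force_min_temperature()` enumerates all orderings (guarded at
`N! * M! <= 1e6`) and serves as the exactness oracle for the GA.

## Revealed comparative advantage

Weighted country-product export tables are binarized through
`R[i,a] = w[i,a] W / (w_i w_a)`: the observed volume relative to the
volume expected from the margins. A link is kept iff `R >= 1`
(inclusive), zero-margin rows/columns are dropped before the division,
and rows or columns left empty after thresholding are stripped. Per-
destination export records are aggregated by summation before RCA.

## Synthetic generators

The generators provide ground-truth fixtures so that every claim in the
package is testable without downloads.

* `perfect_nested()` must produce a matrix whose temperature is *exactly*
  zero. Since temperature always judges a matrix against the isocline of
  its own fill, the pattern has to be a fixed point: its link count `L`
  must reproduce itself when the curve is re-solved at `L/(N M)`. The
  generator searches for the self-consistent count nearest the target
  fill (bracketing plus a local scan). Fixed points are dense at
  moderate fills but sparse at low fills and small sizes, so the
  realized fill (reported in the `"realized_fill"` attribute) can
  deviate from the target there -- and for a 2 x 2 matrix no fixed point
  exists at all, which the generator reports as an error.
* `noisy_nested()` applies `ceiling(noise * L)` random fill-swaps (a
  random 1 moves to a random 0), conserving `L` -- and hence the
  isocline -- exactly, so noise levels differ only in ordering
  difficulty, not in fill. Swaps may silence a specialist entirely;
  downstream code strips empty lines with `drop_empty()`.
* `random_matrix()` places exactly `round(Phi N M)` links uniformly,
  redrawing (bounded) when a row or column comes out empty.
* `nested_trade_table()` builds export volumes `w = c_i p_a exp(eps)`
  on a nested capability mask, with log-normal country sizes (largest
  for the most diversified countries), log-normal product values
  (heaviest tail, default sd 2, assigned to the rarest products) and
  volume noise of dispersion 0.25. These defaults were calibrated once
  so that RCA binarization recovers the mask's fill to within about
  0.05: with product-form weights the generalist-country x
  ubiquitous-product corner mathematically always has `R < 1` (the
  total `W` of a masked product measure is strictly below the
  independence total), so some corner loss is intrinsic, exactly as in
  empirical RCA matrices. Off-mask volumes are exactly zero, so
  binarization can never invent a link.

What the synthetic ensemble does *not* emulate: the heavy-tailed degree
distributions, forbidden links and sampling effort biases of real
pollination data. Swap noise is unstructured and partially reversible
by local search, which makes a strong optimizer look better against the
FCA here than on empirical networks; passing the synthetic comparisons
therefore says the machinery is correct, not that the empirical
FCA-vs-GA win rate will be reproduced.

## Problem sizes used in the checks

The package's own test battery runs at sizes chosen to keep the full
suite near ten minutes on one core: the calibration grid spans sizes
{2, 3, 5, 10, 25, 50, 100, 200} crossed with fills 0.05-0.95; the
GA-vs-bruteforce check uses twenty 4 x 4 / 4 x 3 matrices at fill 0.4
with fifty seeds each; the ranker comparison uses fifty noisy-nested
30 x 20 matrices at fill 0.25 and noise 0.1 (three GA repetitions per
matrix, best kept); the trade-recovery check uses 30 countries x 40
products at fill 0.3. The acceptance script repeats the same
computations at slightly reduced batch sizes from a caller-supplied
seed.

## Known limitations

* The temperature framework itself is undefined for matrices whose fill
  lies outside the isocline's attainable range (an issue only for very
  small or extreme matrices, e.g. any 2 x 2).
* The GA is stochastic; only the small-matrix regime carries an
  exactness guarantee (via the brute-force oracle in the tests). On
  larger matrices it is a strong local optimizer with no optimality
  certificate.
* RCA preprocessing does not harmonize product classifications,
  deflate values, or correct re-exports; it assumes a clean
  country-product-volume table.
* No significance testing against null models, and no alternative
  nestedness indices (NODF, spectral radius): the package is about
  temperature minimization.
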