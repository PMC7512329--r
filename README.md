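# nestpack

Nestedness temperature minimization for binary bipartite networks.

Ecological interaction matrices (plants x pollinators) and
country-product export matrices are often *nested*: the partners of a
specialist are a subset of the partners of more generalist nodes, so a
well-ordered incidence matrix looks triangular. nestpack measures the
distance from perfect nestedness with the Atmar-Patterson *temperature*
`T` and searches for the row/column ordering that minimizes it — the
classical matrix "packing" problem of community ecology, which also
shows up in economic complexity.

The temperature of a ranked `N x M` matrix with fill `Phi = L/(NM)` is
computed against the *line of perfect nestedness*

```
f(x; p) = 0.5/N + ((N-1)/N) * [1 - (1 - (Mx - 0.5)/(M-1))^p]^(1/p)
```

whose shape parameter `p` is calibrated so the area above the curve
equals `Phi`. Cells that disagree with the curve's prediction are
*unexpected*; each contributes the squared ratio of its distance `d` to
the curve (along a slope −1 probe line) over the probe line's
axis-intercept span `D`:

```
U = (1/NM) * sum over unexpected cells of (d/D)^2,    T = 100 * U / 0.04145
```

A perfectly nested ranked matrix has `T = 0`; disordered matrices run
hot. nestpack provides three rankers:

* **degree** — rows/columns by decreasing degree (baseline);
* **fitness-complexity (FCA)** — the non-linear iterative map from the
  economic-complexity literature (`F_i = sum_a B_ia Q_a`,
  `Q_a = 1 / sum_i B_ia / F_i`, mean-normalized each step, stopped when
  the rankings stabilize);
* **genetic algorithm (GA)** — a BINMATNEST-style elitist search over
  row/column permutation pairs, with order-based crossover and
  cyclic-slice mutation.

plus an exact brute-force minimizer for tiny matrices, revealed
comparative advantage (RCA ≥ 1) binarization of weighted trade tables,
seeded synthetic generators (perfectly nested, noisy nested, random,
nested trade tables), and a batch pipeline comparing the rankers.

## Worked example

```r
library(nestpack)

# a noisy nested 30 x 20 matrix: fill 0.25 target, 10% of links displaced
m <- drop_empty(noisy_nested(nested_spec(30, 20, 0.25, noise = 0.1, seed = 42)))$matrix
m
#> incidence_matrix: 30 x 20, L = 183, fill = 0.3050

temperature(m, degree_ranking(m))
#> temperature: T = 5.9407 (U = 0.00246242, 48 unexpected cells, p = 1.612)

r_fca <- rank_by_fca(m)           # fitness-complexity ranking
attr(r_fca, "state")
#> fca_state: n = 38 (converged, n* = 28), 30 fitness / 20 complexity scores
temperature(m, r_fca)
#> temperature: T = 5.7305 (U = 0.0023753, 122 unexpected cells, p = 1.612)

fit <- ga_minimize(m, ga_config(seed = 7))   # genetic algorithm
fit$result
#> temperature: T = 5.3434 (U = 0.00221485, 70 unexpected cells, p = 1.612)

compare_methods(m, id = "demo", seed = 7)
#>     id n_rows n_cols links  fill t_degree t_fca n_star  t_ga ratio rho_rows rho_cols
#> 1 demo     30     20   183 0.305    5.941 5.731     28 5.152 1.112   0.7838   0.9203
```

Reading the numbers: the degree baseline leaves the matrix at
`T = 5.94`; the FCA packs it slightly colder (5.73) after stabilizing
its rankings at iteration `n* = 28`; the best of three GA repetitions
reaches 5.15, so here the GA wins (`ratio = T_fca / T_ga = 1.11`), while
the two methods' rankings stay strongly correlated (Spearman 0.78 for
rows, 0.92 for columns). The isocline parameter `p = 1.61` is shared by
all rankings of the same matrix: temperature differences come purely
from the ordering. Note that `T` weighs unexpected cells by their depth
in the wrong region, not by their count — the FCA ranking has more
unexpected cells than the degree ranking but keeps them nearer the
line, and ends colder.

A thin command-line interface wraps the same functions
(`exec/nestpack`): `temperature`, `rank`, `synth`, `rca-binarize` and
`compare` subcommands, reading the labelled matrix-csv dialect used by
the web-of-life.es exports or plain edge lists, and writing JSON/CSV
reports.

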