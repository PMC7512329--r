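Package: nestpack
Title: Nestedness Temperature Minimization for Bipartite Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring and maximizing the nestedness of binary
    bipartite networks via the Atmar-Patterson nestedness temperature with
    the Rodriguez-Girones-Santamaria line of perfect nestedness. Provides
    three row/column ranking methods - degree, the fitness-complexity
    iterative algorithm from the economic-complexity literature, and a
    BINMATNEST-style genetic algorithm over permutation pairs - together
    with an exact brute-force minimizer for tiny matrices, revealed
    comparative advantage (RCA) binarization of weighted country-product
    export tables, seeded synthetic generators of perfectly nested, noisy
    nested and random matrices, and a batch pipeline comparing the
    temperatures achieved by the different rankers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
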