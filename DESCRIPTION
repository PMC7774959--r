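Package: osmiaplace
Title: Optimal Placement of Solitary-Bee Nesting Aids in Orchards
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Locates artificial nesting aids for cavity-nesting solitary
    bees (such as Osmia cornuta) on orchard trees by lexicographic
    two-stage optimization: first the minimum number of aids such that
    every tree lies within the bee foraging range of an aid (a set
    covering location problem), then the minimum total flight distance
    from every tree to its nearest aid at that fixed aid count (a
    coverage-capped p-median problem). Large instances are solved with an
    integer-encoded rand/1/bin differential evolution scheme; small
    instances are solved exactly by subset enumeration, which doubles as
    a validation oracle for the metaheuristic. Includes generators for
    regular-grid and random orchard layouts, coverage diagnostics, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
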