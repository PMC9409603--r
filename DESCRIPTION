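Package: znss
Title: Z-Number Soft Sets for Decision Support Under Unreliable Evidence
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A calculus for soft sets whose cells are Z-numbers: pairs of a
    membership degree and a reliability degree, both in [0,1], recorded for
    every (alternative, parameter) judgment. Provides construction and
    validation of Z-number soft sets, their algebra (complement, union and
    intersection under product or min/max norms, subset and equality,
    null and absolute sets, matrix form), a two-component ratio similarity
    measure between two sets over a shared parameterized universe, and a
    multi-observer diagnostic workflow that fuses observer reports by union
    and ranks candidate disease models by similarity. Ships the worked
    reference tables as plain-text fixtures, a seeded random-set generator
    for property testing, CSV/JSON interchange, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
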