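Package: voxdiss
Title: Voxel-Based Virtual Tablets and Dissolution Profile Validation
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for validating in silico dissolution predictors against
    tablet microstructure. Builds and accounts voxel-based virtual tablet
    matrices (read from labelled 8-bit TIFF stacks or generated by random
    placement and seed-and-grow), computes composition recovery rates and
    Derringer-style desirabilities, applies the tablet-porosity and virtual
    excipient-porosity mapping used to parameterise voxel dissolution
    engines, compares predicted and experimental dissolution profiles by
    the f1 difference and f2 similarity factors, fits Higuchi and
    Korsmeyer-Peppas release kinetics on the 20-60 percent release window
    with regression-equality t-tests, and ships a small transparent
    cellular-automaton dissolution simulator as a reference fixture so the
    whole validation pipeline runs end-to-end without proprietary software.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
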