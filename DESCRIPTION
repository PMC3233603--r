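Package: dcafold
Title: Residue Contact Prediction and Coarse-Grained Folding from
    Sequence Covariation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers direct residue-residue couplings from a multiple
    sequence alignment with a mean-field maximum-entropy (inverse Potts)
    model, scores column pairs by direct information and mutual
    information, filters the ranked pairs into evolutionary inferred
    contacts, folds coarse-grained C-alpha/C-beta models by distance
    geometry with restraint-based annealing, ranks candidates by
    handedness and knot criteria, and evaluates predictions against
    reference structures with contact-map and superposition metrics.
    Includes a Potts-model sequence simulator with planted contact
    topologies for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
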