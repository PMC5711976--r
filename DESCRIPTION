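Package: seqcs
Title: Sequence-Based Prediction of Protein NMR Chemical Shifts
Version: 0.1.0
Authors@R:
    person("seqcs", "developers", email = "seqcs@example.org", role = c("aut", "cre"))
Description: Statistical prediction of protein NMR chemical shifts from the
    amino-acid sequence alone. Gaussian-kernel density estimates of
    per-residue shift distributions, nearest-neighbour pair corrections
    weighted by density overlap, and a calibrated normalisation factor give a
    random-coil predictor for intrinsically disordered proteins. For folded
    proteins the same machinery is conditioned on three-state (Q3) secondary
    structure, augmented with empirical boundary-region correction profiles
    and an optional feedforward neural refiner that is robust to predicted
    (rather than observed) secondary structure. Includes database curation
    (identity clustering, referencing quality control, outlier removal),
    leave-one-out benchmarking, a ground-truth synthetic data generator, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
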