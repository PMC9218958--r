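Package: irbench
Title: Benchmark-Based Validation of Nontargeted LC-MS Feature Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds validated benchmark peak lists for liquid
    chromatography-mass spectrometry runs from known molecules, using
    isotopologue abundance ratios predicted from molecular formulas to
    confirm that every benchmark peak is quantitatively reliable. Any
    nontargeted feature detection output (unaligned peak lists or aligned
    feature tables) can then be scored against the benchmark for peak
    recovery before and after alignment, isotopologue-ratio accuracy,
    split peaks, and replicate precision, with percentile bootstrap
    confidence intervals obtained by resampling benchmark molecules.
    Includes a synthetic centroided mzML simulator with exact ground
    truth and a controlled table corrupter, so every reported metric can
    be checked against a known expected value.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mzR,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
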