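Package: meiorec
Title: Meiotic Recombination Analysis for Low-Coverage Backcross Sequencing,
    Tetrad Genetics and Single-Molecule Spot Counting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects meiotic crossover breakpoints in low-coverage backcross
    (BC1) sequencing data by binning informative SNPs and classifying bin
    zygosity with the pooled heterozygosity score; computes genetic distances
    (Perkins' formula), crossover interference ratios and event spectra from
    fluorescent-tagged-line pollen tetrad and single-pollen observations;
    counts single-molecule fluorescence maxima in 16-bit images with
    ImageJ-style prominence semantics and derives volume-normalized
    oligo/protein fractions and genotype fold changes. Ships a synthetic-data
    generator with known ground truth (gamma-renewal crossover process,
    Poisson read coverage, Bernoulli-chiasma tetrads, Gaussian spot images)
    that drives the package's validation suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
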