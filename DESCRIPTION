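Package: canidemog
Title: Coalescent Simulation and Divergence Statistics for Canid
    Demographic History
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the demographic history of dogs, gray
    wolves and the golden jackal from individual diploid genomes. Provides
    a structured-coalescent simulator for population trees with
    piecewise-constant effective sizes and low-rate migration bands;
    diploid pairwise-divergence estimators with neighbor-joining trees and
    windowed-bootstrap support; ABBA/BABA/BBAA quartet site-pattern
    counting with block-jackknife D-statistic tests and a model-fit score
    for comparing demographic models; windowed heterozygosity,
    variant-site sharing classification and a simple run-of-homozygosity
    masker; mutation-rate and generation-time calibration including CpG
    correction; and read-depth based copy-number estimation for
    multi-copy loci such as the pancreatic amylase gene.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
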