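Package: beeniche
Title: Feeding Niche Partitioning Between Wild Bees and Honeybees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trait-based analysis of feeding niche partitioning between a
    wild bee community and the local honeybee population. Computes the
    per-site mean pairwise Euclidean distance between wild-bee and honeybee
    individuals in a scaled six-trait space (intertegular distance, relative
    tongue length, feeding specialization, phenology start and end, daytime
    activity), links it to local and landscape resource availability and
    beekeeping intensity through a piecewise structural equation model with
    d-separation tests, Fisher's C, information criteria and Moran's I
    diagnostics, derives landscape buffer predictors from land-cover grids
    and hive registers, and ships a synthetic community and landscape
    generator implementing competition and environmental-filtering assembly
    scenarios so every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    knitr,
    pracma,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
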