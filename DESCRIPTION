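Package: spectramapper
Title: Topological Profiling of Comprehensive Two-Dimensional GC-MS Data
    with Ball Mapper
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Untargeted profiling of comprehensive two-dimensional gas
    chromatography (GC x GC) high-resolution time-of-flight mass
    spectrometry data. Mass spectra are discretised to integer m/z bins by
    per-bin maximum, projected onto the unit sphere, and summarised per
    sample by a greedy epsilon-net Ball Mapper cover graph whose landmarks
    act as representative spectral vectors. Sample-specific markers
    (relatively unique spectral vectors) are detected by a cross-sample
    separation rule, and statistically robust representative sample groups
    are mined from randomised Ball Mapper views via bootstrap Adjusted Rand
    Index stability scoring and consensus extraction. Includes a synthetic
    data generator with known ground truth for end-to-end validation.
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
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    arrow,
    mclust,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
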