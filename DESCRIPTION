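Package: phenodrought
Title: Image-Based Drought Phenotyping of Plant Diversity Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for high-throughput drought phenotyping trials
    on conveyor-type imaging platforms. Extracts biovolume, height and
    HSV colour traits from multi-view plant images, models the plant-available-
    water irrigation regime of a drought/recovery experiment, estimates variance
    components, broad-sense heritability and genotype BLUEs from replicated
    two-experiment designs, derives relative growth rate, drought loss, phase
    water-use efficiency and photosystem-II plasticity, and ranks panel
    genotypes against the panel mean. A synthetic-data generator renders
    multi-view images with known ground truth and simulates trait tables and
    watering records so every stage is verifiable without raw trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    graphics,
    grDevices,
    lme4,
    png,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    EBImage,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
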