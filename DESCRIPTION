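Package: pefastax
Title: Nanosecond Pulsed Electric Field Dosimetry and Astaxanthin
    Induction Analysis for Microalgae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for nanosecond pulsed electric field (nsPEF)
    treatment of the astaxanthin-producing green alga Haematococcus
    pluvialis. Implements a single-shell membrane-charging model for a
    spherical cell in a uniform field (azimuthal cosine law, exponential
    charging), permeabilisation-geometry and specific-energy dose
    summaries for continuous-flow treatment chambers, per-cell astaxanthin
    quantification from RGB micrographs by inverted channel subtraction
    and integrated density, Evans-Blue dye-exclusion mortality accounting,
    actin-normalised 2^(-ddCt) relative transcript quantification with a
    3 biological x 3 technical replicate design, two-sample t-tests with
    star annotation, and seeded synthetic-data generators (micrographs,
    Ct tables, count tables) with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    EBImage,
    dplyr,
    tibble,
    tidyr,
    rlang,
    jsonlite,
    yaml,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
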