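Package: multifrag
Title: Multi-Method Peptide Fragmentation Annotation, Intensity Prediction and Rescoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for tandem mass spectrometry data acquired with
    collision- (HCD), electron- (ECD, EID, ETciD) and photon-based (UVPD)
    peptide fragmentation. Provides exact monoisotopic fragment-ion mass
    calculus over the ten main backbone ion series (a, a+1, b, c-1, c, x,
    x+1, y, z, z+1), tolerance-based spectrum annotation with precursor
    window exclusion and isotope flagging, construction of model-ready
    training datasets with an occurrence-filtered ion dictionary and
    masked intensity targets, a recurrent (GRU) encoder-decoder model of
    fragment ion intensities conditioned on charge and fragmentation
    method trained with a masked spectral-distance loss, target-decoy
    rescoring statistics, and a fully specified synthetic-spectra
    simulator so the complete pipeline can be exercised end to end
    without raw instrument data.
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
    utils,
    withr
Suggests:
    arrow,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
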