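Package: scalegram
Title: Spectral Analysis of Cyclical Growth Patterns in Fish Scale Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated quantification of growth increments (circuli) from
    digitized fish scale images. A scale image is radially unwrapped around an
    operator-annotated focus into a dense fan of saturation transects, each
    transect is mapped to a short-window Fourier spectrogram, the spectrograms
    are stretched to a common length and ensemble-averaged, and the dominant
    spectral ridge is extracted as a growth trace in circuli-spacing units.
    The first marine growth year is segmented from the across-transect
    variance of the spectral peak. Includes a synthetic ring-image generator
    with ground truth for validation, and comparison tools (standardized
    interpolation, cohort summaries, PCA) for classical single-transect
    inter-circuli measurements.
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
    png,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
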