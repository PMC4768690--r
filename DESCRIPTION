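Package: stftda
Title: Automated Fish Species Identification from Otolith Contours
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fully automated identification of fish species from images of
    their sagittal otoliths. The external outline of the otolith is extracted
    from a grayscale image, converted to a one-dimensional radius-versus-angle
    signal about the centre of gravity, resampled to a fixed length by
    band-limited Fourier interpolation, and analysed with a short-time Fourier
    transform (STFT). The per-segment maxima of the z-scored spectral
    magnitudes and phase angles form a compact 32-element shape descriptor
    that is classified with a linear discriminant model (the STFT-DA method).
    Includes sixteen spectral window functions, sweep utilities for window and
    feature-set ablations, a seeded generator of synthetic otolith-like shapes
    for end-to-end validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    signal,
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    MASS,
    optparse,
    yaml,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
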