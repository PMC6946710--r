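Package: psafret
Title: Homo-FRET Quantification from Anisotropy Changes During Photoswitching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies homo-FRET between identical fluorescent proteins from
    the rise in fluorescence anisotropy observed while photoswitchable
    fluorophores are driven to their off state (psAFRET). Reads dual-view
    polarization image stacks, calibrates the instrument g-factor on an
    isotropic dye reference, applies the Axelrod correction for polarization
    mixing in high numerical aperture objectives, fits anisotropy against the
    fraction of fluorophore photoswitched, and extrapolates to the anisotropy
    with and without energy transfer. The anisotropy change is converted to a
    drFRET efficiency that is comparable across optical configurations. A
    physics-based simulator of photoswitching oligomers (steady-state cluster
    anisotropy, binomial ensemble mixing, camera noise, rendered image stacks)
    provides ground truth for validation, and group-level statistics
    (Welch t, one-way ANOVA with Tukey-Kramer, Cohen's d) support reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    jsonlite,
    yaml,
    pracma,
    minpack.lm,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
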