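Package: herdseason
Title: Reconstructing Caprine Herding Seasonality from Archaeological Remains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative tools for reconstructing sheep and goat herding
    practices from archaeological skeletal remains. Models sequential
    intra-tooth enamel oxygen isotope series with a cosine seasonality model
    to estimate season of birth (x0/X), estimates the phase shift between
    paired oxygen and carbon isotope sequences, converts carbon isotope
    values in enamel and bone collagen to percent C4 diet with a
    two-end-member mixing model, performs collagen quality control and the
    associated descriptive and inferential statistics, builds caprine
    mortality profiles with Dirichlet credibility intervals and survivorship
    curves alongside taphonomic indices (taphonomy proportions, Marean
    completeness, MAU%, density-mediated attrition tests), processes
    MALDI-ToF collagen peptide-mass fingerprints to call Ovis versus Capra
    from COL1a2 markers (ZooMS), and generates seeded synthetic datasets for
    every input so that the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    minpack.lm,
    signal,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mzR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
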