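Package: photoacclim
Title: Irradiance-Controlled Cyanobacterial Growth Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of irradiance-controlled steady-state
    growth of cyanobacteria in turbidostat photobioreactors. Estimates net
    specific oxygen production from a gas-liquid mass balance, fits
    saturating and photoinhibited light-response (Platt-type) curves to
    growth and photosynthesis rates, derives growth-to-photosynthesis
    yields per light regime, computes PAM chlorophyll-fluorescence
    statistics (rETR, rapid light curves, post-illumination rise as a
    cyclic electron flow proxy, Fv/Fm), clusters RPKM expression matrices
    with per-cluster eigengenes and Fisher exact functional enrichment,
    and summarises cell volumes from confocal axis measurements. Includes
    a synthetic-data generator with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
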