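Package: rlregions
Title: Regional Disaggregation of Red List and Protected-Area Indicators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Disaggregates global biodiversity indicators to policy regions
    and subregions: species richness, endemism and threatened-fraction bounds
    under Data Deficiency; spatially downscaled Red List Index contributions;
    dissolved-polygon coverage of important sites (IBAs, AZE sites) and
    protected areas on land and sea; and Monte Carlo trend estimation, with
    confidence intervals, of the proportion of sites wholly covered by
    protected areas when establishment dates are partly missing. Includes a
    synthetic-world generator with recorded ground truth so every stage of
    the pipeline can be exercised and validated without licensed global
    datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
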