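Package: ektopo
Title: Posterior Corneal Topography Metrics and Grading After Endothelial Keratoplasty
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing corneal elevation topography after endothelial
    keratoplasty (DMEK and DSAEK). Implements normalized Zernike polynomial
    fitting of anterior, posterior and total corneal wavefronts over 4.0- and
    6.0-mm zones with the standard higher-order, spherical and coma RMS
    aberration metrics; an automated 0-5 "posterior color grade" classifier of
    the posterior refractive power map; a seeded synthetic-cornea cohort
    generator calibrated to published group-level outcomes of DMEK, DSAEK and
    control eyes; the accompanying nonparametric statistical battery
    (Mann-Whitney U, Wilcoxon signed rank, Kruskal-Wallis with Dunn's post hoc,
    chi-squared, Pearson correlation); and a config-driven study pipeline that
    emits publication-shaped summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
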