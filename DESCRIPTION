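Package: oenoscreen
Title: LC-HRMS Screening and Chemometric Authentication of Varietal Wines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Rule-based target and suspect screening of liquid
    chromatography high-resolution mass-spectrometry peak lists against
    phenolic compound databases, calibration-based quantification with
    method-validation metrics (linearity, matrix effect, LOD/LOQ,
    precision), and OPLS-DA chemometrics (Pareto scaling, Kennard-Stone
    splitting, VIP marker selection, permutation and ROC validation) for
    two-class wine authentication studies.  Ships a synthetic-study
    generator emulating a 46-sample Agiorgitiko/Xinomavro design so the
    whole workflow runs end to end without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
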