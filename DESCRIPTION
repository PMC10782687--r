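Package: gpresem
Title: Path Analysis of Green Plant Regeneration Efficiency in Triticale Anther Culture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recursive path-analysis (structural equation modelling) toolkit
    built around the copper / pectin / S-adenosyl-L-methionine / glutathione /
    DNA-methylation model of green plant regeneration efficiency (GPRE) in
    triticale anther culture.  Provides maximum-likelihood covariance-structure
    estimation for acyclic path models over observed variables, the full
    goodness-of-fit index battery (RMR, SRMR, GFI/AGFI/PGFI, NFI/RFI/IFI/TLI/CFI,
    PNFI/PCFI, RMSEA with 90% confidence interval and PCLOSE, ECVI, Hoelter
    critical N), direct/indirect/total effect decomposition, packaged fixtures of
    the published descriptive statistics, correlation matrix and parameter
    estimates, a multivariate-normal synthetic-data generator emulating the
    37-regenerant, eight-trial design, and ATR-FTIR band quantification
    (replicate averaging, baseline correction, unit-area normalisation, band
    means) for the pectin, SAM and glutathione absorbance variables.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
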