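Package: orthoscreen
Title: Cross-Species Expression Concordance and Transcriptome-Proteome
    Substrate Screening
Version: 0.1.0
Authors@R:
    person("Maintainer", "Orthoscreen", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing differential-expression profiles across
    species and platforms, and for nominating candidate protease substrates
    from matched transcriptome and proteome fold changes.  Provides ortholog
    based pairing of fold-change tables, Pearson concordance with Fisher
    r-to-z comparison of correlations, DEG overlap counting, hypergeometric
    and EASE-score gene-set over-representation, a four-stage standardized
    residual screen for mRNA-protein discordance, and a summary-statistic
    simulator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
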