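Package: proturn
Title: Protein Turnover Kinetics from Heavy-Water Metabolic Labeling
Version: 0.1.0
Authors@R: person("proturn", "developers", email = "proturn@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for proteome dynamics experiments that use
    heavy water (2H2O) metabolic labeling and MS1 mass-isotopomer
    quantification. Computes peptide elemental compositions and natural or
    deuterium-enriched isotopomer distributions, converts isotopomer
    intensity time courses into total-labeling series, fits one-compartment
    exponential-rise kinetics to derive rate constants and half-lives,
    aggregates peptides to protein-level turnover per animal, and runs
    two-group cohort statistics (t-tests, through-origin regression,
    half-life summaries). Includes a synthetic-cohort generator with a
    recorded ground-truth ledger for validating the estimator, and a
    packaged catalog of HDL protein half-lives for summary-statistic
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
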