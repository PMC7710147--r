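Package: proalanase
Title: Characterization Toolkit for Proline/Alanine-Specific Acid Proteases
Version: 0.1.0
Authors@R:
    person("ProAlanase", "Toolkit Developers", email = "proalanase-dev@example.org",
           role = c("aut", "cre"))
Description: In-silico digestion with configurable cleavage rules, cleavage
    specificity and missed-cleavage profiling of identified-peptide tables,
    sequence-context motif statistics at cleavage sites, multi-enzyme
    sequence-coverage and phosphosite analysis, score-filtered de novo
    peptide assembly against a reference, and low-pH disulfide-species mass
    mapping with in-source-reduction triad validation. Ships a seeded
    synthetic-data generator (proteomes, identified-peptide lists with
    controlled terminal composition or mechanistic per-site cleavage,
    phosphosite tables, de novo reads, nonreduced disulfide digests) so the
    whole pipeline is testable without raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
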