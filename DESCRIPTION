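Package: clinnum
Title: Numeric Lexical Variants and Cohort Identification in Clinical Notes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how numbers and numerical concepts are written
    in free-text clinical notes. Provides deterministic generators and
    detectors for twelve categories of numeric surface variants (spelled-out
    cardinals, Roman numerals including malformed additive forms, ordinal
    suffixes and their hybrids, invalid calendar dates, biologically
    implausible ages, medical classification compounds, tuples, and quantity
    lexicons), a positional inverted index with exact case-insensitive phrase
    search and distinct-document and distinct-patient counting, cohort-overlap
    statistics quantifying the share of a patient cohort missed when only one
    numeric variant of a phrase is searched, and a seeded generator of
    synthetic clinical-note corpora with a ground-truth injection ledger for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
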