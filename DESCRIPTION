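Package: rtalign
Title: Retention-Time Alignment of Gas-Chromatography Peak Lists
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Aligns peaks across gas-chromatography (GC-FID) peak lists using
    retention times only. Implements a three-step procedure: correction of
    systematic linear retention-time drift against an automatically selected
    reference sample, row-wise partial alignment of individual peaks against
    the running mean retention time, and information-preserving merging of
    adjacent rows. Includes input validation, removal of substances shared
    with negative controls (blanks) and of single-sample substances, relative
    abundance normalisation, diagnostic summaries, a mode-row alignment error
    rate for datasets with known substance identities, and a seeded simulator
    of multi-sample peak lists with ground truth for validating alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
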