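Package: sigmotif
Title: Transcription Factor Binding Site Detection by Sequence
    Information Gain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects transcription factor binding sites by measuring how
    two parametric information quantities change when a candidate
    sequence is appended to a small set of aligned binding sites: a
    per-position Renyi redundancy profile and a between-position Renyi
    divergence matrix. The two resulting information-gain features are
    classified with a quadratic discriminant, combining the robustness
    of per-position (PWM-like) information with sensitivity to
    correlated motif positions. Includes finite-sample screening of
    correlated position pairs with a precomputed lookup library for fast
    sequence scanning, leave-one-out selection of the Renyi order,
    synthetic motif generators with tunable conservation and position
    coupling, and FASTA/BED input-output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
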