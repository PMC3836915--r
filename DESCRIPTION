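Package: mapresp
Title: Multi-Attribute Preference Response Measurement of Health
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for deriving interval-level health-state values from
    binary preference responses with the multi-attribute preference
    response (MAPR) model, which embeds the conditional-logit discrete
    choice model inside the Rasch measurement framework. Provides
    probability kernels for the whole model family (Thurstone's law of
    comparative judgment, random utility simulation, conditional logit,
    Rasch, MAPR), judgment-task designs (full pairwise, own-state pivot,
    partial profile, adaptive item selection), synthetic response
    simulation, maximum-likelihood estimation (pairwise conditional
    logit, Rasch conditional and joint ML, MAPR attribute weights),
    Guttman scalogram diagnostics, dead-state anchoring, and a small
    command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
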