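Package: rbottleneck
Title: Redundancy Bottleneck Analysis for Partial Information Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying redundant information that a set of discrete
    source channels carries about a target variable. Implements the redundancy
    bottleneck, an information-bottleneck formulation of partial information
    decomposition redundancy: an augmented joint distribution over the target,
    a source-identity variable and the pooled source outcome is built, and an
    alternating iterative algorithm traces the tradeoff between prediction of
    the target and leakage of source identity. Also provides exact Blackwell
    redundancy for small systems via vertex enumeration of the garbling
    polytope, channel deficiency, per-source decompositions of the bottleneck
    curve, the standard logic-gate benchmark systems, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
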