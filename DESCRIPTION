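Package: rxnscript
Title: Human-Readable Reaction-Network Models with Lossless SBML Level 3 Translation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A plain-text, human-readable language for biochemical reaction
    network models, with bidirectional, lossless translation to SBML Level 3
    Version 2 (Core plus the Flux Balance Constraints and Distributions
    packages and a minimal Layout subset). Provides a line-oriented parser
    with implicit symbol declaration, a deterministic serializer, content
    MathML conversion including the rateOf and time csymbols and
    distribution-draw functions, seeded numeric evaluation of expressions,
    a seeded random model generator for round-trip testing, and a
    command-line converter.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
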