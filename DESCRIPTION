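Package: codonopt
Title: GC-Constrained Codon Optimization for E. coli Expression Hosts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A model-agnostic codon-optimization toolkit for Escherichia coli.
    Implements a combined amino-acid/codon token vocabulary, a coding-sequence
    curation pipeline (structural validation, redundancy reduction, CAI ranking),
    an augmented-Lagrangian training objective that holds expected GC content at
    a target while minimizing a masked-language-modeling loss, GC-constrained
    beam-search decoding with position-aware feasibility pruning, a multi-metric
    in-silico evaluation suite (CAI, tAI, GC content, 5' folding energy,
    inhibitory cis-element counts, paired-test benchmark reports), and a
    synthetic coding-sequence generator with controllable codon-usage bias so
    the whole pipeline is exercisable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
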