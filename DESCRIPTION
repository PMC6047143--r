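Package: splidr
Title: Split-Inducing Indels as Binary Phylogenetic Characters
Version: 0.1.0
Authors@R: person("Maintainer", "Splidr", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Extracts split-inducing indels (splids) from multiple sequence
    alignments (MAF or aligned FASTA) and codes them as binary
    presence/absence characters with explicit missing data, for use in
    maximum-likelihood phylogenetics with ascertainment-bias correction.
    Includes terminal-gap masking, block filtering and concatenation,
    FASTA/PHYLIP/NEXUS matrix writers with summary statistics, normalized
    Robinson-Foulds and quartet tree distances, and a sequence-evolution
    simulator (F81 substitutions with insertion/deletion events under
    geometric or Lavalette length distributions) that emits a true alignment
    plus a complete event log for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
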