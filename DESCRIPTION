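Package: halorange
Title: Host-Range Matrices, Genome Motif Avoidance, and Phylogenetic
    Signal Tests for Haloarchaeal Viruses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing virus-host interaction screens of
    haloarchaeal viruses and the comparative genomics that follows them.
    Builds plaque-confirmed virus-host matrices from spot-on-lawn and
    plaque-assay tables, computes efficiency of plating (EOP) with
    one-significant-figure reporting, and summarises infecting-isolate
    counts with genome-identity deduplication.  Computes motif counts and
    Karlin-style tetranucleotide relative-abundance statistics to detect
    restriction-site avoidance in viral genomes, and scans protein
    alignments for substitutions at conserved columns.  Tests for
    phylogenetic signal in a binary host-infectivity trait via a
    symmetric two-state Markov model: pruning likelihood, maximum
    likelihood rate estimation, stochastic character mapping with
    endpoint-conditioned path sampling, Markov-jump counting, highest
    posterior density intervals, and a tip-randomisation null.  Includes
    simulators for every input (Yule trees with trait histories of known
    jump count, Markov-model genomes with avoided motifs, and screening
    tables with halocin-style false positives) so the whole pipeline is
    testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
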