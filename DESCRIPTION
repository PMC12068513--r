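Package: symfrag
Title: Symmetry-Constrained Fragment Decomposition and Monte Carlo Tree
    Search Molecular Generation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fragment-based design of conjugated organic molecules such as
    non-fullerene acceptors. Decomposes molecules into fragments by cleaving
    single bonds between aromatic rings and between aromatic rings and
    aliphatic chains, labelling every reactive position with the identity of
    the fragment removed there so that the symmetry of attachments is
    preserved. Generation runs Upper-Confidence-bound Tree search (UCT) over
    staged molecular-assembly decision processes constrained to the extracted
    fragments, with a diversity-penalised iterative reward,
    expected-improvement acquisition, and an active-learning loop around a
    pluggable property predictor. Canonicalisation and circular (Morgan/ECFP)
    fingerprints are delegated to Open Babel through ChemmineOB.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ChemmineOB,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
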