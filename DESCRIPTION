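Package: allonet
Title: Elastic Network Models of Entropy-Driven Allostery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained elastic network models (ENM) for dynamic,
    entropy-driven allostery in multimeric proteins, exemplified on the
    cAMP-binding CAP homodimer. Builds C-alpha spring networks for apo,
    singly- and doubly-liganded states, computes normal modes of the Tirion
    potential, per-mode vibrational entropy changes, the allosteric free
    energy and the cooperativity ratio K2/K1, diagnostic observables
    (B-factor fits, cumulative motion, eigenvector overlap, residue
    cross-correlations), and per-residue spring-perturbation scans that
    yield a global allosteric control map for rational mutation design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
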