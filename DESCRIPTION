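Package: knotfold
Title: Coarse-Grained Folding and Knot Analysis for Knotted Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for studying how proteins tie themselves into knots
    during folding. Implements a C-alpha structure-based (Go) model with an
    optional quasi-chemical non-native contact term, overdamped Langevin and
    Metropolis Monte Carlo samplers, ratchet-and-pawl biased dynamics along
    the fraction of native contacts, Onsager-Machlup action scoring with
    dominant-pathway selection, and a full open-chain topology pipeline:
    deterministic chain closure, KMT simplification, Alexander-determinant
    knot typing, trefoil chirality, knotted-core localization, slipknot
    detection, and classification of knotting mechanisms (direct threading,
    slipknotting, mousetrapping). Deterministic fixture generators provide
    parametric knots, toy native folds and scripted knotting trajectories so
    the whole pipeline is testable without external structure files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
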