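Package: stressmap
Title: Comparative Stress Analysis of Multidomain Protein MD Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Metrics and reporting for comparing molecular-dynamics
    trajectories of multidomain proteins (antibody Fab fragments in
    particular) between a reference condition and stress conditions such as
    low pH or elevated temperature. Implements per-domain Kabsch
    superposition with RMSD and windowed RMSF, radius of gyration,
    soft-cutoff native-contact fractions at domain, interface and residue
    level, total-contact counts, salt-bridge detection with occurrence
    statistics, a minimal Kabsch-Sander beta-strand assignment with
    per-strand occupancy change, Shrake-Rupley solvent-accessible surface
    area, occluded-surface packing density, aggregation-prone-region
    exposure tracking, mutational-scan bookkeeping with stabilising-
    consensus intersection of external free-energy tables, and alignment
    column entropy. A synthetic mini-Fab generator produces idealised
    four-domain structures and stress trajectories with known ground truth
    so that every stage is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    seqinr,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
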