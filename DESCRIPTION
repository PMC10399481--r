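Package: dualphore
Title: Dual-Target Pharmacophore Screening and Enrichment Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reusable pipeline for dual-target structure-based virtual
    screening of small molecules. Implements pharmacophore feature
    perception (hydrogen-bond donor, aromatic centroid, hydrophobic
    centroid) from 3D structures, RMSD-based pharmacophore matching with
    optimal rigid superposition, Guener-Henry goodness-of-hit enrichment
    statistics for decoy-set validation, a dual docking-energy threshold
    cascade with intersection and ranking, trajectory stability metrics
    (RMSD time series, per-residue RMSF), and assay-readout arithmetic
    (inhibition rates, four-parameter logistic IC50 fitting, potency
    ratios, xenograft tumour volume). Ships deterministic synthetic-data
    generators so every stage is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    ChemmineR,
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
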