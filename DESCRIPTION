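Package: assemblyMP
Title: Quantitative Analysis of Protein Oligomerization and Its Inhibition
    from Mass Photometry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying protein self-association equilibria and
    their small-molecule modulation from single-particle mass photometry
    event lists. Implements a monomer-dimer-tetramer mass-action equilibrium
    solver with substrate/inhibitor linkage, a seeded synthetic-data
    generator emulating serial-dilution and titration designs for UDP-GlcNAc
    2-epimerase (GNE) assembly, Gaussian mixture quantification of oligomer
    fractions from mass histograms, Hill-logistic affinity and IC50 fitting,
    Cheng-Prusoff Ki conversion (classical, Hill and empirically calibrated
    variants), Schild analysis, and global fitting of the operational model
    of allosterically modulated agonism (OMAM).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
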