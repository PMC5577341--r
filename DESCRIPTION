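Package: remscape
Title: Conformational Landscape Analysis for Replica-Exchange Peptide Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for conformational ensembles of intrinsically
    disordered peptides sampled by replica-exchange molecular dynamics (REMD),
    developed around the amyloid-beta 42-mer bound to N-terminal hexapeptides.
    Provides hydrogen-bond-based secondary-structure assignment with block-error
    propensity profiles, radius of gyration and RMSD observables with Kabsch
    superposition, residue contact maps and difference maps, salt-bridge
    frequencies, Shrake-Rupley solvent-accessible surface area, two reaction
    coordinates (normalized strand count and inter-region contact count), 2D
    potentials of mean force with rectangular-state populations, gromos-style
    RMSD clustering, and a single-trajectory MM-GB/SA binding-energy
    decomposition. A bundled synthetic-data module generates toy REMD ensembles
    and state mixtures with planted populations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
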