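Package: SECdimer
Title: Homodimer Dissociation Analysis from Size-Exclusion Chromatography
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize the monomer-dimer equilibrium of
    homodimeric proteins from size-exclusion chromatography (SEC) dilution
    series. Simulates and reads chromatograms, corrects baselines,
    integrates monomer and dimer peaks, converts peak areas to species
    concentrations under mass balance, and estimates the dissociation
    constant K_D from the linearized [M]^2 = K_D [D] relation with
    bootstrap uncertainty. Also provides mutational free-energy
    bookkeeping (delta-delta-G of dissociation, hydrogen-bond and
    buried-apolar-surface energy budgets), a deterministic Shrake-Rupley
    solvent-accessible surface area implementation for protein interface
    characterization (buried areas, polarity, inter-chain hydrogen
    bonds), and Michaelis-Menten kinetics fitting from product
    time courses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    minpack.lm,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
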