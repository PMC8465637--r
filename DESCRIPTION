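Package: parpromoter
Title: Cooperative ParA Dimer Assembly on Partition Promoters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis chain for the assembly of type Ia
    partition ATPase (ParA) dimers on their autoregulated promoter regions.
    Provides seeded synthetic-data generators emulating the wet-lab inputs
    (AT-rich promoters with embedded hexamer binding motifs, surface plasmon
    resonance sensorgrams under 1:1 Langmuir kinetics, cooperative and
    ligand-depletion titration isotherms, two-state thermal melt curves, and
    coordinate trajectories with a flexible loop); motif scanning and
    inverted-repeat architecture classification with logo quantification;
    SPR kinetic fitting and binding-stoichiometry estimation; Hill and
    depletion isotherm fitting; curved B-DNA arc geometry; least-squares
    trajectory superposition with simulated B-factor profiles; and melting
    point extraction from the first derivative of dual-wavelength
    fluorescence ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
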