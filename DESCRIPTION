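Package: hostguest
Title: Lipophilicity Fields, Pocket Polarity, Binding Affinity and
    Barrier Permeability for Host-Guest Inclusion Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Profiles cyclodextrin-type host-guest inclusion complexes
    from structure to transport. Computes molecular lipophilicity
    potential (MLP) fields from fragmental lipophilic constants,
    scores binding-pocket polarity with the lipophilicity index,
    back-calculates logP from MLP sums with calibrated linear weights,
    post-processes docking pose ensembles (RMSD clustering, top-pose
    summaries, Gibbs free energy to dissociation-constant conversion),
    and estimates apparent permeability (Papp) from Transwell
    time-courses with sampling-replacement correction and quadratic
    initial-slope fitting. Includes seeded synthetic-data generators
    for cage-like hosts, docking ensembles, and two-compartment
    diffusion time-courses so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    bio3d,
    jsonlite,
    yaml,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
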