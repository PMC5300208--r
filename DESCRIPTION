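Package: gagmimic
Title: Ensemble-Based Assessment of Glycosaminoglycan Mimicry by Sulfated Small Molecules
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether a synthetic sulfated small molecule
    (a non-saccharide glycosaminoglycan mimetic, NSGM) structurally mimics a
    target glycosaminoglycan such as a heparan sulfate hexasaccharide, from
    molecular-dynamics conformational ensembles. Provides readers for
    multi-model PDB files and plain coordinate tables; per-frame shape
    descriptors (end-to-end distance, minimum-volume enclosing ellipsoid via
    Khachiyan's algorithm, optimal-superposition RMSD, RMSD to the average
    structure, positional principal components); RMSD-radius conformer
    clustering with medoid representatives; geometric hydrogen-bond detection
    and residue-level occupancy profiling; ingestion of per-residue
    binding-energy decompositions; and a three-leg decision procedure
    (free-state shape comparison, binding-site identity, bound-state
    interaction and energetics comparison) that ranks candidate mimetics
    against a reference glycosaminoglycan. Seeded synthetic-ensemble
    generators with recorded ground truth support fully reproducible testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
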