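Package: filterdyn
Title: Selectivity-Filter Dynamics of K+ Channels from NMR and Structural Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for potassium-channel selectivity-filter modal
    gating. Quantifies chemical-shift perturbations between channel variants
    (per-nucleus and combined amide CSPs), fits mono-exponential rotating-frame
    (R1rho) and longitudinal (T1) relaxation decays into per-residue rate
    profiles with standard errors, maps H/D-exchange protection from paired
    protonated/deuterated peak intensities, classifies inwards/outwards
    carbonyl states of filter residues from backbone dihedrals of structural
    ensembles, measures hydrogen-bond, rotamer and buried-water occupancies,
    and back-calculates population-weighted chemical shifts so that predicted
    and experimental CSPs can be compared. Includes seeded synthetic-data
    generators with planted ground truth for every input stream, readers for
    NMR-STAR v3 chemical-shift loops, TSV tables and PDB ensembles, and a
    config-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    bio3d,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
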