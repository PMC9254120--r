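Package: lipidsites
Title: Lipid Binding-Site Detection, Residence-Time Kinetics and
    Receptor Dose-Response Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of lipid-protein interactions from molecular dynamics
    trajectories of membrane proteins: dual-cutoff (hysteresis) contact
    detection, survival-curve residence-time kinetics with bootstrap
    uncertainty, binding-site identification by co-contact community
    detection, representative bound-pose extraction with orientation
    classification, and occupancy-titration estimation of apparent
    dissociation constants in mole-percent units. Also implements
    dose-response statistics for hormetic (bell-shaped) cAMP responses:
    three-parameter logistic and superposed stimulatory/inhibitory fits,
    pertussis-toxin subtraction of the inhibitory component, a combined
    Emax/EC50 agonism index with regression against cellular cholesterol,
    and the glucagon-alanine index. Includes a ground-truthed synthetic
    bilayer-trajectory and dose-response generator so every stage is
    verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    igraph,
    minpack.lm,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'contacts.R'
    'kinetics.R'
    'md_io.R'
    'pharm.R'
    'pipeline.R'
    'sites.R'
    'synthetic.R'
    'titration.R'
    'utils.R'
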