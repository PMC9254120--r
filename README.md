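# lipidsites

Analysis of lipid–protein interactions from molecular-dynamics
trajectories of membrane proteins, plus the dose-response statistics used
to connect membrane cholesterol to receptor signalling. The package was
built around the question of how cholesterol engages a class B GPCR (the
glucagon receptor): where cholesterol binds on the transmembrane surface,
how long it stays, how tightly it binds in mole-% units, and how the
receptor's hormetic cAMP response decomposes into Gαs and Gαi components.

**Who it is for:** computational membrane biologists analysing
coarse-grained or atomistic bilayer trajectories, and pharmacologists
fitting bell-shaped cAMP concentration-response data.

## What it computes

* **Dual-cutoff contacts** — a lipid–residue contact opens when the
  minimum-image minimum distance falls strictly below a lower cutoff
  (default 0.475 nm, coarse-grained) and closes when it reaches an upper
  cutoff (0.70 nm); hysteresis suppresses boundary rattling. Events open
  at the final frame are kept for occupancy but flagged censored for
  kinetics.
* **Residence times** — the survival curve of event durations
  `S(t) = #{d >= t}/N` is fitted with
  `S(t) = A exp(-k1 t) + (1-A) exp(-k2 t)` (mono/biexponential, corrected
  AIC selection on the event-level likelihood); the residence time is
  `tau = 1/k2`, with a bootstrap percentile CI.
* **Binding sites** — residues are joined by the fraction of frames in
  which one lipid molecule touches both simultaneously; seeded Louvain
  community detection on that graph yields sites, scored by occupancy and
  site-level `tau`, with RMSD-clustered representative bound poses and
  per-frame cholesterol orientation (canonical vs flipped, from hydroxyl
  vs ring height relative to the bilayer midplane).
* **Occupancy titration** — across bilayer compositions,
  `Occ(x) = Occ_max * x / (Kd_app + x)` is fitted against the free
  cholesterol mole % (unbound cholesterol over all lipids,
  time-averaged), giving an apparent dissociation constant with a
  profile-likelihood CI.
* **Dose-response** — 3-parameter logistic and bell-shaped
  (superposed stimulation/inhibition) fits with Hill slopes of 1; the Gαi
  component by pertussis-toxin subtraction; the combined agonism index
  `log10[(Emax/EC50)_treatment / (Emax/EC50)_vehicle]` and its regression
  on cellular cholesterol; the glucagon–alanine index.
* **Synthetic ground truth** — a bilayer-trajectory generator with
  planted sites and Markovian on/off kinetics (`Kd = k_off / c` exactly,
  exponential dwell times) and a hormetic dose-response generator, so
  every stage above is verifiable end to end.

## Worked example

Generate the default synthetic system — 100 lipids at 25 mole-%
cholesterol, 20 µs at 1 ns/frame, two planted sites: a deep flipped-pose
site (tau 0.8 µs, Kd 6.6 mole %) and a canonical site (tau 0.25 µs,
Kd 15 mole %) — and analyse it:

```r
library(lipidsites)

spec <- syntheticSpec(seed = 1)
gen <- generateMembraneTrajectory(spec)
contacts <- detectContacts(gen$trajectory, gen$topology)
contacts
#> ContactSet (cholesterol): 1007 events, 25 lipid molecules, 20000 frames
#>   cutoffs 0.475/0.700 nm, stride 1

sites <- scoreSites(detectSites(buildCoContactGraph(contacts), seed = 2),
                    contacts, seed = 3)
siteTable(sites)
#>   site_id n_residues occupancy_pct   tau_ns ci_low_ns ci_high_ns n_events flag
#> 1  site-1          6        73.165 651.8622  464.8494   982.6630       25   ok
#> 2  site-2          6        61.585 269.7651  215.5391   381.4287       50   ok
```

Both planted sites are recovered with their exact residue membership. The
top-ranked site's fitted residence time (0.65 µs, 95% CI 0.46–0.98) brackets
the planted 0.8 µs from only 25 events; the faster site (planted 0.25 µs)
fits at 0.27 µs. Orientation of the bound cholesterol at the top site:

```r
ors <- siteOrientations(sites, "site-1", contacts,
                        gen$trajectory, gen$topology)
mean(ors$orientation == "flipped")
#> [1] 1
```

— every occupied frame shows the hydroxyl-toward-midplane (flipped) pose
that was planted there. The same objects export as CSV/JSON/PDB via
`writeContactEvents()`, `writeSiteTables()`, `writePoses()` and
`writeSaturationReport()`, and the whole chain runs from one YAML
configuration with `runPipeline()` (see
`inst/scripts/run-pipeline.R` for a shell entry point).

## Layout

* `R/` — implementation (S4 classes with validity/show methods; one file
  per analysis stage).
* `tests/testthat/` — unit, property and acceptance tests; all fixtures
  are generated in code.
* `vignettes/lipid-site-kinetics.Rmd` — the methods vignette: models,
  assumptions, parameter choices, numerical decisions, limitations.
* `scripts/acceptance.R` — headline-number reproduction (above).
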