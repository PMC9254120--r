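---
title: "Lipid binding-site kinetics, occupancy titration and hormetic dose-response analysis"
author: "lipidsites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lipid binding-site kinetics, occupancy titration and hormetic dose-response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidsites)
```

# The problem

Cholesterol modulates the signalling of membrane receptors such as the
glucagon receptor, in part by binding at specific sites on the
transmembrane surface. Coarse-grained molecular dynamics makes the
multi-microsecond sampling needed to see such lipid binding feasible, but
turning raw trajectories into *sites*, *residence times* and *apparent
affinities* is an analysis problem of its own. `lipidsites` implements that
analysis end to end:

1. **Contact detection** with a dual-cutoff (hysteresis) scheme,
2. **Residence-time kinetics** from survival curves of contact durations,
3. **Binding-site identification** by community detection on a residue
   co-contact graph, with representative bound poses and cholesterol
   orientation classification,
4. **Occupancy titration** across bilayer compositions yielding an apparent
   dissociation constant $K_d^{app}$ in mole-% units,
5. **Dose-response statistics** for the hormetic (bell-shaped) cAMP
   response that arises from superposed G$\alpha_s$ stimulation and
   G$\alpha_i$ inhibition,
6. A **ground-truthed synthetic generator** so that every stage can be
   verified quantitatively without external data.

All internal units are nm and ns; file I/O converts at the boundary
(PDB Ångströms, GRO nm). Only orthorhombic boxes are supported — bilayer
systems in scope are orthorhombic, and this keeps the minimum-image
distance contract exactly testable.

# Contact detection: the dual-cutoff rule

A lipid–residue contact opens when the minimum distance between the lipid's
particles and the residue's particles drops strictly below a lower cutoff,
and remains open until the distance first reaches or exceeds an upper
cutoff. The hysteresis suppresses the rapid boundary rattling that a single
threshold would count as many spurious events. Boundary conventions are
fixed — strict `<` to open, `>=` to close — so results are bit-exact
reproducible; with equal cutoffs the scheme degenerates to plain
thresholding.

Defaults are 0.475/0.70 nm for coarse-grained and 0.35/0.55 nm for
atomistic resolution — conventional values for this family of methods, and
deliberately configuration rather than constants, since appropriate cutoffs
depend on the force field. An event still open at the trajectory's final
frame is *censored*: it counts towards occupancy but is excluded from
kinetic fits by default, which avoids silently biasing the off-rate
downward. A Kaplan–Meier-style inclusion (via the survival package) is
available behind `policy = "km"` for datasets where censoring is heavy.

```{r contacts-demo}
d <- c(0.50, 0.45, 0.60, 0.70, 0.80, 0.40)   # nm
lipidsites:::hysteresisBound(d, 0.475, 0.70)
```

# Residence times

The empirical survival curve of event durations, $S(t) = \#\{d \ge t\}/N$,
is fitted with
$S(t) = A e^{-k_1 t} + (1 - A) e^{-k_2 t}$, $k_1 \ge k_2$, and the
mono-exponential special case. Fitting happens in log-survival space with
weights $N \cdot S(t)$ (more events surviving, more information) and
deterministic multi-starts, which stabilises the ill-conditioned
biexponential problem. The residence time is defined from the slower rate,
$\tau = 1/k_2$, matching how long-lived lipid interactions are reported in
the field.

Model selection is deliberately split from parameter estimation: the
survival-grid residuals are neither independent nor homoscedastic, so an
information criterion computed on them badly over-selects the biexponential
(we measured roughly half of pure-exponential datasets). Instead, the
corrected AIC is evaluated on the exponential-mixture likelihood of the raw
durations (which *are* iid), and the biexponential is accepted only with
the conventional $\Delta\mathrm{AICc} > 2$ support margin, a fast
amplitude $A \in (0.02, 0.98)$ and rate separation $k_1/k_2 \ge 2$. On pure
exponential data this selects the mono model in $\ge 95\%$ of replicates
while still identifying well-separated two-phase data essentially always.

Uncertainty comes from a percentile bootstrap over durations (default 200
resamples, seed mandatory); the bootstrap refits within the selected model
family. Fits with fewer than 20 events are returned flagged `"low_n"`
rather than failing, because sparse sites are common and a flagged estimate
is more useful than an error.

# From contacts to sites

Residues that hold the *same* lipid molecule at the *same* time belong
together: the co-contact graph weights each residue pair by the fraction of
frames in which at least one single lipid bridges both. Sites are
communities of this graph found by seeded Louvain modularity maximisation
(resolution 1.0), after pruning edges below a weight floor (default 0.05)
and discarding communities smaller than 4 residues or without any internal
edge — both suppress spurious one-residue "sites" from incidental contacts.
Sites are ranked by residence time with occupancy as tie-break; the ranking
statistic is a documented choice, since occupancy and kinetics can order
sites differently.

Site-level events apply the maximal-run rule to the per-lipid OR over site
residues, so site occupancy is always at least the best per-residue
occupancy. Representative poses are extracted from occupied frames,
superposed on the site residues (Kabsch, with minimum-image unwrapping
around the site), clustered by RMSD over the lipid particles
(average-linkage, cut at 0.2 nm by default), and ranked by cluster size;
each cluster is represented by its medoid, with ties broken by earliest
frame so that the output is deterministic.

Cholesterol orientation is classified per frame by comparing the height of
the hydroxyl (head) particle and of the ring centre (centroid of the
remaining particles) against the bilayer midplane, estimated as the mean
z of all lipid particles (robust to bilayer drift): a pose whose hydroxyl
sits nearer the midplane than its ring centre is *flipped* — the
orientation reported for the deep TM6/TM7 cholesterol site of the glucagon
receptor — otherwise *canonical*.

# Occupancy titration and $K_d^{app}$

Across bilayers of varying cholesterol content, site occupancy follows a
saturation curve in the *free* cholesterol fraction. Free cholesterol % is
defined here as unbound cholesterol molecules over **all** lipid molecules,
time-averaged; this keeps $x$ on the familiar mole-% composition scale
while correcting for protein-sequestered cholesterol, and the definition is
recorded in every report since other normalisations are conceivable.

`fitSaturation()` fits
$Occ(x) = Occ_{max}\, x / (K_d^{app} + x)$, optionally plus a linear
non-specific term, weighted by $1/SE^2$ when standard errors are supplied.
The 95% CI for $K_d^{app}$ is profile-likelihood based (Wald intervals
undercover for this curved parameter; we measured the difference in seeded
simulations). A dataset is flagged `non_saturable` only when a pure line
carries at least as much AICc support as the hyperbola **and** the fitted
$K_d^{app}$ lies beyond the sampled composition range — i.e. when
half-saturation was never actually observed. Compositions, replicates and
trajectory paths come from an explicit manifest; the tool never infers
composition from file names.

# Hormetic dose-response decomposition

The glucagon receptor's cAMP concentration-response is bell-shaped:
G$\alpha_s$-mediated stimulation engages at low agonist concentrations and
G$\alpha_i$-mediated inhibition at roughly ten-fold higher ones. The
package fits, with Hill slopes fixed at 1 (three-parameter convention):

* `fitLogistic3`: $R(c) = basal + (E_{max} - basal)/(1 + EC_{50}/c)$
* `fitBell`:
  $R(c) = basal + span_s/(1 + EC_{50,s}/c) - span_i/(1 + EC_{50,i}/c)$,
  with $EC_{50,i} = EC_{50,s} \cdot 10^{\delta}$, $\delta \ge 0$ — the
  parameterisation both encodes the biological ordering of the two
  potencies and stabilises the fit.

A bell fit collapses to the logistic (and says so) when the nested model
has at least equal AICc support; without this, stimulatory and inhibitory
spans with similar potencies can cancel into a degenerate but
equal-residual fit. The G$\alpha_i$ component is isolated operationally:
responses measured under pertussis toxin (which blocks G$\alpha_i$) are the
G$\alpha_s$-specific response, and the pointwise difference PTX − total is
the positive-signed G$\alpha_i$ suppression, summarised by its trapezoidal
AUC over $\log_{10}$ concentration. `agonismIndex` combines efficacy and
potency as $\log_{10}[(E_{max}/EC_{50})_{treat}/(E_{max}/EC_{50})_{veh}]$,
which is invariant to common response rescaling and zero for vehicle;
`cholesterolResponseRegression` regresses it on relative cellular
cholesterol. `glucagonAlanineIndex` is the plain product of fasting
glucagon (pmol/L) and alanine (mmol/L), a surrogate of glucagon
resistance.

# The synthetic generator

The generator's purpose is exact ground truth, not physics. Binding is a
site-level continuous-time Markov chain made spatially consistent
afterwards: a free site binds a cholesterol with per-frame probability
$c \cdot x \cdot \Delta t$ ($x$ = instantaneous free cholesterol mole %)
and releases it with probability $k_{off} \Delta t$, so equilibrium
occupancy is exactly $x/(x + K_d)$ with $K_d = k_{off}/c$ and bound
durations are exponential with mean $1/k_{off}$. The recruited molecule is
the nearest free cholesterol (preferring those inside the capture disc);
gating the *hazard* itself on proximity would make the realised $K_d$
depend on diffusion and destroy the exactness the recovery tests rely on —
the well-mixed assumption is therefore part of the model's definition.

Geometry: cholesterol is three beads (hydroxyl, ring centre, tail) so
orientation classification is exercisable; phospholipids are single head
beads; each planted site is a ring of residue beads around an anchor, with
bound cholesterol placed at the anchor (small jitter, inside the lower
contact cutoff of all site residues) and written hydroxyl-toward-midplane
at flipped-designated sites. Free lipids perform 2D Brownian motion in
their leaflet, wrapped periodically and excluded from a disc around each
site axis (so spontaneous approaches never masquerade as binding); a
molecule returns to its home leaflet on release, keeping leaflet
compositions stationary. Decoy protein beads away from the sites generate
realistic incidental contacts that the community detection must reject.

Default desk-scale conditions: 100 lipids at 25 mole-% cholesterol —
the plasma-membrane-like cholesterol content of the study system — with
two planted sites, a deep flipped-pose site with $\tau = 0.8\ \mu s$ and
$K_d = 6.6$ mole % (the strong-site regime reported for cholesterol on
several membrane proteins) and a canonical site with $\tau = 0.25\ \mu s$,
$K_d = 15$ mole %; 20,000 frames at 1 ns/frame. Titration datasets default
to 5 µs per replicate. These sizes run in seconds to a couple of minutes on
a laptop while leaving enough events (tens per site) for meaningful
kinetics.

What passing tests on this generator do **not** show about real data:
there are no membrane undulations, no competing lipid species, no
multi-site cooperativity, no force-field energetics, and binding events
are geometrically clean. Recovery of planted parameters demonstrates that
the *analysis* is correct and calibrated, not that any particular force
field or system is.

```{r end-to-end, eval = FALSE}
spec <- syntheticSpec(seed = 1)
gen <- generateMembraneTrajectory(spec)
contacts <- detectContacts(gen$trajectory, gen$topology)
sites <- scoreSites(detectSites(buildCoContactGraph(contacts), seed = 2),
                    contacts, seed = 3)
siteTable(sites)
```

# Numerical choices and degenerate inputs

* Nonlinear fits use Levenberg–Marquardt (minpack.lm) with deterministic
  multi-start grids; every stochastic step requires an explicit seed, and
  reruns of the pipeline with an identical configuration are byte-identical
  (volatile output paths are excluded from the report).
* Ties in pose ranking and medoid choice break towards the earliest frame.
* Empty inputs are errors where the result would be meaningless (empty
  selections, empty survival input, fewer than 3 distinct compositions,
  fewer than 4/6 distinct concentrations); they are *flagged results*
  where a partial answer is useful (low event counts, all-zero
  occupancies, non-saturable titrations, collapsed bell fits).
* Same-frame exchange of a site's cholesterol for the same molecule can
  merge two ground-truth events into one detected event; this is a
  property of frame-resolution contact analysis generally, is rare at the
  default rates, and biases $\hat\tau$ upward by well under the bootstrap
  CI width at the study conditions.
* The Kd of a slow site ($\tau$ near a microsecond) sampled for a few
  microseconds per replicate is intrinsically noisy — a handful of binding
  sojourns per window. The saturation fit's profile CI reflects this
  honestly; point estimates at desk scale scatter by a factor of about two
  around the planted value, which is why the recovery properties are
  stated as CI coverage rather than point accuracy.
* Small bilayer patches add a finite-size depletion artifact to
  titrations: one protein-bound cholesterol is a full mole-% of a
  100-lipid patch, which lowers the measured free-cholesterol axis at low
  compositions and steepens the apparent curve (about a 10% downward pull
  on $K_d^{app}$ at 100 lipids, under 3% at 400). The headline-number
  script therefore titrates a 200-lipid patch; users analysing real
  coarse-grained systems (hundreds of lipids per leaflet) are unaffected.

# Problem sizes used by the tests

The test suite and the acceptance script choose desk-scale sizes as the
package's own study conditions: contact-oracle equivalence on 1,000 random
series; kinetics calibration on 200 datasets of 200 events (point recovery
on 2,000 events); planted-site recovery on the default 20,000-frame system
(50,000 frames in the acceptance script, i.e. 50 µs); Kd coverage on 100
seeded titrations spanning the planted $K_d \in \{6.6, 10.7, 15.0,
18.3\}$ mole %; and full-pipeline determinism on a 2,000-frame system.

# Known limitations

* XTC trajectories are not read; use multi-model PDB, multi-frame GRO or
  DCD.
* Triclinic boxes are rejected rather than approximated.
* The co-contact graph uses binary bound states; no interaction-strength
  weighting beyond co-occupancy frequency.
* Assigning sites to helices is reporting metadata, not computed.
* Inter-condition hypothesis testing (ANOVA and friends) is out of scope;
  base R provides it directly on the exported tables.
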