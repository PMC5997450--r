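---
title: "Methods: quantifying neuromast microcircuits from contour annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying neuromast microcircuits from contour annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuromast)
```

This vignette documents the models, rules, and numerical choices behind the
package: what each stage computes, which parameters matter and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the known limitations.

## The system and its vocabulary

A neuromast is a discrete lateral-line organ of the larval zebrafish
containing 8–20 hair cells between supporting and mantle cells. Hair cells
arise as sibling pairs from one transit-amplifying division; after a
rotatory rearrangement, the more anterior sibling normally becomes
sensitive to caudad water motion and the posterior sibling to rostrad
motion. Afferent axonal branches from the posterior lateral-line nerve
cross the basal lamina, occupy perisynaptic compartments beneath hair-cell
synaptic poles, and receive input at ribbon synapses; a single efferent
terminal innervates every mature hair cell.

Two distinctions run through the data model and are easy to conflate:

* **Sensitivity vs position.** *Rostrad*/*caudad* always name the
  direction of water motion a cell or terminal responds to, never where
  the cell sits. A cell's position relative to its sibling after
  rearrangement is the separate `ap_position` field
  (anterior/posterior/unresolved). In wild type the two correspond; in the
  mutants analysed here they decouple, which is exactly why both fields
  exist.
* **Age classes.** Post-mitotic age is categorical: 0–5 h (nascent, no
  definite polarity, no stable position, no ribbons yet), 5–15 h, and
  >15 h. Nascent cells are excluded from specificity and mixed-innervation
  statistics because neither grouping is defined for them; they are
  retained in redundancy and dominance summaries.

## Contact geometry

Annotations arrive as closed polygonal membrane traces per cell per
section, in nm, with 30 nm section spacing and 6 nm lateral pixels. Manual
tracing follows a membrane with a precision of roughly ±60 nm, so two
membranes are scored as in contact wherever their traces are separated by
**less than 60 nm** (strict inequality, `contact_threshold`) **and no
other trace intervenes**. Contact length on a section integrates to area
as `area = Σ length × section_thickness`.

Numerical choices:

* **Arc sampling.** One boundary is sampled at arc-length midpoints with
  step `arc_sampling_step` (default 6 nm, the pixel pitch, so that contact
  *localization* is resolved no finer than the source data). Intervals
  adjacent to an accept/reject flip are re-measured at 1 nm so the
  *arc-length integral* does not accumulate localization error; without
  this, short contacts carry discretization error of order one step per
  boundary transition.
* **Occlusion.** "No other trace intervened" is not defined geometrically
  by the tracing convention, so two operationalizations are provided.
  `strict` (default): the straight segment from a sample point to its
  nearest point on the other trace must cross no third-trace boundary.
  `corridor`: additionally, no third trace may enter the quadrilateral
  spanned by consecutive matched point pairs. Both modes agree on the
  fixtures tested; `strict` is the default because it matches the
  point-to-nearest-membrane reading most directly.
* **Symmetry.** Directed contact length (arc of A near B) genuinely
  differs from its reverse when boundary curvatures differ — a sharp
  vertex of one cell can face a long flat stretch of the other — so
  `contact_area()` reports the mean of the two directed lengths per
  section, making the result symmetric in its arguments by construction.
  On parallel straight edges the two directions agree to within sampling
  error.
* **Parallel-edge closed form.** Two facing edges of length $L$ at gap
  $g < t$ (threshold $t$) have contact length $L + 2(t-g)$, not $L$: the
  boundary just beyond each corner is still within $t$ of the opposing
  membrane. The trace-fixture generator records both this corrected form
  and the naive facing-edge form in its ledger; tests assert against the
  corrected one.
* **Defects.** Intersecting traces of the two cells under comparison are a
  segmentation error and abort the computation; containment (one ring
  inside another) is legitimate geometry and is handled.
* **Oracle.** `brute_force_contact_area()` re-implements the contract by
  dense point sampling (≤1 nm) of both boundaries with exhaustive
  occlusion checks. The test suite compares the two implementations on
  hundreds of random convex polygon pairs; agreement is asserted within 2%
  or the area of one sampling step of arc per boundary, whichever is
  larger, since contacts shorter than a few pixels cannot be resolved more
  finely than the data.

Apical contact area — a maturity feature — is the cell's trace perimeter ×
thickness summed over annotated apical sections; which sections are apical
is an annotation (`geometry_config(apical_sections=)`), not an inference.

## Annotation rules

* **Efferent identification.** A terminal is efferent iff it contacts
  every mature hair cell, is apposed to zero ribbons, and (by default)
  carries both structural flags (vesicle-filled bouton, postsynaptic
  cistern). The flag requirement is configurable because the wiring rule
  alone identifies the efferent in clean data, but the flags guard against
  a promiscuous afferent in small organs. More than one candidate warns
  rather than errors: occasional neuromasts carry two.
* **Ribbon partners.** The terminal with the largest annotated apposition
  area opposite a ribbon receives it (weight 1). "Occupied equally" is
  quantified as a relative area difference ≤ `tie_area_tolerance`
  (default 0.10 — the annotation literature gives no tolerance, so a
  round 10% is used and exposed); equal occupants each receive half the
  ribbon. At most two terminals share a ribbon; ribbons with no apposed
  terminal are flagged unpartnered and counted separately rather than
  dropped.
* **Polarity preference.** A terminal's preference is the majority group
  by summed ribbon weight over mature polarized cells; ties and
  ribbon-less terminals fall back to the contact-area majority, mirroring
  how preference is inferred for terminals on nascent cells from their
  innervation by neighbouring mature cells; a persisting tie leaves the
  terminal unassigned. Immature cells never vote. Note the consequence:
  a terminal whose *only* ribbon is a wiring error is called by that
  ribbon, so pipeline-derived mismatch counts can undercount planted
  errors; exact ledger comparisons therefore fix preferences to the
  planted identities (`apply_planted_identities()`).

## Statistics

Specificity, redundancy, dominance, sibling exclusivity, mixed-terminal
fraction, and branch counts are all computed per specimen and pooled.
Pooling is by summed counts and areas (micro-average); per-specimen
fractions are reported alongside since macro- and micro-averages can
differ and the choice is not standardized. Half-ribbons contribute
fractional weight to weighted tallies; integer active-zone counts (each
ribbon once) are reported in parallel and used wherever whole-synapse
counts are the natural unit. Contact-area specificity is reported pooled
over all polarized cells and per age class, covering both plausible
readings of an "overall" figure. Group comparisons use the classic
pooled-variance two-tailed Student's *t* test with SEM error bars and
0.05/0.01/0.001 star coding; no multiple-testing correction is applied,
matching standard practice for these descriptive panels.

For *trilobite* and Notch-overexpression specimens, bundle polarity is
uninformative (random orientations, or uniformly rostrad), so grouping
switches to `ap_position` — cells are scored by whether they completed
rearrangement anterior or posterior to their sibling.

## Age classification

Four features per cell — membrane area (perimeter × thickness summed),
volume (polygon area × thickness summed), total ribbon volume, apical
contact area — feed a CART classifier: binary axis-aligned splits
minimizing Gini impurity. CART is implemented directly (about eighty
lines) rather than wrapped, because the tree is part of the specified
method and a self-contained implementation is fully serializable to JSON
(feature index, threshold, children, leaf class) and deterministic;
`rpart` serves as an independent cross-check in the tests, never as the
implementation. Defaults `max_depth = 3`, `min_leaf = 3` suit the
~90-labelled-cell regime this classifier targets (88 labelled of 149
cells); both are exposed. Features are not standardized — axis-aligned
thresholds are scale-equivariant, and the tests assert prediction
invariance under a consistent nm→µm unit change. The train/test split
(default 70/30) is the only randomness; fits are reproducible given the
seed.

## The synthetic-data generator

The generator emulates the *statistical wiring structure* of the three
genotypes at the table level, with a ledger recording every draw. Wiring
rules:

* **Wild type** — siblings take opposite positions and opposite
  polarities; wiring identity follows polarity.
* ***trilobite*** — the two wiring identities are still uniquely allocated
  within each pair, but at random with respect to position; bundle
  orientations are uniform on the circle (recorded in the ledger;
  `polarity` is undetermined).
* **Notch overexpression** — both siblings receive the same wiring
  identity and all bundles are rostrad-sensitive; each cell contacts the
  full terminal set of its identity, so sibling pairs universally share
  innervated terminals.

Each mature cell draws a ribbon count by age class (`1 + Poisson(mean−1)`,
defaults 2.5 and 5 for 5–15 h and >15 h — the printed record fixes the
1-to-6 range of per-edge synapse counts and the rise of partners from one
to two with age, but not a distribution, so these means are the package's
choice); each ribbon independently goes to a terminal of the cell's
identity with probability 1−ε (default ε = 4/344, the observed wild-type
error rate), choosing among the identity's terminals by the dominance
simplex (default 0.55/0.30/0.10/0.05). Because allocation is per-ribbon,
per-terminal shares are unbiased multinomial proportions and the planted
weights are recoverable; distinct-partner counts per cell are emergent
(≈1.3 rising to ≈2.3 under the defaults) rather than planted directly.
Membrane contacts are planted for every ribbon partner; stray
opposite-identity contact area is topped up to a fraction `contact_error`
(default 0.08, matching 92% area specificity) of the cell's afferent
contact area, on terminals the cell's *sibling* does not innervate —
without that exclusion, stray contacts collide with sibling partners and
destroy the near-perfect sibling exclusivity that is a robust feature of
the real circuit. Perisynaptic compartments receive terminals of both
identities, making perisynaptic occupancy essentially unselective, as
observed. One efferent contacts every mature cell; one nerve fiber never
crosses the basal lamina (excluded from all statistics); afferents beyond
the two identity groups taper without synapsing. The age mix defaults to
0.20/0.35/0.45 across the three classes — no class proportions are
printed for the real organs, so this is a plausible maturing-organ mix,
chosen once.

What the generator does **not** emulate: spatial geometry of real cells
(wiring is table-level; trace stacks are a separate rectangular fixture
path), age-dependent dominance (a single dominance simplex serves all
ages, so the generator does not reproduce the *rise* of per-cell dominance
with age seen in real data — young cells' high dominant shares here are a
small-count artifact), per-age contact-area distributions (simple
log-normal stand-ins), and developmental dynamics. Passing tests
therefore demonstrate correctness of the *pipeline computations* on data
with known structure, not biological fidelity of every marginal
distribution.

The age-cohort generator scales every class-dependent effect — including
the near-absence of ribbons in nascent cells — by a single `separation`
multiplier, so `separation = 0` yields genuinely class-blind features
(chance-level classification) and large values yield separable classes.

## Problem sizes and determinism

Test and calibration sizes are chosen to give stable statistics at
interactive cost: ≥200 random polygon pairs for the geometry oracle, 50
neuromasts for dominance recovery and position–identity independence,
1000 simulations for *t*-test type-I calibration, 200 permuted-label
refits for the classifier null, and 100 seeds for generator validity.
Every stochastic routine takes an explicit seed, runs on a private RNG
stream, and restores the caller's stream; pipeline reports are
byte-reproducible from (config, seed), and the run manifest records both.

## Known limitations

* Contact areas are planar per-section integrals; no 3-D mesh or
  curvature correction is attempted, matching how the source annotations
  are made.
* Perisynaptic membership is an input annotation; it cannot be recovered
  from hair-cell and terminal traces alone because the compartment is
  bounded by supporting cells.
* The exact column layout of externally deposited measurement tables is
  not standardized; reproducing statistics from such tables requires a
  small mapping adapter onto the TSV schema documented in
  `?load_annotation_tables`.
* Whether the original contact measurements were directed or symmetric,
  and the precise geometric occlusion test used, are unrecorded; both
  occlusion modes and the symmetrized area are provided and documented.
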