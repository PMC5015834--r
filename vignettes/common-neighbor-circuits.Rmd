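---
title: "Methods: the common-neighbor rule and homogeneous circuit detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the common-neighbor rule and homogeneous circuit detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnrsets)
```

# The data model

A connectome here is a set of named neurons carrying an optional functional
layer (sensory, inter, premotor, motor) and an optional scalar soma
position in [0, 1] along the anterior–posterior axis, plus two edge
classes:

* **chemical synapses** — directed, weighted by synapse count;
* **gap junctions** — electrical couplings stored once per unordered pair
  and treated as bidirectional in every query. Real wiring data rarely
  resolve gap-junction directionality, so symmetry is an explicit modeling
  assumption, not a fact about the biology.

"Neighbor" is always direction-blind: X neighbors Y if any chemical synapse
(either direction) or gap junction links them. A *common neighbor* of a
pair is a third neuron linked to both members. A dyad's state is `none`,
`forward`, `backward` or `reciprocal`; a gap junction alone, or a chemical
synapse one way plus a gap junction, makes a dyad `reciprocal`. The
chemical-only network used by `chemicalOnlyReanalysis()` is produced by
channel filtering of the same object, never by a second loader.

# The common-neighbor rule

`cnrCurve()` bins all unordered pairs by common-neighbor count and records
the connected fraction per bin. Parameters:

* `minPairsPerBin` (default **5**): bins with fewer pairs are excluded from
  the least-squares line. High common-neighbor counts are reached by a
  handful of hub-dominated pairs; fitting through single-pair bins would
  let them steer the slope. The fit is unweighted by default ("fit a line
  through the bin fractions"); a pair-count-weighted fit is available
  behind `weighted = TRUE`.
* When fewer than two bins are eligible the fit is *flagged infeasible*
  (`fit$feasible = FALSE`, statistics `NA`) rather than raising an error —
  a legitimate outcome for dense toy graphs such as a clique.

`ensembleSlopeTest()` compares the observed slope against
`nNetworks` nulls by z-score with a two-sided normal p. Two generators:

* `degree_preserving` — repeated double-edge swaps, chemical and gap layers
  shuffled independently and never interconverted (the two synapse classes
  are biologically distinct, and their composition is analyzed separately
  downstream). `swapFactor = 10` attempted swaps per edge is a standard
  mixing heuristic. Edges are drawn with replacement per attempt; drawing
  the same edge twice is a rejected attempt, which keeps the accepted-swap
  count stochastic even in degenerate graphs. Weights ride with their
  edges, so weight multisets per layer are conserved along with every
  neuron's chemical in-degree, chemical out-degree and gap degree.
* `erdos_renyi` — a directed chemical-only graph matched on node count and
  on directed-link count, with each gap junction counted as two directed
  links (it is bidirectional in every query). All null weights are 1.

Nulls with infeasible fits are dropped and counted; more than 20% dropped
aborts the test.

## Distance controls

`distanceAnalysis()` correlates either common-neighbor count or a 0/1
connected indicator with the absolute soma-position difference, reporting
Pearson r and the one-tailed t-based p (negative tail), with a degenerate
flag (r = NA, p = 1) when either variable has zero variance. Two pair
scopes are implemented because "the number of common neighbors of a
connected pair" can be read over connected pairs only or over all pairs;
reports state which was used.

**Calibration caveat.** The t-test treats the C(N,2) pairs as independent
observations, but pairs sharing a neuron are strongly dependent — the
effective sample size scales with the number of neurons, not pairs. Under a
distance-independent null the p-values are therefore anti-conservative,
increasingly so as networks grow. The package keeps the conventional t
formula because it is the field's reporting convention for these
descriptive correlations, but r itself, not its p, is the quantity to
interpret; the test suite accordingly checks that r is unbiased around zero
under a null, not that p is calibrated.

# The 21-triad taxonomy

With role identity preserved (X, Y the focal pair, Z the shared neighbor),
the X–Y dyad is forward, reciprocal or none, and each pair–Z dyad is
forward (member→Z), backward or reciprocal — never none, or Z would not be
a common neighbor. X and Y are exchangeable exactly when their dyad is
symmetric (reciprocal or none), so the count is 3·3 = 9 ordered
combinations for forward pairs plus 6 unordered combinations each for
reciprocal and unconnected pairs: **21 types**.

Ids follow a single lexicographic rule — state order forward < backward <
reciprocal, X-dyad outer, forward-XY block first — which reproduces all the
anchored identities (#1 multi-output FFL, #2 multi-inter FFL, #5
multi-input FFL, #10 mutually regulating, #13 mutually regulated, #15 fully
bidirectional). All internal statistics are keyed by the canonical dyad
triple, not by id, so a numbering transposition could not corrupt results;
the anchors are unit-tested, and classification is cross-checked against a
brute-force classifier over every dyad combination.

`extractSets()` keeps pairs with at least `minNeighbors` common neighbors
(default **5**: below that, a set dominated by one type arises too easily
by chance) and reorients backward pairs so X is always the source of a
directed X–Y link.

# Homogeneity and enrichment

For each set the dominant type is its most frequent member type. Ties are
broken by the smaller hypergeometric p, then the lower canonical type id —
a deterministic rule favoring the more surprising type (the data do not
dictate one; this is the package's choice). The score is the upper-tail
hypergeometric probability of k or more dominant-type members given the
type's abundance across *all sets of the same connectivity class* — pooling
the population within class keeps connected and unconnected analyses
self-contained, and which pooling the original analyses used is not
recoverable, so the choice is recorded in every report. A set is
homogeneous when p ≤ `alpha` (default 0.05, per set, uncorrected — the
set-level threshold is a descriptive filter, not a family-wise claim) and
at least `majorityFraction` (default ½) of members share the dominant type.

A consequence worth knowing: a population consisting of a single pure set
can never be homogeneous — its type's global abundance *is* the set, so
p = 1. Homogeneity is always relative to a population.

`shuffleSets()` permutes the pooled member-type labels across all member
slots, conserving every set size and the global type multiset exactly; this
is the null for `enrichmentTests()`, which recomputes the assessment on R
shuffles and compares homogeneous counts per type and overall.

**Significance calibration.** The per-type comparison reports the
conventional z-score and normal p, Bonferroni-corrected over the types that
occur in the population (a type with no member triads cannot be tested).
The normal tail, however, is badly anti-conservative when homogeneous
counts are rare: a count of 1 against a Bernoulli(≈0.05) null yields z ≈ 4.
The p used for the significance flag is therefore floored by the one-sided
permutation estimate (1 + #{null ≥ real})/(R + 1), which is exact at the
resolution R affords; a zero-variance null is flagged degenerate and
reported as that bound. Extremely large z-scores should be read as bounds,
not as literal normal tail masses.

`synapseCoverage()` sums the weights of all edges incident to at least one
homogeneous set (the X–Y dyad and every member's X–Z, Y–Z dyads, both
channels) over the total edge weight. `bilateralRatio()` classifies a pair
as bilateral only when the names differ in a terminal L/R, the conservative
naming convention for left/right anatomical partners.

# Layer localization

Layers are curated inputs (a two-column table), never inferred from
topology; neurons missing from the table are `unknown` and are excluded
from layer statistics but counted in reports. For set types with a directed
X–Y link the layer pair is ordered (X is the source); for bidirectional or
unconnected pairs it is unordered, matching the triad canonicalization.

`layerEnrichment()` tests every (set type, layer pair) cell by the same
hypergeometric tail, with population = homogeneous sets with known layers
(an "all sets" background is available as a sensitivity option — the
appropriate background is genuinely ambiguous, so both are implemented),
Bonferroni over all cells tested, threshold 0.005 by default.
`xySynapseComposition()` counts chemical and gap channels on the X–Y dyads
of bidirectional homogeneous sets; a dyad carrying both channels counts in
both tallies.

# Circuit dynamics

Graded-potential units (the worm's neurons are largely non-spiking) with
saturating chemical drive and diffusive electrical coupling:

$$\frac{dA_i}{dt} \;=\; \sum_{\text{chem in}} \mathrm{sign}\,\beta\,
\frac{A_{\text{pre}}}{K + A_{\text{pre}}} \;+\; \sum_{\text{gap}} g\,(A_j - A_i)
\;+\; s_i(t) \;-\; \alpha A_i .$$

Parameters (all rates per unit time, activities dimensionless): decay
α = 1, maximal synaptic rate β = 1, half-saturation K = 1, gap coupling
g = 1; stimuli are rectangular pulses of amplitude 1 and duration 1. The
mutually-regulating circuit receives a single brief pulse to X; the
mutually-regulated circuit receives staggered pulses to Z₁ and Z₂ (offset =
half a pulse width) emulating unsynchronized upstream drive, with an
asymmetry option β(Z₁→X) = 2·β(Z₁→Y), K(Z₁→X) = 10·K(Z₁→Y) to impose
upstream variability. The stimulus enters additively, not through a
saturating term — the simplest reading consistent with a graded external
drive; because such reconstruction choices are not uniquely determined,
every conclusion the package tests about these circuits is **directional**
(connected vs unconnected twin, monotonicity in g), never a specific
numeric trajectory value.

Integration is fixed-step fourth-order Runge–Kutta from the all-zero state;
fixed stepping keeps trajectories exactly reproducible. Rectangular pulse
edges limit local accuracy to O(dt) at the onset, so the step-halving check
in the suite uses a 5·10⁻³ tolerance at dt = 0.02 and additionally asserts
that the error shrinks under refinement. A negative-feedback variant
(sign = −1 links) is exposed and smoke-tested only.

Metrics: `amplificationMetrics()` returns the trajectory peak and the time
spent above a threshold (grid measure); `coordinationMetric()` returns
max |A_X − A_Y|, small values meaning evenly coordinated activation.

# The synthetic-data generator

`generatePlanted()` emulates the features the analysis relies on: layer
labels, uniform soma positions with bilateral L/R partners sharing a
position, planted homogeneous sets wired exactly (all member dyads of the
requested type), and an Erdős–Rényi chemical background overlay that never
displaces a planted edge. The bidirectional X–Y channel rule mirrors the
empirical composition of the circuit families: types #13 and #15 are
gap-coupled, all others chemically coupled. Planted sets draw disjoint node
pools, which keeps the ground truth exact at the cost of slightly
under-dispersed overlap relative to real connectomes. `generateClustered()`
provides a tunable CNR (latent groups with high within-group density);
`generatePreferential()` provides heavy-tailed degrees. What the generator
does **not** emulate: the real degree sequence, weight distribution,
spatial wiring economy, or overlapping set membership of a genuine
connectome — degree-matched conclusions always come from the randomization
module, not from the generator, and a passing synthetic test shows the
machinery is correct, not that real data will show the same effects.

Default study conditions used by the test suite and `scripts/acceptance.R`:
120 neurons (30/40/20/30 across the four layers), planted sets of 5–8
common neighbors in 2–3 copies per type, background edge probability
0.02–0.025, 100-network null ensembles, 100–200 set shuffles, ER null
behavior checked on 300-node graphs at p = 0.05 over 100 seeds, and
dynamics on a 0.01 time step to t = 30. These sizes were chosen as the
smallest at which the planted effects are unambiguous.

# Determinism and degenerate inputs

Every stochastic operation takes an explicit seed, derives sub-seeds
deterministically, and restores the caller's RNG state. Identical seeds
give byte-identical edge lists and reports. Degenerate inputs are handled
explicitly: zero-variance distance vectors (flagged, p = 1), infeasible CNR
fits (flagged), single-edge graphs (returned unchanged by the shuffler,
with a swap count of 0), empty backgrounds, and gap-free connectomes (the
chemical-only reanalysis is then bit-identical to the standard pipeline).

# Known limitations

* Gap junctions are assumed bidirectional and chemical synapse signs
  (excitatory/inhibitory) are unknown; both are constraints of the data
  model, and the dynamics module's sign parameter is a modeling device.
* The t-based p of the distance correlations is anti-conservative under
  dyadic dependence (see above).
* The enrichment z-test's normal p is only trustworthy where counts are
  large; the permutation floor bounds, but cannot sharpen, small-sample
  significance beyond 1/(R+1).
* The taxonomy is the role-preserving X/Y/Z scheme; it is not the
  Holland–Leinhardt 16-class census, and no general graph-wide motif
  census is attempted.
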