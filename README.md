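# cnrsets

Connectome analysis around the **common-neighbor rule (CNR)** and the
**homogeneous common-neighbor sets** it gives rise to. The package is aimed
at systems neuroscientists and network biologists who have a wiring diagram
— directed chemical synapses plus symmetric electrical gap junctions, as in
the *C. elegans* hermaphrodite connectome — and want to ask:

1. Is a pair of neurons more likely to be connected the more common
   neighbors it shares, beyond what degree structure alone explains?
2. Do the common-neighbor sets (a pair {X, Y} plus all of its shared
   neighbors Z₁…Zₙ) have a *homogeneous* internal structure, dominated by a
   single triad type?
3. Where do those homogeneous circuits sit in the sensory → inter →
   pre-motor → motor layer hierarchy, and what could they do functionally?

## The statistics at the core

**CNR curve.** Every unordered pair is binned by its number of common
neighbors *c* (a neighbor is any neuron linked by a chemical synapse in
either direction or a gap junction). Within each bin the fraction of
connected pairs is computed, and a least-squares line is fitted across bins
with at least 5 pairs. The observed slope is compared to two null
ensembles — degree-preserving edge swaps (chemical in/out-degree and gap
degree conserved exactly per neuron) and density-matched Erdős–Rényi
graphs — by z-score: z = (slope_real − mean(slope_null)) / sd(slope_null).

**Triad taxonomy.** Each member Z of a set forms a triad with the pair
(X, Y). Keeping the X/Y/Z role identities, there are exactly **21 triad
types**: 9 with a unidirectional X→Y link, 6 with a bidirectional X–Y link,
and 6 with X and Y unconnected. Named anchors include the multi-output,
multi-inter and multi-input feed-forward loops (#1, #2, #5), the
**mutually regulating** type #10 (X↔Y, both presynaptic to Z), the
**mutually regulated** type #13 (X↔Y, both postsynaptic to Z) and the fully
bidirectional #15.

**Homogeneity.** For a set of size *n* whose dominant type occurs *k*
times, with that type occurring *K* times among the *N* member triads of
all sets in the population, the score is the upper-tail hypergeometric
probability

P(H ≥ k), H ~ Hypergeometric(N, K, n),

and a set is *homogeneous* when P ≤ 0.05 **and** k/n ≥ ½. Per-type
enrichment is assessed against nulls built by permuting all member-triad
labels across sets (sizes and global type counts conserved exactly).

**Circuit dynamics.** Graded-potential (non-spiking) units with
Michaelis–Menten chemical drive and diffusive gap coupling:

dAᵢ/dt = Σ<sub>chem in</sub> sign·β·A_pre/(K + A_pre) + Σ<sub>gap</sub> g·(Aⱼ − Aᵢ) + sᵢ(t) − α·Aᵢ

with α = β = K = 1 defaults, used to compare connected vs unconnected
mutually-regulating (#10) and mutually-regulated (#13) circuits.

## Worked example

Generate a synthetic connectome with planted homogeneous sets — three
mutually-regulating sets in the sensory layer and three gap-coupled
mutually-regulated sets in the motor layer — and run the analysis:

```r
library(cnrsets)

g <- generatePlanted(
    nPerLayer = c(sensory = 30, inter = 40, premotor = 20, motor = 30),
    planted = list(
        plantedSetSpec(10, nZ = 6, xLayer = "sensory", zLayer = "inter", count = 3),
        plantedSetSpec(13, nZ = 6, xLayer = "motor", zLayer = "premotor", count = 3)),
    pBackground = 0.02, seed = 42)
con <- g$connectome
con
#> Connectome: 120 neurons, 377 chemical edges, 3 gap junctions
#>   layers: sensory=30, inter=40, premotor=20, motor=30
#>   soma positions for 120 neurons

cnrCurve(con)
#> CNRCurve: 7 bins (6 used in fit)
#>   fit: slope 0.1388, intercept -0.1331, R^2 0.641

ensembleSlopeTest(con, "degree_preserving", nNetworks = 100, seed = 1)
#> EnsembleResult [degree_preserving, 100 networks]: real slope 0.1388,
#>   null 0.007231 +/- 0.01904, z = 6.91, p = 4.73e-12

sets <- extractSets(con, minNeighbors = 5)
enr <- enrichmentTests(sets, R = 200, seed = 2)
enr
#> NullComparison (R = 200 shuffles): 6 homogeneous sets vs null 0.17 +/- 0.41
#>   (z = 14.06, p = 0.00498)
#>   enriched types: #10, #13

xySynapseComposition(con, enr$results)
#>   set_type n_sets n_chemical n_gap
#> 1       10      3          3     0
#> 2       13      3          0     3

layerPairHistogram(con, enr$results)$pairs
#>   set_type      layer_pair count
#> 1       10 sensory:sensory     3
#> 2       13     motor:motor     3
```

Reading the output: the planted network's CNR slope (0.139) is almost 7
null standard deviations above degree-preserving expectation; all six
planted sets are recovered as homogeneous against a shuffled-set null of
0.17 ± 0.41; the mutually-regulating pairs are chemically coupled in the
sensory layer while the mutually-regulated pairs are gap-coupled in the
motor layer — exactly the planted ground truth.

Real data enter through `readEdgeList()` (generic CSV, adjacency-matrix,
or the wormatlas "neuronal wiring" spreadsheet layout), plus
`readLayerTable()` / `readPositionTable()`; `runPipeline()` drives all
stages from one config and writes JSON/CSV reports.

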