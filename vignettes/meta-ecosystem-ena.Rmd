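---
title: "From landscape flux budgets to meta-ecosystem network indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From landscape flux budgets to meta-ecosystem network indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaflux)
```

## The problem

A landscape is a set of ecosystems exchanging matter laterally (runoff,
litter subsidies) and vertically (gas exchange with the atmosphere). Two
analytical traditions meet here awkwardly. Landscape-system analysis treats
the region as open and asks which spatial features matter for modelling.
Meta-ecosystem theory assumes a (quasi-)closed, mass-conserving set of
interconnected ecosystems and derives whole-system ("holistic") properties
from the flow network, using the information-theoretic indices of Ecological
Network Analysis (ENA; Ulanowicz 1986, 2004). `metaflux` operationalizes the
bridge: a flux budget goes in, a closed flow network and its indices come
out, with every transformation explicit and configurable.

The worked example throughout is the carbon budget of the Northern Highlands
Lake District (NHLD) of Wisconsin and Michigan — forests, wetlands and
surface waters — assembled from the regional estimates of Buffam and others
(2011) and shipped in `inst/extdata/`.

## The procedure

### Step 1: the flux network

A `flux_network` is a validated directed multigraph: compartments (internal
ecosystems, exterior pools, storage) and flow records (process label,
orientation, best/low/high magnitudes in Gg C yr⁻¹). Validation enforces the
data model rather than trusting it: unique ids, declared endpoints, one
record per (source, target, process), finite magnitudes, ordered ranges,
self-flows only for the storage processes (accumulation, sedimentation), and
negative magnitudes only for accumulation — a pool may draw down.

Two per-compartment primitives drive everything downstream.
`compartment_throughput()` sums the magnitudes of all flows touching a
compartment; self-flows are excluded by default because a storage term is not
exchange with a neighbour (including them would let a large internal storage
mask a weak coupling). `net_balance()` is inflow minus outflow — the
empirical analogue of a local growth rate in the absence of spatial flows.

A bookkeeping subtlety in the NHLD budget: the published forest accumulation
(968) equals the forest balance *without* carbon precipitation (968.7), while
the full balance is 974.9. The budget's internal convention is not stated, so
neither number is canonicalized: `net_balance()` always returns the full
balance, and the fixture stores the published 968 as the accumulation flow,
exactly as printed.

### Step 2: significance and classification

A boundary-crossing flux is treated as negligible when it is two orders of
magnitude smaller than the activity of the ecosystems it touches. The rule
implemented in `flag_significance()`: a flow is **significant iff its
magnitude is at least `ratio` (default 0.01) times the throughput of at least
one internal ecosystem it touches**. The at-least-one-endpoint form is a
genuine design choice — donor-only, recipient-only and both-endpoints rules
are all defensible a priori — and was chosen because it is the only simple
rule consistent with all the NHLD verdicts: forest DIC runoff (10 Gg) is far
below 1% of the forest throughput (5503.5) yet clearly matters to surface
waters (throughput 113.7), and is retained; wetland DIC runoff (1.0) clears
neither endpoint and is dropped.

Three further conventions avoid order-dependence and edge-case surprises:
thresholds are computed once on the *unfiltered* network, so flagging is
idempotent; ties (flux exactly at threshold) count as significant,
conservatively retaining flows; self-flows are always significant (a storage
term cannot be insignificant relative to its own compartment). A network
whose internal ecosystems have zero throughput gets every non-self flow
flagged insignificant, with a warning.

`classify_landscape_system()` then reads the flagged network: internal
ecosystems significantly interconnected and significant flows crossing the
boundary → *fragmental*; interconnected with nothing crossing → *systemic*;
not interconnected but two or more ecosystems retain significant vertical
flows (coupled through the overlying medium) → *laterally discrete*;
otherwise *omnidirectionally discrete*. The NHLD, with GPP/respiration
crossing vertically, runoff leaving laterally and DOC connecting ecosystems
internally, is fragmental.

### Step 3: adjustment to a closed meta-ecosystem

`to_meta_ecosystem()` closes a fragmental system by simplification: every
boundary-crossing flow is re-pointed at an exterior compartment chosen by
orientation (defaults: vertical → `atmosphere`, lateral → `downstream`),
insignificant flows are dropped, and storage terms become self-loops.
Exterior compartments are inexhaustible: no stock, no balance requirement.
Automatic boundary *expansion* (swallowing neighbouring ecosystems until the
system closes) is deliberately out of scope; only the exterior-compartment
simplification is provided.

Storage is represented as a self-loop on the compartment itself rather than
as a separate storage node. The alternative (explicit storage compartments)
roughly doubles the apparent constraint of the network — every accumulation
becomes a fully determined pathway — and pushes AMI far above what the
aggregate budget supports; the self-loop form keeps storage inside the
compartment's own marginals.

A negative accumulation (the NHLD surface waters store −15: a net release)
needs a sign policy, `negative_accumulation`:

* `release_inflow` (default): the release re-enters the compartment as a
  positive self-loop of the same magnitude — carbon mobilized from storage is
  real activity;
* `signed_self_loop`: kept as printed; downstream index code uses absolute
  magnitudes;
* `exclude`: omitted entirely.

All three are retained because budget tables differ in convention; the
choice moves the NHLD TST by 15 Gg C yr⁻¹ (0.2%).

`source_sink_residual()` reports how far the adjusted system is from the
closed-system constraint that local net balances sum to zero. For an
empirical budget it is non-zero — the NHLD stores carbon — and equals the sum
of internal balances over the adjusted flow list (1056.3 Gg C yr⁻¹ for the
defaults).

### Step 4: the ENA indices

With `T_ij` the pair-aggregated flow matrix (parallel processes summed,
absolute magnitudes), `T` the total, `T_i.` row (outflow) and `T._j` column
(inflow) marginals:

* `TST = T` — size/activity;
* `AMI = k Σ (T_ij/T) log₂(T_ij T / (T_i. T._j))` — organization, in bits
  (defaults `k = 1`, base 2);
* `A = Σ T_ij log₂(T_ij T / (T_i. T._j)) = TST × AMI` — ascendency;
* `C = −Σ T_ij log₂(T_ij/T)` — development capacity, the flow diversity
  scaled by TST;
* `R = C − A ≥ 0` — redundancy, read as resilience.

Numerical conventions: `0·log 0 = 0` (zero flows are skipped); capacity is
implemented with the conventional negative sign so that `C ≥ A ≥ 0` and
`A + R = C` hold on every network — the sign is occasionally dropped in the
applied literature, but only the negative-signed form is an upper bound on
ascendency. Self-loops are included in TST and in the marginals by default
(`include_self_loops = FALSE` removes them everywhere consistently). Base-2
logarithms and `k = 1` are defaults, not constants, but all reported
identities are checked in base 2.

Two closed forms anchor the implementation and the tests: a unidirectional
ring of `n` equal flows is maximally constrained (`AMI = log₂ n`, `R = 0`),
and the uniform complete network with self-loops is maximally free
(`AMI = 0`, `R = C`). The production matrix path is additionally checked,
flow for flow, against a brute-force double-loop evaluation of the defining
sums written independently in the test helpers.

## Spatial budget models

A separate question from the network indices: how much spatial structure does
a *model* of the region need? `select_spatial_model()` encodes the standard
decision tree (Lovett and others 2005): no lateral fluxes, no variable
drivers, no nonlinearity → *homogeneous* (mean intensities suffice);
variable drivers or nonlinearity → *mosaic* (model each ecosystem, sum);
significant lateral fluxes → *interactive* (composition and configuration).
The NHLD, with significant DOC runoff, is interactive.

The budgets themselves are linear intensity models, in g converted to Gg
(1 Gg = 10⁹ g): areal terms are intensity (g C m⁻² yr⁻¹) × area (m²);
shoreline subsidies are lineal intensity (g C m⁻¹ yr⁻¹) × interface length
(km, converted to m). The vertical (mosaic) budget closes by construction
through the atmosphere term `F_a,v = −(F_f,v + F_w,v + F_s,v)`; the lateral
(interactive) budget closes through the downstream export,
`F_f,l + F_w,l + F_s,l + F_d,l = 0`. Both identities are asserted exactly in
the tests. An asymmetry of the NHLD source budget is mirrored, not repaired:
surface waters carry gas-evasion intensities rather than separate GPP and
respiration, so their vertical budget is precipitation minus evasion.

Compartment areas are not published directly; they are back-derived from
(total flux)/(local intensity) pairs of the same budget: forest and wetland
from their GPP pairs (3233/936 and 878/490 → 3.454×10⁹ and 1.792×10⁹ m²),
surface waters from the sediment pair (17/20 → 0.85×10⁹ m²), the only
surface-water pair whose two cells are mutually consistent to the printed
precision. The derivations are recorded in the fixture header.

## Scenarios

`apply_scenario()` substitutes explicit replacement magnitudes for named
(source, target, process) records — never mutating the base network — and
`compare_scenarios()` tabulates ENA reports with per-index deltas. Scenario
inputs are explicit maps rather than automatic range sampling: mechanically
substituting all upper-range bounds produces *a* valid network, but published
"active"/"inactive" scenario analyses of this budget are built from curated
flux sets whose construction rules are not recoverable, so the package
provides the mechanism and leaves the flux sets to the user (plain-text
format: one `source,target,process,value` line each).

## The synthetic generator

`generate_network()` emulates the *shape* of the problem for property
testing: `n` compartments, directed edges with probability `connectance`,
log-normal magnitudes (heavy right tail, like real budgets where GPP dwarfs
litter), a ring backbone guaranteeing strong connectivity, and optional exact
per-compartment balance obtained by iterated proportional rescaling of each
compartment's outflows (matrix balancing; a single pass cannot balance a
general digraph, the iteration converges on strongly connected graphs —
tolerance 10⁻¹⁰ relative, cap 10⁴ sweeps). Defaults (`n = 5`,
`connectance = 0.5`, `meanlog = 0`, `sdlog = 1`) give small dense networks
like the adjusted NHLD (5 compartments, 13 aggregated arcs).

What it does *not* emulate: the NHLD's extreme magnitude spread (five orders
between GPP and wetland litter), process semantics, storage self-loops, or
the correlation structure of a real budget (vertical pairs roughly
balancing). Passing the property suite therefore certifies the index
algebra — identities, bounds, equivariances, oracle agreement — on arbitrary
strongly connected weighted digraphs, not the fidelity of any particular
empirical encoding; that fidelity is tested separately against the NHLD
fixture.

## Problem sizes used in the checks

The test suite exercises ~100 generated networks of 2–8 compartments for the
oracle/bounds properties, 40 round-trip seeds for I/O, and closed forms for
`n = 2..8`; `scripts/acceptance.R` runs the full NHLD pipeline (21 flow
records). These sizes already cover every code path; the indices are O(n²)
and run comfortably at hundreds of compartments.

## Known limitations

* The adjusted network's exact composition is convention-dependent:
  insignificant-flow handling, the negative-accumulation policy and self-loop
  treatment each move TST by a few tenths of a percent and AMI by ~1%.
  Published index values for the same budget can therefore differ from any
  single configuration at that level; the configuration switches expose every
  composition this package considers defensible.
* Exterior compartments are sinks/sources without balance constraints;
  nothing forces the closed system to conserve mass exactly (see
  `source_sink_residual()`).
* Only the five holistic indices are computed — no input/output environ
  analysis, cycling (Finn) index, or trophic aggregation.
* Compartments are aspatial: scalar areas and interface lengths, no geometry.
* Unit handling covers g ↔ Gg carbon-per-year tables; anything else is
  rejected rather than guessed.

## References

Buffam I. and others (2011). Integrating aquatic and terrestrial components
to construct a complete carbon budget for a north temperate lake district.
*Global Change Biology* 17:1193–1211.

Lovett G.M., Jones C.G., Turner M.G., Weathers K.C., eds (2005). *Ecosystem
Function in Heterogeneous Landscapes*. Springer.

Ulanowicz R.E. (1986). *Growth and Development: Ecosystems Phenomenology*.
Springer.

Ulanowicz R.E. (2004). Quantitative methods for ecological network analysis.
*Computational Biology and Chemistry* 28:321–339.
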