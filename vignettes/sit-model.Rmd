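---
title: "The segregation-to-integration transformation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The segregation-to-integration transformation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

sitnet simulates how a memory, represented as a modular neural-ensemble
network, evolves under repeated reactivation. This vignette documents the
model the package implements, the choices that were genuinely open when
writing it, and what the simulations do and do not show.

## The model

A memory network is a simple, undirected, unweighted graph on `N` nodes
with a fixed partition into `C` communities and a binary activation state
per node. Each community stands for the neural ensemble of one encoded
episode; edges are functional couplings; the partition never changes, only
the edge set does.

**Initial state.** `build_segregated_network(N, C, Z0)` draws each
community as an independent random `k_int`-regular graph on `N/C` nodes
(default `k_int = (N/C)/2`) and then places
`L_ext = round(Z0 * L_int / (1 - Z0))` inter-community edges uniformly at
random over distinct-community pairs (at least one whenever `Z0 > 0`).
Regularity guarantees no node or community is isolated and all play
symmetric roles. The *degree of integration*

$$Z = \frac{L_{\mathrm{ext}}}{L},$$

the fraction of edges that cross community boundaries (each edge counted
once), is then approximately `Z0`. `Z ~ 0` is a fully segregated
(modular) memory; `Z ~ 1` a fully integrated one. The seven standard
sizes `N = 16 ... 1024` with `C = 4` use designated starting values
`Z0 = 0.3, 0.09, 0.02, 0.01, 0.001, 0.0004, 0.0001`, which the builder
reproduces at their stated precision.

**Reactivation.** One reactivation event is the composition of three
stages, run by `reactivate()`:

1. *Turn-on* (stochastic). For each cued community a fraction is drawn
   from `Normal(Int, 0.05)`, clipped to `[0, 1]`, and converted to a node
   count by nearest-integer rounding. The intensity `Int` models the
   overlap between the external cue and the stored memory. Node selection
   draws that many uniform picks over the community and keeps the
   distinct ones (see *Design choices*).
2. *Spreading* (deterministic). Synchronous linear-threshold diffusion:
   an inactive node with degree $k_n$ activates exactly when its active
   neighbours number strictly more than $\theta k_n$; active nodes stay
   active. Iteration stops at the first fixed point, or after 50 updates
   (a cap that, in every configuration exercised by the test suite, is
   never the stopping reason). The excitability threshold $\theta$ is a
   proxy for neuronal excitability: permissive (low) thresholds let
   activation escape its community.
3. *Plasticity* (deterministic). A Hebbian rewiring applied simultaneously
   to every unordered node pair: both endpoints active — connected
   afterwards; exactly one active — disconnected afterwards; both
   inactive — unchanged. Consequently the steady-state active set always
   ends up a clique with no edge to the inactive remainder, which the
   test suite asserts on every run. All states are then reset, so
   reactivations are independent events.

**Metrics.** After each reactivation the package records:

* `Z` — degree of integration, as above.
* `H` — random-walker network entropy,
  $H = \frac{1}{N \ln(N-1)} \sum_n \ln k_n$ (isolated nodes contribute
  0); `H = 1` exactly on the complete graph. High `H` means high
  uncertainty in where activation flows, i.e. an accessible memory.
* `deltaL` — malleability index,
  $\Delta L = (L^c + L^R)/L_{-1}$: created plus removed edges over the
  edge count before the event. Its *nonlinearity amplitude*
  `amp_deltaL = max(deltaL) - mean(last five)` quantifies the inverted-U
  malleability window; note the formula makes the amplitude non-negative
  by construction.
* `T` — community tightness: external incident edges over all edges
  incident to the community, so `T = 1/2` exactly when as many links
  leave the community as stay inside, and the decay slope is the OLS fit
  of the run-averaged `T` against the 1-based reactivation index over
  reactivations 3–9.

## Protocols and problem sizes

`run_transformation()` is the default protocol: 25 independent runs, each
a fresh `N = 128`, `C = 4`, `Z0 = 0.01` network receiving 10 reactivations
at `Int = 0.3`, `theta = 0.4`. `run_single_community()` cues only one
community for 15 reactivations and tracks its tightness.
`run_sweep()` executes grids over `Int` (canonically 0.1–0.7, step 0.02),
`theta` (0.1–0.6, step 0.02), `N` and `Z0`; a paired grid (one designated
`Z0` per `N`) can be passed explicitly. The shipped YAML files under
`inst/configs/` encode each standard protocol for the command-line
front end.

The test suite runs the default protocol at full size (25 runs of
`N = 128`), the threshold comparison at three thresholds, the intensity
scan on a step-0.04 grid, and the single-community protocol at four
initial integration levels — each of these completes in seconds because a
reactivation is a handful of dense matrix operations at `N = 128`. The
exhaustive spreading-engine cross-check enumerates every graph on up to 5
nodes under every initial state vector, plus all 64 state vectors on a
fixed-seed sample of 400 six-node graphs; full enumeration at six nodes
(32 768 graphs) adds nothing qualitatively and was scaled down to keep
the suite brisk.

## Seed discipline

Every stochastic element flows from one base seed: the protocol derives
per-run (and per-grid-point) seeds deterministically via R's RNG, each
run re-seeds before building its network and consuming turn-on
randomness, and runs are mutually independent — results are identical
whatever the execution order, which is what makes the parallelism
contract trivial and the builder bit-reproducible.

## Design choices

Several aspects of the model's usual presentation are ambiguous; the
package fixes them as follows.

* **Intra-community degree.** `k_int` defaults to half the community
  size. This is the reading under which "a tightness of one half means as
  many links inside as outside" is exact, and it reproduces all seven
  standard `(N, Z0)` pairs with small integer external-edge counts.
  `k_int` is exposed as an override.
* **Cross-edge counting in `Z`.** A literal double sum over communities
  would count every cross edge twice and put `Z` in `[0, 2]`; each edge
  is counted once so that `Z` spans `[0, 1]` as its interpretation
  requires.
* **Turn-on selection.** The count `round(f * N/C)` is realised by that
  many uniform draws over the community with the distinct picks kept, so
  collisions can make the activated set slightly smaller than the
  nominal count. This matches the natural implementation of "a uniform
  random number generator selecting values between 1 and N/C" and it is
  the reading under which the default protocol shows its documented
  entropy peak at the second reactivation; exact distinct sampling is
  available as `turn_on_select = "distinct"`. The drawn fraction is
  clipped to `[0, 1]` before rounding (out-of-range Normal draws are not
  re-drawn).
* **Strict threshold.** Spreading uses the strict inequality
  $\theta k_n < \sum_{j} S_j$; a hub with exactly $\theta k_n$ active
  neighbours stays inactive. Degree-0 nodes never self-activate (an
  empty neighbour sum is 0 and $\theta \cdot 0 < 0$ is false).
* **Synchronous updates.** All nodes are evaluated against the previous
  step's states, the standard convention for deterministic
  linear-threshold diffusion; because activation is monotone and
  permanent, the fixed point would be the same under asynchronous
  sweeps.
* **Network-wide plasticity.** The rewiring rule has no locality
  restriction: co-active nodes in different communities become linked.
  This is what drives integration, and it concentrates a large share of
  total rewiring into the first reactivation at moderate-to-high
  intensities: with four communities cued at `Int = 0.3` the first
  co-activation alone creates hundreds of cross edges on a 1034-edge
  substrate, so the run-averaged malleability trajectory peaks at the
  first reactivation and then relaxes, rather than rising to a
  mid-trajectory maximum. A mid-trajectory malleability peak appears in
  this implementation only at substantially lower effective intensities
  (around `Int ≈ 0.14`), where integration is still ongoing at
  reactivations 4–5.
* **State reset.** States are cleared after plasticity; turn-on is
  defined on inactive nodes and reactivation events are treated as
  independent.
* **Fresh networks per run.** Ensemble runs resample the initial network
  as well as the turn-on randomness; `resample_network = FALSE` fixes
  one substrate across runs when only cue variability is of interest.

## Limitations

The simulator works on unweighted, undirected, single-layer graphs with a
fixed, given partition — there is no community detection, no synaptic
weight plasticity, no forgetting (nodes never deactivate within an event,
and edges between inactive pairs are never touched), and no dependence of
parameters on brain state. The generated substrates are statistically
homogeneous (equal community sizes, regular internal degree); real
engram ensembles are neither, so passing tests demonstrate properties of
the model, not of biological memory.
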