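---
title: "Modeling signal propagation in engineered bacterial consortia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling signal propagation in engineered bacterial consortia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

consortnet simulates molecular communication in engineered *E. coli*
consortia as a stochastic process on a dynamic graph.  Each node is a cell
carrying four nonnegative weights — substrate $s_i(t)$, hydrogen peroxide
$H_i(t)$ (µM), autoinducer-1 $A_i(t)$ and GFP $G_i(t)$ — and each undirected,
unweighted edge is a transient communication channel along which the two
diffusible inducers (hydrogen peroxide and AI-1) move.  GFP and substrate
never leave a cell.  Time is discrete; one simulated timestep applies, in
order:

1. **Gene activation and production.**  A Bernoulli draw per cell gates
   production for this step.
2. **Electrode source** (electrical induction only): peroxide deposition
   and electrode-link reset.
3. **Signal diffusion** of hydrogen peroxide, then AI-1, across edges.
4. **Growth**: substrate-gated stochastic division with edge inheritance.
5. **Edge rewiring** according to the culture's mixing mode.

Two cellular systems are built in.  In the *Monoculture*, every cell senses
peroxide through an OxyR-type circuit and accumulates GFP.  In the
*Transmitter/Receiver* consortium, 10% of cells (transmitters) carry that
same circuit but synthesize the quorum-sensing signal AI-1 (and GFP), while
the remaining 90% (receivers) respond to AI-1 — at nanomolar potency — by
making GFP.  The second stage amplifies a weak peroxide input into strong
population-level expression.

## Activation and production kinetics

Peroxide-driven activation is a logistic in the local concentration,

$$P_{H}(h) = \frac{1}{1 + e^{-(h - 8)/2}}, \qquad P_H(0) = 0,$$

so activation becomes likely above roughly 8–12 µM.  AI-1-driven activation
uses a far steeper logistic, $P_A(a) = (1 + e^{-50(a - 0.25)})^{-1}$ with
$P_A(0)=0$, an almost step-like switch reflecting quorum-sensing
sensitivity.  When a peroxide-sensing cell activates it produces

$$R_H(h, s) = \frac{2s}{1 + e^{-h}}$$

units of product (GFP for Monoculture receivers; AI-1, plus GFP, for
transmitters): steeply peroxide-dependent at low concentration, saturating
at $2s$.  Activated AI-1 receivers produce $R_A(a, s) = 0.2\,a\,s$, linear
in both signal and substrate.  All rates are evaluated on the state at step
entry, so production always uses the previous step's concentrations.  A
`deterministic_expectation` switch replaces the Bernoulli gate by its
expectation ($P \cdot R$ added deterministically) for mean-field comparison
runs.  All constants are exposed through `kinetic_params()`.

## Diffusion and the outflux limiter

Both inducers follow synchronous discrete graph diffusion

$$c_i(t+1) = c_i(t) + \alpha\,\Delta t \Big( \sum_{j \in N_i} c_j(t) -
c_i(t)\,\deg(i) \Big),$$

i.e. a pairwise flux $\alpha \Delta t\,(c_j - c_i)$ on every edge.  With the
default $\alpha = \Delta t = 1$ this explicit scheme violates its stability
bound whenever a node's degree exceeds 1: a node can be asked to export more
mass than it holds, which drives concentrations negative (and, if negatives
are merely clamped, silently creates mass — a 46 µM electrode with five
links would inject roughly five-fold its nominal output per step).  The
package therefore defaults to a *mass-conserving outflux limiter*: each
node's outgoing fluxes are scaled, if necessary, so it never exports more
than it holds.  Wherever no node overdraws, the limiter is exactly the raw
update (the unit tests verify equality against the graph-Laplacian matrix
form); total mass is conserved to machine precision in every case, and
concentrations stay nonnegative.  The raw update (`"none"`) and a clamp
with an audited mass deficit (`"clamp"`) remain available for comparison.

A consequence worth knowing: at $\alpha \Delta t = 1$, two nodes joined by a
single edge *swap* their concentrations in one step, and generally one
shared edge equilibrates a pair completely.  Per-step transport is
therefore very fast relative to the other timescales; see *Limitations*.

## Growth and division

Each cell whose substrate strictly exceeds `k = 1` divides with probability
`p_div = 0.015` per step.  Substrate, peroxide and AI-1 are halved between
parent and daughter; GFP is copied to both (fluorescence is inherited and
protein degradation is neglected); role and mobility are inherited.
Substrate is consumed by division only, so a founder starting at
`s0 = 20` supports at most five generations and a network of $n_0$ founders
can never exceed `max_network_size(n0, 20, 1)` $= 32\,n_0$ nodes — 1600
for 50 founders, 3200 for the default 100.  Divisions are decided for all
cells first; each divided pair then inherits edges from the parent's
pre-division neighborhood, augmented by that neighborhood's same-step
daughters and capped at 10 sampled neighbors per daughter, plus the shared
parent–daughter edge.  Both daughters remain eligible to divide again (the
division bookkeeping keeps the parent id as one daughter purely for stable
identifiers; the dynamics are symmetric).

## Edge dynamics and topology variants

Mixing is modeled entirely through the edge set:

* `randomized` — a stirred batch culture: every step, the current number of
  cell–cell edges is resampled uniformly over all cell pairs.
* `static` — a biofilm or otherwise immobilized culture: edges persist and
  change only through division.
* `partial` — only edges between two *immobile* nodes persist; all others
  are resampled with at least one mobile endpoint.  Used for transmitters
  fixed to an electrode with receivers free in suspension.  (An optional
  flag instead keeps the immobile endpoint of a mixed edge and resamples
  only the mobile side.)

The edge count is preserved under rewiring in every mode so stirred and
static cultures stay comparable.  Statically grown networks accumulate
family-cluster structure and score high Louvain modularity (~0.7–0.8 at
180 steps), while per-step randomization keeps modularity low (~0.2) —
this structural contrast is robustly reproduced by the test suite.

## Induction modes and the electrode

Chemical induction adds a uniform peroxide dose (0–100 µM) to every cell at
$t = 0$.  Electrical (electrogenetic) induction instead attaches a single
electrode node that deposits 46 µM peroxide per step while charged (a value
fitted for a 100-cell network and deliberately not rescaled with size), for
`charge_duration` steps.  At most 5% of cells are wired to the electrode at
any time: resampled each step in stirred scenarios, persistent (and merely
topped up as the population grows) in static ones, and restricted to the
transmitter pool when transmitters are fixed to the electrode surface.
Division is suspended while the electrode is on — cultures show negligible
growth during induction — and resumes at `growth_resume_step` (default:
charge end).  With the limiter, the peroxide entering the network equals
`charge_duration × 46` exactly, so a 12-step charge yields a network
average near $12 \times 46 / 100 \approx 5.5$ µM on a 100-cell network.

## Metrics

Endpoints are summarized per step and pooled across replicates: node count,
median GFP, percent active (GFP strictly above 1000), per-species means and
SDs, and Louvain modularity of the cell–cell graph (best of 10 random
restarts; electrode excluded by default).  `fold_change()` compares matched
stirred/static conditions by the ratio of pooled mean GFP.

## Scenario presets, replicates and reproducibility

`scenario_config()` expands six presets (`monoculture_chemical`,
`tr_chemical`, `monoculture_electrical`, `tr_electrical`,
`tr_fixed_transmitters`, `tr_fully_static`); the same presets ship as YAML
files under `inst/extdata/presets/` for `load_config()` and the
command-line script in `inst/cli/`.  Chemical runs simulate 180 steps after
dosing; electrical runs simulate `charge_duration + 180` steps so all
endpoint comparisons happen 180 steps post-induction.  A run consumes a
single seeded random stream, making trajectories bit-reproducible;
`run_replicates()` executes independent seeds and pools node-level
endpoints, mirroring aggregate-of-10-replicate analyses.

```{r example, eval = FALSE}
library(consortnet)
reps <- run_scenario("tr_chemical", seeds = 1:10, dose = 100)
median_gfp(reps)        # pooled endpoint median over ~10^4 nodes
percent_active(reps)    # fraction of cells above 1000 GFP
```

## What the generator emulates — and what it does not

The simulator is itself the data generator: all validation inputs are
simulated networks under the parameter set above (100 founders, mean degree
4, `s0 = 20`, `k = 1`, `p_div = 0.015`, `alpha = 1`, 10% transmitters,
doses 0–100 µM, charges 0–30 steps, 10 replicates).  It reproduces
log-phase population growth to a substrate-limited plateau, dose-dependent
activation with T/R amplification (~5-fold higher pooled median GFP than
the Monoculture at 100 µM), electrode mass budgets, and the
static-vs-stirred modularity contrast.  It does not model continuous
space, protein degradation and dilution of intracellular GFP, Monod-type
growth kinetics, peroxide scavenging, or electrochemistry beyond a
constant per-step source term; passing tests therefore say nothing about
those aspects of real cultures.

## Numerical and design choices

* Initial GFP is Gaussian (mean 500, SD 250) truncated at zero via
  inverse-CDF sampling — fluorescence cannot be negative, and the
  truncation shifts the mean by under 3%.
* G(n, m) initialization samples exactly `round(n × mean_degree / 2)`
  distinct non-loop pairs by decoding uniform draws over the pair index;
  disconnected components are permitted.
* Division uses a strict `substrate > k` gate; ties never divide.
* Percent-active uses a strict `> 1000` comparison; ties count as inactive.
* Louvain is order-dependent, so modularity reports the best of 10
  random-permutation restarts under the caller's seed.
* The electrode is excluded from all biological metrics and from division
  and edge-inheritance bookkeeping.

## Limitations

The dominant caveat is the transport rate.  At the default
$\alpha\,\Delta t = 1$, one shared edge fully equilibrates (or swaps) a
node pair per step, so any connected topology — even a static,
biofilm-like graph — delivers a point source's signal across the whole
network within a few steps.  Output metrics consequently differ only
weakly between stirred and static edge dynamics, and between chemical and
electrical induction at matched average peroxide, even though the
*structural* contrast (modularity) is large.  Spatial attenuation of a
point source — much lower static-culture output, electrode-proximal
AI-1 hot spots — emerges only when per-edge transport is slow relative to
production and growth ($\alpha\,\Delta t \ll 1$); users who want to study
such effects should lower `alpha` deliberately rather than rely on the
default parameterization.  The acceptance suite keeps the default and
reports the corresponding contrasts as measured.

## Problem sizes used by the tests

Unit tests run on networks of 1–100 nodes and oracle graphs of at most 20
nodes (brute-force modularity: 8).  The endpoint-reproduction suite and
`scripts/acceptance.R` run the full study conditions — 100 founders, 180
steps post-induction, up to 210 total steps, 10 replicates per condition,
dose and charge sweeps of six conditions each — roughly 250 simulations in
a few minutes on one core.
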