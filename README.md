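# consortnet

Discrete-time, graph-based stochastic simulation of molecular signal
propagation in engineered bacterial consortia.

Synthetic consortia split work between strains that talk to each other
with diffusible molecules, and "electrogenetic" interfaces let an
electrode drive those conversations by generating hydrogen peroxide
electrochemically.  Understanding how far and how fast such signals
propagate — through a stirred culture, a biofilm, or cells fixed onto the
electrode itself — is hard to measure directly.  `consortnet` models the
culture as a dynamic graph: nodes are cells with substrate $s_i(t)$,
hydrogen peroxide $H_i(t)$, autoinducer-1 $A_i(t)$ and GFP $G_i(t)$
weights; undirected edges are transient communication channels.  It is
aimed at systems/synthetic-biology modelers who want a fast, seeded,
fully scriptable sandbox for consortium and induction design.

Each timestep applies five transitions in order:

1. **Activation & production** — a cell activates with probability
   $P_H(h) = 1/(1+e^{-(h-8)/2})$ (peroxide sensing) or
   $P_A(a) = 1/(1+e^{-50(a-0.25)})$ (AI-1 sensing), with $P(0)=0$;
   activated cells produce $R_H = 2s/(1+e^{-h})$ (GFP, and AI-1 in
   transmitters) or $R_A = 0.2\,a\,s$ (GFP in AI-1 receivers).
2. **Electrode source** (electrical mode) — a single source node deposits
   46 µM peroxide per on-step, wired to at most 5% of cells.
3. **Diffusion** — $c_i \mathrel{+}= \alpha\,\Delta t\,(\sum_{j\in N_i} c_j -
   c_i \deg i)$ for both inducers, with a mass-conserving outflux limiter
   that keeps the explicit scheme physical at $\alpha = 1$.
4. **Growth** — cells with substrate $> k$ divide with probability
   $P_{div}$; substrate/peroxide/AI-1 halve, GFP copies, daughters inherit
   up to 10 of the parent's neighbors.
5. **Edge rewiring** — per-step randomization (stirred culture), static
   edges (biofilm), or partially fixed subpopulations.

Built-in scenario presets cross the Monoculture (peroxide → GFP) and
Transmitter/Receiver (peroxide → AI-1 → GFP) systems with chemical and
electrical induction and with stirred, static, and
transmitter-fixed-to-electrode topologies.

## Worked example

A stirred Transmitter/Receiver culture, 100 founders with four edges per
cell, induced with 100 µM hydrogen peroxide and simulated for 180 steps:

```r
library(consortnet)
cfg <- scenario_config("tr_chemical", dose = 100)
run <- run_simulation(cfg, seed = 1)
run
#> <consortnet_run> seed 1 | chemical induction | randomized edges
#>   180 steps, final nodes 959, median GFP 17370.0, 100.0% active
run$network
#> <consortnet_network> t = 180
#>   nodes: 959
#>   cell-cell edges: 6405  electrode links: 0
#>   roles: ai1_receiver=878, transmitter=81
#>   median GFP 17370.0 | mean H2O2 10.428 | mean AI-1 53.971 | mean substrate 2.086
```

The population grew from 100 to 959 cells (log phase; the substrate cap
bounds it at 3200), every cell ended above the 1000-GFP activation
threshold, and the peroxide input was amplified through AI-1 into a median
GFP near $1.7\times 10^4$ — roughly 5–6-fold the matched Monoculture run.
Pooling replicates mirrors aggregate distribution analyses:

```r
reps <- run_scenario("tr_chemical", seeds = 1:3, dose = 100)
median_gfp(reps)
#> [1] 15890.99
percent_active(reps)
#> [1] 0.9986413
set.seed(1); louvain_modularity(run$network)
#> [1] 0.2393533      # stirred networks stay unstructured; static runs reach ~0.77
```

`run$metrics` holds the per-step time series (node count, median GFP,
percent active, species means/SDs); `write_run()` emits tidy CSV/JSON/
GraphML bundles; `sweep_scenario()` crosses a preset over dose or charge
lists.  See the vignette in `vignettes/consortia-signaling.Rmd` for the
full model description, parameter table and design notes.

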