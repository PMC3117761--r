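---
title: "Simulating mutualistic communities with mutnetsim: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating mutualistic communities with mutnetsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(mutnetsim)
```

## The model

`mutnetsim` simulates a plant–animal mutualistic community as a population
of *host* agents (the sessile partner, e.g. flowering plants) and *visitor*
agents (the mobile partner, e.g. pollinators) that meet at random and
negotiate resource exchanges through a fixed interaction protocol. The
protocol encodes the ecological conditions believed to gate mutualistic
interactions — shared habitat, trait matching, and morphological
complementarity — and either party walks away at the first condition that
fails:

1. **Habitat.** The host reveals its habitat label. If the two agents live
   in different habitats the interaction normally ends (`quit_habitat`);
   occasionally the visitor agrees to a *meta-community* interaction, which
   is allowed only when its own resource pool holds at least half the
   community maximum and then happens with probability
   `metacommunity_prob` (default 0.1). Cross-habitat interactions carry an
   extra resource surcharge, which is why they stay rare.
2. **Trait.** The host announces one of its traits, chosen uniformly at
   random per interaction. If the visitor does not possess that trait the
   attempt ends (`quit_trait`).
3. **Complementarity.** The two agents compare sizes of the shared trait —
   the analogue of bill length against corolla depth. The degree of
   complementarity is `1 - |s_v - s_h| / s_max`; the interaction continues
   only if it strictly exceeds `complementarity_threshold`
   (`quit_complementarity` otherwise).
4. **Resources.** The visitor demands `base_demand × degree` resource units
   and offers back a reward of `reward_fraction × demand` (capped so the
   visitor never commits below its own survival floor). The host offers as
   much of the demand as it can afford while staying at or above its floor,
   counting the incoming reward. If it can offer nothing the attempt ends
   (`quit_resources`); otherwise both sides settle — the visitor also pays
   a fixed living cost, plus the meta-community surcharge when applicable —
   and the attempt is a *success*.

Agent state changes only on success; every quit leaves both agents
untouched. A simulation run repeats random encounters (a uniformly chosen
active visitor picks a uniformly chosen active host) until a fixed quota of
successful interactions — 300 by default — has accumulated; the network of
who-exchanged-with-whom is the object of study. Agents whose pool falls
below their survival floor become inactive and decline further
interactions; they are not removed.

Resource accounting is exactly conservative: for every success, visitor
gain + host net change + living cost + surcharge = 0, so community
resources decline precisely by the sum of logged costs. This identity is
asserted over full runs in the test suite.

## The emergent network and its metrics

Each completed run is aggregated by `build_network()` into a weighted,
directed bipartite graph: one arc per (host, visitor) pair with at least
one success, weighted by the number of successes, arcs pointing host →
visitor (the direction of energy flow). Agents with no successful
interaction are not part of the network. The metrics suite computes the
descriptors standard in mutualistic-web analysis:

* **Connectance** `C = L/S²`, with `L` distinct links and `S` interacting
  species.
* **NODF nestedness** on the binarised host-by-visitor matrix: every pair
  of rows (and of columns) whose marginal totals differ contributes
  `100 × overlap / (fill of the poorer one)`, equal-fill pairs contribute
  zero, and NODF is the mean over all pairs. The implementation is
  vectorised; the tests pin it to a literal loop-based oracle to 1e-9 on
  hundreds of random matrices and cross-check it against
  `vegan::nestednodf`.
* **Isocline of perfect nestedness**: the boundary a perfectly nested
  matrix of the same fill would have, for overlay on the sorted count
  matrix. We use the smooth family `y(x) = r (1 - x/c)^p` with
  `p = 1/fill - 1`, which is monotone non-increasing and encloses exactly
  `fill × r × c`; the defining contract is the area property, and the
  sampled curve integrates to it within 1%.
* **Interaction-frequency and degree distributions** (distinct partners per
  node; in-degrees belong to visitors and out-degrees to hosts under the
  arc convention), with a power-law exponent fitted by unweighted least
  squares on log(frequency) against log(degree). Repeat events with the
  same partner are edge weights, not extra degrees.
* **Dependence** of a species on a partner: the fraction of its interaction
  events attributable to that partner, computed in both directions (these
  are asymmetric), plus binned relative-frequency distributions.

## Default parameters and why

Community-level settings follow the reference experimental design for this
kind of simulation: 10 hosts and 15 visitors (animal species outnumber
plant species in real pollination webs), 2 habitats with round-robin
assignment, initial resources from a normal distribution centred on the
midpoint of [5, 20] with sd a quarter of the range and truncated to those
bounds, trait sizes uniform on [0, 5], meta-community probability 0.1 with
the half-of-maximum eligibility rule, and termination at 300 successes.

The remaining knobs are genuinely free — no reference values exist for
them — and were fixed once, jointly, so that replicate runs occupy the
structural ranges reported for real mutualistic webs (connectance between
0.05 and 0.1, NODF between 25 and 80), and were not revisited afterwards:

| parameter | default | role |
|---|---|---|
| `base_demand` | 4 | resources demanded at perfect complementarity; a typical exchange moves a few units of a 5–20 pool |
| `reward_fraction` | 0.5 | reward returned to the host per unit demanded; keeps resources circulating so runs do not starve |
| `complementarity_threshold` | 0.4 | niche half-width of 3 size units on the 0–5 scale; prunes poorly matched links without isolating whole agents |
| `living_cost` | 0.2 | per-interaction cost; large enough that visitors gradually drop below the meta-community eligibility bar (keeping cross-habitat links rare late in a run), small enough that the community never starves before the success quota |
| `metacommunity_surcharge` | 1 | extra cost of a cross-habitat exchange |
| `n_traits_universe` | 10 | size of the community trait pool |
| `traits_per_agent` | 1–6, geometric weight `trait_count_decay = 0.6` | specialist-heavy guild composition: ~44% of agents carry a single trait, generalists with 5–6 traits are rare |
| `trait_popularity_decay` | 0.85 | some traits are community-wide common, others rare |

The last three deserve comment, because they are where the network
structure comes from. With uniform trait counts and popularities the
simulated webs come out too dense (connectance above 0.1) and too
homogeneous in degree. Making specialists common and generalists rare —
the composition actually observed in mutualistic guilds — produces the
heavy-tailed degree distributions and the generalist hubs, and because a
generalist's trait set tends to contain a specialist's, it also produces
nested (NODF) structure by containment. Skewed trait popularity
strengthens that containment and stabilises the nestedness of individual
runs. The calibration was a coarse grid over these knobs scored on the
per-run connectance and NODF windows across several replicate experiments
with different base seeds.

Living costs interact with the meta-community rule in a way worth knowing
about: costs near 0.1 leave every visitor above the eligibility bar for
the whole run, flooding the network with weak cross-habitat links and
pushing connectance above 0.1, while costs above roughly 0.4 sink the
whole community before 300 successes (the quota's sunk costs exceed the
resources the community starts with). The default 0.2 sits between the
two regimes.

## Randomness, determinism and numerical choices

All randomness in a run flows from R's RNG seeded once with `config$seed`
at the top of `run_simulation()`; identical configurations reproduce
identical attempt logs, final states and exported artefacts byte for byte.
`run_replicates()` uses consecutive seeds so replicates differ only in the
random initialisation and encounter history. Truncated-normal draws use
rejection sampling; a run aborts with an informative error after
`1000 × target_successes` attempts, which flags configurations where
success is impossible (e.g. an unreachable complementarity threshold).
Matrix rows and columns are ordered by decreasing totals with id
tie-breaks purely for display and overlay reproducibility — every metric
is permutation invariant, which the tests assert directly. Degenerate
inputs error early and explicitly: connectance and the distributions are
undefined for empty networks, NODF needs at least two non-empty rows and
columns, the power-law fit needs three distinct positive degrees.

## Problem sizes used in the checks

The packaged tests and the acceptance script work at the scale of the
reference experiment itself: 15 replicate runs of 25 agents to 300
successes each (a few thousand protocol attempts per run), NODF oracle
comparisons on 200 random 10×15 matrices, and Monte-Carlo frequency checks
of the uniform-choice operations at 10⁴–10⁵ draws. A full replicate
experiment takes on the order of half a minute.

## What the generator does and does not emulate

The synthetic communities reproduce the *structural* signatures of real
mutualistic webs — connectance in the empirical 0.05–0.1 band, NODF
nestedness in the 25–80 band, skewed degree distributions with generalist
hubs, an excess of weak dependences with a secondary mode of fully
dependent specialists. They do not emulate: population dynamics (no birth,
death or replacement; inactive agents persist), evolution or trait change,
seasonal or spatial structure beyond the two-habitat label, sampling
effort or observation error in empirical matrices, or abundance-driven
encounter rates (encounters are uniform). Passing tests therefore say the
interaction protocol suffices to *generate* these structural patterns, not
that it explains any particular natural community.

## Known limitations

* Per-run statistics of 15-replicate experiments are extreme-value noisy:
  with a per-run probability of roughly 0.93 of landing jointly inside the
  connectance and NODF windows, an occasional experiment has 2–3 of 15
  runs outside, whatever the seed.
* A strict per-run *majority* of nodes with ≤ 2 partners is generally not
  attainable simultaneously with connectance above 0.05: with ~25
  interacting species, C > 0.05 forces more than ~31 links and hence a
  mean above ~2.5 partners per node. The simulated webs show the softer
  form of the pattern — partner-count histograms dominated by 1 and 2 with
  a long right tail and hub nodes well above twice the mean.
* NODF is computed on binarised matrices (its original definition);
  weighted variants are not implemented.
* The power-law fit is a descriptive log–log regression, not a maximum
  likelihood estimate with a truncation model; it is meant to summarise
  the direction and steepness of the decay, not to test the power-law
  hypothesis.

## A worked example

```{r example}
cfg <- sim_config(seed = 1)
res <- run_simulation(cfg)
res

net <- build_network(res$records)
net

report <- metrics_report(net)
report
```

Replicate experiments and file-based workflows go through the `cmd_*`
wrappers (`cmd_run()`, `cmd_replicates()`, `cmd_analyze()`, `cmd_sweep()`),
or the command-line front end installed at
`system.file("cli", "mutnetsim.R", package = "mutnetsim")`.
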