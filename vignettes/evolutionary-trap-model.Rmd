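---
title: "An individual-based model of parasitoid evolution on an evolutionary-trap host"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An individual-based model of parasitoid evolution on an evolutionary-trap host}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paratrap)
```

## The question the model addresses

When a novel host species invades the range of a parasitoid, females may
attack it even though their offspring cannot develop in it: the invader is
chosen but unsuitable, a preference–performance mismatch known as an
*evolutionary trap*. `paratrap` simulates a 2-host/1-parasitoid community in
which every parasitoid carries two heritable, clonally inherited traits:

* a **host-preference trait** `q` on `[-1, +1]` that controls patch
  rejection (`q = 0` accepts every patch; `q = +1`/`q = -1` exclusively
  accept patches of host 1 / host 2), and
* a **parasitization strategy** `S` in `{1, 2, 3}`: specialists
  physiologically compatible only with host 1 or host 2, or a generalist
  compatible with both that pays a developmental-rate cost.

Incompatible attacks come in two flavours, selected by the `scenario`
parameter: they either leave the host unharmed (scenario 1) or kill it
without producing parasitoid offspring (scenario 2, *non-reproductive host
mortality*). The package's purpose is to expose every mechanism of this
model as a tested operation and to run replicated evolutionary experiments
over the grid of search efficiencies, generalist efficiencies, mutation
regimes and scenarios.

## Host demography

Host generations are discrete and non-overlapping. The surviving adults of
species $i$ reproduce and scatter offspring uniformly over that species'
$n_i$ patches; each patch receives an independent Poisson number of
offspring with mean

$$\lambda_{i} = \frac{1}{n_i}\, r_i\, \tilde H_i\, e^{-\tilde H_i / K_i},$$

a stochastic Ricker model whose parasitoid-free equilibrium is
$H_i^\ast = K_i \ln r_i$ (`equilibrium_density()`). Density regulation and
reproduction are this single combined step; there is no separate survival
draw. Each juvenile host is vulnerable to parasitism for an exponentially
distributed *sensitive period* with mean `tau_dH` (10 time units by
default), after which it matures and can no longer be parasitized.
Simulations start with `round(K ln r)` adults per species, i.e. at the
parasitoid-free equilibrium.

## Foraging

Within a generation, time is continuous. A female cycles through three
phases:

1. **Search.** Patches are found at rate `1/tau_s`; the located patch is
   uniform over all `n1 + n2` patches. The patch is rejected with
   probability `max(0, -q)` (host-1 patch) or `max(0, +q)` (host-2 patch);
   rejection costs only the redrawn search time, so selectivity is paid in
   expected search time.
2. **Patch exploitation.** Each of the `m` encounterable hosts in the patch
   is met as an independent Poisson process with mean interval `tau_e`, so
   the next encounter arrives after an exponential wait with mean
   `tau_e / m`. Every *first* encounter with a vulnerable host yields one
   egg (females do not discriminate against already-attacked hosts, so
   superparasitism by different females is common); a *second* encounter
   with the same individual during the visit, or `tau_a` time units without
   any encounter (anchored at patch entry for empty patches), triggers
   departure. The number of distinct hosts met per visit therefore follows
   birthday-problem scaling, about $\sqrt{\pi m / 2}$.
3. **Recovery.** After leaving, the female recovers for a
   Gamma(`k`, scale `tau_r`) time, one exponential unit per egg laid, then
   resumes searching.

This generates a saturating (Holling type 2) per-host attack probability as
an emergent property, which the test suite checks across host densities.

## Egg development and host fate

Each egg's development time is exponential with a mean set by the
*mother's* strategy: `tau_dP1 = tau_dP2 = 20` for specialists and the
slower `tau_dP3` for generalists (maternal physiology governs the egg, so
a freshly mutated offspring genotype is expressed only from its own
adulthood). Compatibility follows the mother's strategy and the host's
species. Whether an egg can *decide* the host's fate depends on the
scenario: in scenario 1 only compatible eggs qualify (an incompatible egg
is inert from the moment it is laid); in scenario 2 every egg qualifies.

The host's fate is the race between its maturation time and the earliest
qualifying egg completion $T^\ast$ (a later-laid egg can decide if it
completes first). If $T^\ast$ comes first the host dies at $T^\ast$:
reproductively — exactly one offspring emerges, the parasitoid being
solitary — when the deciding egg is compatible, non-reproductively (no
offspring) when it is not. Otherwise the host survives and all its eggs
are inviable. Because the remaining sensitive time at any lay moment is
again exponential, a single attack kills with probability
$\tau_{dH} / (\tau_{dH} + \tau_{dP})$, the closed form used as the test
oracle (`single_attack_success_probability()`): 1/3 for specialists,
0.177–0.190 for generalists across the default `tau_dP3` grid
(46.51–42.55, i.e. generalist efficiencies 0.43–0.47). Killed hosts leave
the encounterable pool at their death time, so other females can waste
eggs on a doomed host until then.

The generation ends when no vulnerable host remains anywhere; pending
forager events are then discarded (no further reproduction is possible),
offspring replace the parental parasitoid generation, and surviving hosts
seed the next Ricker draw.

## Genetics

Both traits sit on single haploid clonal loci. Per reproductive event the
preference mutates with probability `mu_q` by a standard-normal increment
clamped to `[-1, 1]` (the trait's defined range; the sd of the resulting
clipped kernel from `q = 0` is 0.718), and the strategy mutates with
probability `mu_S` along the kernel `1 -> 3`, `2 -> 3` (probability 1) and
`3 -> 1` / `3 -> 2` (probability 1/2 each): a specialist cannot become the
other specialist in one step, so a host shift must pass through the
generalist bridge. Under forced mutation this chain's stationary
distribution is (1/4, 1/4, 1/2) (`strategy_transition_matrix()`).

## Simulation engine and numerical choices

The within-generation dynamics are a race of competing memoryless clocks,
simulated event by event (a continuous-time, Gillespie-style discrete-event
scheme) in compiled code: events are processed in `(time, sequence)` order
from a binary heap, with the sequence number as a deterministic tie-break,
and stale events are skipped via per-actor version counters. Because all
waiting times are exponential, pool-size changes (a host dying mid-wait)
are handled exactly by redrawing the affected female's next-encounter
clock. All randomness flows through R's RNG, so a single `set.seed()`
makes entire replicates bit-reproducible; `replicate_seed()` derives
per-replicate seeds deterministically from a master seed so any grid cell
can be rerun in isolation. Host regeneration, mutation and reporting run
in R on columnar state.

Two readings of the model were genuinely open and are resolved as follows:

* **Matured hosts** remain present and encounterable (they cost foraging
  time and count toward the second-encounter leaving rule) but cannot be
  parasitized, since post-period encounters are implied by parasitism
  being conditional on finding the host *before* the sensitive period
  ends. The alternative — removal at maturation — sits behind the
  `matured_encounterable` switch so the two readings can be compared
  directly; they differ only in how foraging time is spent late in a
  generation.
* **Per-visit memory** is cleared on departure, so a female re-entering a
  patch may oviposit again in a host she attacked earlier
  (self-superparasitism across visits is rare but possible).
* In scenario 1 an incompatible egg never enters the decisive race;
  "no interaction" is taken literally, the attack has no physiological
  consequence for the host.

## What the experiments show, and a structural caveat

With preference fixed (`mu_q = 0`) an all-specialist-1 population facing
the trap host evolves along the mutational path specialist-1 →
generalist → specialist-2. Which endpoint dominates depends on the
generalist's developmental efficiency and on search efficiency, and the
scenarios differ sharply: without non-reproductive killing the untouched
novel-host population is an open niche that pulls generalists (and then
novel-host specialists) in, while with non-reproductive killing the
resident specialists already suppress both host populations, removing that
advantage and hindering establishment of novel-host genotypes.

One structural property of the model deserves emphasis. In scenario 2 with
`q` fixed at 0, the model is exactly symmetric under simultaneously
relabelling the host species and the two specialist strategies, which
makes the two specialists selectively neutral relative to each other;
their joint frequencies drift, fed by mutational input through the weakly
selected generalist class. Small populations and long horizons therefore
always produce occasional excursions of the novel-host specialist even
under non-reproductive killing; what the killing scenario changes robustly
is the *rate* of establishment and the suppression of the generalist
bridge, not an absolute exclusion. The acceptance suite runs this contrast
at a reduced scale and reports both the replicate fraction in which
novel-host specialists appear and their maximum frequency.

## Problem sizes used by the tests

The test and acceptance runs use reduced problem sizes chosen to keep the
full suite fast while staying in the regime where the mechanisms operate:
the parasitoid-free equilibrium check runs the default community for 500
generations; distributional oracles use $10^5$ draws with 3-standard-error
bands; the scenario contrast uses `K = 200`, 8 patches and 100 founding
parasitoids for 500 generations and 10 replicates per scenario. The
full-scale configuration (`K = 1000`, 20 patches, `P0 = 500`, 1000
generations, 30 replicates) is exposed through `trap_grid()` and the
command-line front end (`inst/cli/paratrap.R`).

## What the synthetic community does and does not emulate

The simulator generates every individual internally; there is no field
data. It captures time-limited foraging, patch structure, superparasitism
races, the specialist–generalist trade-off and non-reproductive host
mortality. It deliberately omits haplodiploid or sexual genetics,
recombination, multilocus traits, host counter-resistance, egg limitation,
learning, interspecific host competition and environmental stochasticity
in `r` and `K`; passing tests therefore say nothing about systems where
those forces dominate.

## A worked example

```{r example, eval = FALSE}
p <- trap_params(K1 = 200, K2 = 200, n1 = 8, n2 = 8, P0 = 100,
                 generations = 500, tau_s = 3, tau_dP3 = 46.51,
                 mu_S = 0.01, mu_q = 0, scenario = 1)
sim <- trap_sim(p, replicate_seed = 11)
print(sim)
plot(sim)
write_timeseries(sim, "run.csv")
```
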