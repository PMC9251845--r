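# paratrap

Individual-based simulation of parasitoid evolution when an invasive host
acts as an **evolutionary trap** — a host that is attacked but unsuitable
for offspring development. The package is aimed at evolutionary ecologists
and biological-control modellers who want to ask: under which foraging and
trade-off conditions do parasitoids escape the trap by evolving behavioural
avoidance, by expanding their physiological host range (generalism), or by
a complete host shift — and how does **non-reproductive host mortality**
(an incompatible attack that kills the host without yielding offspring)
constrain those routes?

## The model

Two host species live in separate patches (`n1`, `n2` patches). Host
generations are discrete; the offspring of species *i* in each patch are
Poisson with mean

    lambda_i = (1/n_i) * r_i * H_i * exp(-H_i / K_i)

(a stochastic Ricker model; parasitoid-free equilibrium `H* = K ln r`).
Each juvenile is vulnerable for an exponential sensitive period with mean
`tau_dH`.

Within a generation, time-limited parasitoid females forage in continuous
time: they find patches at rate `1/tau_s`, reject them according to a
heritable preference `q` in `[-1, +1]` (rejection probability `max(0, -q)`
for host-1 patches, `max(0, +q)` for host-2 patches), encounter the `m`
hosts of an accepted patch at superposed per-host rate `m/tau_e`, lay one
egg per first-encountered vulnerable host, leave on a repeat encounter or
after `tau_a` without one, and then recover for one exponential time of
mean `tau_r` per egg laid. Each female also carries a heritable
parasitization strategy `S`: specialist on host 1, specialist on host 2,
or generalist. Eggs develop in exponential time with mean `tau_dP1 =
tau_dP2 = 20` (specialist mothers) or the slower `tau_dP3` (generalist
mothers) and race the host's maturation; the first *qualifying* egg to
complete decides the host's fate, and a single attack kills with
probability `tau_dH / (tau_dH + tau_dP)`. Incompatible attacks either do
nothing (scenario 1) or kill the host without producing offspring
(scenario 2). Traits are clonal haploid loci with rare mutation (`mu_q`:
clamped standard-normal jumps; `mu_S`: specialist -> generalist with
probability 1, generalist -> either specialist with probability 1/2).

The within-generation event race is simulated exactly (Gillespie-style
event queue, compiled with Rcpp); everything is seeded and bit
reproducible.

## A worked example

A reduced-scale community (`K = 200`, 8 patches per species, 100 founding
females, 500 generations) under scenario 1, high search efficiency
(`tau_s = 3`) and the least efficient generalist (`tau_dP3 = 46.51`), with
strategy mutation only:

```r
library(paratrap)
p <- trap_params(K1 = 200, K2 = 200, n1 = 8, n2 = 8, P0 = 100,
                 generations = 500, tau_s = 3, tau_dP3 = 46.51,
                 mu_S = 0.01, mu_q = 0, scenario = 1)
sim <- trap_sim(p, replicate_seed = 11)
print(sim)
#> Host-parasitoid trap simulation: 500 generations, seed 11
#>   scenario 1, tau_s = 3, generalist efficiency 0.430, mu_q = 0, mu_S = 0.01
#>   final: P = 202 (S1 0.27, S2 0.28, S3 0.45), H1 = 172, H2 = 165
#>   outcome: polymorphic
```

The founding population consisted purely of host-1 specialists; after 500
generations specialists of the *novel* host (S2, frequency 0.28) have
established alongside the original specialists and generalists — the trap
has been escaped by adaptation. `plot(sim)` draws the strategy-frequency
and density trajectories, `summary(sim)` aggregates the run, and
`write_timeseries(sim, "run.csv")` writes the per-generation records with
a JSON provenance sidecar. Replicated parameter grids run through
`experiment_design()` + `trap_grid()`, and a command-line front end lives
in `inst/cli/paratrap.R`:

```sh
Rscript inst/cli/paratrap.R run --scenario 2 --tau_s 3 --generations 200 \
        --K 200 --n 8 --P0 100 --seed 4 --outdir out/
```

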