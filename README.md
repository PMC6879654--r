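# cytodyn

Does the clock time of a severe blunt injury change the systemic
inflammation program that follows it? `cytodyn` is an R package for
analysts of serial inflammatory-mediator panels (cytokines, chemokines,
soluble receptors, cortisol, NO2-/NO3- in pg/mL, drawn repeatedly over the
first week after trauma) who want to contrast daytime- versus
nighttime-injured patients on matched cohorts.

The package implements the full chain:

1. **Cohort construction** — classify injury clock time into half-open
   day (`[8:00, 17:00)`) and night (`[22:00, 5:00)`) windows; filter to
   ISS > 20; 1:1 greedy nearest-neighbour matching on age within exact sex
   strata (10-year caliper); mean ± SEM / n (%) summary tables; Fisher's
   exact test by full hypergeometric enumeration.
2. **Group-by-time statistics** — per-mediator two-way ANOVA
   (group × time, Type II sums of squares for unbalanced data, on
   `log10(x + 0.01)`), Mann-Whitney confirmation, Spearman correlation.
3. **Dynamic Network Analysis (DyNA)** — correlation networks in adjacent
   8-h windows (`[0,8)`, `[8,16)`, `[16,24)` h post-injury), edge iff
   `|r| >= 0.7`, complexity summarized by the density statistic
   `E * N / (N(N-1)/2)` (a complete graph has density `N`).
4. **Dynamic Bayesian Network (DyBN) inference** — exact per-child
   enumeration of all parent sets up to fan-in 3 over time-sliced mediator
   panels, scored with a linear-Gaussian BIC
   `-n/2 log(RSS/n) - (|P|+2)/2 log n`; posterior edge probabilities by
   Bayesian model averaging; self-edges reported as feedback; central
   nodes ranked by outgoing posterior mass.
5. **Synthetic cohorts** — a seeded generator emulating the study design
   (32 mediators, 3 draws in 24 h then daily to day 7, two groups of 15,
   group-by-time log-scale effects, block-correlated log-normal noise,
   assay floor, missingness), used by every downstream test.

The methods vignette (`vignettes/cytodyn-methods.Rmd`) explains each model,
its assumptions, and the design decisions.

## Worked example

```r
library(cytodyn)

cfg <- runConfig(synthetic = syntheticConfig(seed = 11), seed = 11)
runPipeline(cfg, "demo_run")

st <- read.csv("demo_run/stats.csv")
subset(st, p_group < 0.05,
       select = c(mediator, F_group, p_group, p_int, mw_p))
#>    mediator F_group  p_group   p_int    mw_p
#> 8      IL-7   16.15 1.04e-04 0.79645 0.07284
#> 12    IL-15    6.54 1.18e-02 0.50079 0.01748
#> 13   IL-17A   12.82 5.04e-04 0.09092 0.05303
#> 17   MIP-1a    7.04 9.04e-03 0.84066 0.12821
#> 20   GM-CSF   27.89 6.01e-07 0.00849 0.00117
#> 21  Eotaxin    5.94 1.63e-02 0.66126 0.05303
#> 29     sST2    7.85 5.94e-03 0.90067 0.12821
#> 31 Cortisol    7.54 6.99e-03 0.70116 0.03497

read.csv("demo_run/dyna_density.csv")
#>   group window_start window_end n_nodes n_edges density
#> 1   Day            0          8      32      59    3.81
#> 2   Day            8         16      32      60    3.87
#> 3   Day           16         24      32      59    3.81
#> 4 Night            0          8      32      59    3.81
#> 5 Night            8         16      32      67    4.32
#> 6 Night           16         24      32      59    3.81
```

The stats table flags the mediators whose trajectories differ between the
matched day and night groups: the generator's planted pattern (night-raised
IL-17A and sST2, day-raised IL-7/IL-15/GM-CSF/MIP-1α) is recovered, with
per-mediator ANOVA group p-values and the per-time-point Mann-Whitney
minimum p alongside. The density trace quantifies network complexity per
group per window — here the night group's `[8,16)` network is the densest
(67 of 496 possible edges among 32 evaluable nodes, density 4.32). The run
directory also contains per-window networks (SIF + GraphML), DyBN edge
posteriors and central-node rankings per group, the matched pairs, cohort
summary tables, and a `manifest.json` whose MD5 config hash makes reruns
verifiable: the same config and seed reproduce every output byte.

A thin CLI wrapper is included: `Rscript inst/scripts/cytodyn-cli.R run
--seed 11 --out demo_run`.

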