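---
title: "Methods: diurnal mediator dynamics, windowed networks, and dynamic Bayesian networks"
author: "cytodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diurnal mediator dynamics, windowed networks, and dynamic Bayesian networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytodyn)
```

# The scientific question

After severe blunt trauma, circulating inflammatory mediators (cytokines,
chemokines, soluble receptors, cortisol, reactive nitrogen end-products)
rise within hours and evolve over days. Because the immune system is under
diurnal/circadian control, the clock time at which the injury occurs may
shift the whole inflammation program. `cytodyn` implements an analysis
chain for that question on serial plasma panels: it contrasts patients
injured in a daytime window against patients injured at night, on matched
cohorts, at three levels of resolution — per-mediator group-by-time
statistics, windowed correlation-network complexity, and directed
time-slice (dynamic Bayesian) network structure.

# Cohort construction

**Day/night classification.** Injury clock time (minutes since midnight) is
assigned to `Day` on `[480, 1020)` (8:00–17:00, the shortest annual daylight
period at a mid-latitude site), `Night` on `[1320, 1440) U [0, 300)`
(22:00–5:00, the shortest night), otherwise `Neither`. Both windows are
half-open: the written definitions ("8 am–5 pm") carry no boundary
semantics, and the half-open convention guarantees each minute belongs to at
most one window (the three classes partition the day into 540/420/480
minutes).

**Severity filter and matching.** Only moderately/severely injured patients
(ISS strictly greater than `issMin`, default 20) are match candidates.
Matching is 1:1: exact on sex, greedy nearest-neighbour on age, with a
10-year caliper. A full logistic propensity model on (age, sex, ISS > 20)
with sex matched exactly degenerates to distance on age within sex strata,
so the greedy matcher is presented as what it is rather than dressed up as a
fitted model. Determinism: globally closest age pairs are accepted first,
ties broken by smaller absolute ISS difference and then lexicographic
patient id; with distinct ages the result is symmetric in the two groups.

**Summaries and categorical tests.** Cohort tables report mean ± SEM
(sample SD over the square root of n) for continuous variables and n (%)
for categorical ones, with percentages rounded half-up to one decimal, the
convention of clinical tables. Fisher's exact test for 2×2 tables is
computed by full hypergeometric enumeration with the two-sided
sum-of-small-probabilities rule and a relative slack of 1e-7 on the "at
most as probable" comparison; the mid-p and doubling conventions give
different numbers and are deliberately not used. On the orthopedic
intervention counts of the matched sub-cohorts (5/15 vs 2/15) this test
gives p ≈ 0.39 — reported source tables that print a far smaller value for
these counts cannot be reproduced by any standard two-sided convention, so
the enumeration is treated as authoritative.

# Per-mediator statistics

The response default is `log10(concentration + 0.01)`: mediator panels are
positive and right-skewed, and the nonparametric confirmation step only
makes sense for skewed raw data. The main test is a fixed-effects two-way
ANOVA (group, time, interaction). For unbalanced data — unavoidable with
missed draws — Type II sums of squares are the default: each main effect is
adjusted for the other main effect but not for the interaction, which is
well-defined without reference-level choices. Type III with sum-to-zero
contrasts is available behind a flag. Repeated measures are treated as
independent observations; this mirrors the common desktop-statistics
default for this design and is a stated limitation, not an oversight — a
mixed model is out of scope.

Exactly cell-constant data receive F = 0 for zero-variation terms (and
F = Inf for a term that absorbs all variation), rather than 0/0.

The Mann-Whitney U test (midranks; exact enumeration when
`n_x * n_y <= 400` and tie-free, otherwise normal approximation with tie
and continuity corrections) is run per time point between groups and pooled
per mediator as the minimum p over time points. The pooling is an
interpretation: the source description of "comparing the p-values" of the
ANOVA is ambiguous, and the minimum-p confirmation is the reading that is
actually computable. It is reported alongside, never instead of, the ANOVA.
Spearman correlation is Pearson on midranks with the t approximation on
n − 2 degrees of freedom. No multiplicity adjustment is applied across the
32 mediators by default (per-mediator p-values are the reported quantity);
Benjamini-Hochberg is available behind a flag.

# Windowed correlation networks (DyNA)

Within each adjacent window (`[0,8)`, `[8,16)`, `[16,24)` hours
post-injury; half-open, multiple draws averaged), the correlation of every
mediator pair is computed across patients (Pearson on the log scale by
default; Spearman by flag — the source method names no coefficient, so both
are supported and the default is documented). An edge is created when
`|r| >= 0.7`; the absolute-value convention is the default because inverse
co-regulation is biologically meaningful, and signed thresholding is a
flag. The signed `r` is kept on the edge.

Network complexity is summarized by the density statistic

\[ \mathrm{density} = \frac{E \cdot N}{N(N-1)/2} = \frac{2E}{N-1}, \]

edge count scaled by node count over the maximum possible edge count; a
complete graph has density N. `N` counts the mediators with evaluable data
in the window (at least 3 non-missing values), not the panel size, so
density is comparable across windows with missing assays; the panel-size
convention is available via the node-count argument. Pairs with fewer than
3 complete observations, and constant mediators, are skipped.

# Dynamic Bayesian networks (DyBN)

Time is modelled discretely: each mediator gets one node per time slice,
and all edges run from slice t to slice t+1 (self-edges model feedback).
Transitions are built per patient from consecutive occupied grid slots;
a missed draw breaks the chain (no pair is formed across a gap, so no
dynamics are fabricated), and pairs with any missing variable are dropped.
The t and t+1 matrices are z-scored per column independently, which makes
the score invariant to affine rescaling of any variable.

Each child is scored against every parent set of size at most `fanIn`
(default 3 — for 32 mediators that is 5,489 regressions per child, all of
which are solved from one precomputed cross-product matrix) with a
linear-Gaussian BIC:

\[ s(\text{child}, P) = -\tfrac{n}{2}\log(\mathrm{RSS}/n)
   - \tfrac{|P|+2}{2}\log n . \]

Because the structure factorizes over children, per-child argmaxes compose
into the exact global optimum; no search heuristics are involved. Under a
uniform prior over parent sets, the posterior of a set is proportional to
`exp(score - max)`, and an edge's posterior is the mass of sets containing
that parent. Central nodes are ranked by summed outgoing posterior mass —
the operationalization of "most influential upstream mediator".

Design choices made here, openly: the cited research lineage for this
analysis uses non-homogeneous change-point samplers, but a grid of at most
10 slices with 15 patients per group cannot support change-point inference;
exact bounded-fan-in enumeration is deterministic and testable, and matches
the discrete-Markov description. Transitions over 8-hour and 24-hour steps
are pooled into one kernel (no spacing correction is described in the
source lineage); a per-gap weighting flag is a possible extension but is
off by default. Degenerate fits are handled explicitly: a zero-residual
regression is floored at variance 1e-12, and collinear designs fall back to
a pseudo-inverse with a warning.

# The synthetic-cohort generator

Real panels of this kind are rarely shareable, so the generator is
first-class, tested code that defines the study conditions the analyses are
validated under: 15 day-injured plus 15 night-injured patients; the
32-mediator panel; draws at 0, 8, 16 hours (the within-24-h spacing is not
specified in the emulated design, so a nominal 8-hour grid is adopted) and
then daily to 168 h.

Log-concentrations for patient i at time t are

\[ \log x = b_0 + b_1 e^{-t/\tau} + \Delta(\text{group}, t) + \sigma (L z),\]

with baseline `b0 = log(10)`, early peak `b1 = 1.5` decaying with
`tau = 48 h` (the qualitative early-peak-then-decay shape of post-trauma
time courses; not fitted to any figure), group-by-time effects Δ active on
half-open hour intervals, equicorrelated block noise (Cholesky factor L),
and `sigma = 1.0` natural-log units, a realistic coefficient of variation
for multiplex cytokine panels. Values are truncated below at an assay floor
of 0.01 pg/mL and i.i.d. missingness is applied at 2% — chosen as the
simplest testable missingness model; the rate keeps complete-case
transition pairs plentiful (complete-case retention across 32 variables
scales as `(1 - r)^64`). The default effects emulate the qualitative
published pattern: IL-17A (from 24 h) and sST2 elevated after nighttime
injury; IL-7, IL-15, GM-CSF and MIP-1α elevated after daytime injury; round
log-scale magnitudes (0.4–1.0), not fits. Correlation blocks may be
restricted to one group and a time interval, which is how a configuration
expresses stronger early co-regulation after nighttime injury.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: within-patient serial correlation (each
draw's noise is independent given the mean trajectory), assay-specific
detection-limit censoring patterns, informative missingness (draws missed
because patients are in surgery), mechanism-of-injury effects on mediators,
and any pharmacokinetic realism. The VAR(1) panel generator used for DyBN
benchmarks is a separate, deliberately minimal linear process with a known
adjacency, stable whenever `|coef|` times the maximum absolute row sum of
the adjacency is below 1.

# Numerical and testing choices

* Fisher enumeration is validated exhaustively against an independent
  log-binomial-coefficient oracle on **every** 2×2 table with total at
  most 40 (about 136,000 tables), to 1e-12.
* The ANOVA engine is validated against an independent Type II/III
  implementation (`car::Anova`) on random unbalanced all-cells-occupied
  designs, to 1e-8 on sums of squares and F.
* DyBN enumeration is validated against a naive re-enumeration oracle
  (per-subset `lm()` fits) exactly, and on a planted 6-node, 8-edge VAR(1)
  benchmark (coefficient 0.5, noise SD 1, 30 patients × 10 time points) it
  must recover at least 7 of 8 planted edges at posterior > 0.5 with at
  most 2 false edges in at least 90% of 50 seeds. Rows of the planted
  adjacency with two parents carry weight 0.9 so the stability condition
  holds at coefficient 0.5.
* Null calibration: with all effects and blocks removed, the per-mediator
  ANOVA group test must reject at the nominal 5% level within binomial 99%
  bounds over 200 seeds × 8 mediators (an independent 600-seed check during
  development put the rate at 0.053).
* Problem sizes in the test suite (e.g. 8-mediator null panels, 50-seed
  recovery sweeps) are the package's own choice of smallest sizes at which
  the binomial/recovery bounds are sharp.

# Known limitations

Repeated measures are not modelled; the DyBN is homogeneous across
unequally spaced transitions; matching is greedy rather than optimal (an
optimal assignment can differ when calipers bind); the generator's
missingness is non-informative. These are documented trade-offs chosen to
keep every component deterministic, exactly testable, and faithful to the
analysis chain it re-implements.
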