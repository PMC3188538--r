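---
title: "Quantifying replication fidelity: fluctuation assays, per-base-pair rates, and the error threshold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying replication fidelity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutfidelity)
```

## What this package models

Haploid budding yeast tolerates large increases in its spontaneous
mutation rate, but only up to a point: when replication errors
inactivate roughly one essential gene per cell division, colonies stop
forming. `mutfidelity` implements the quantitative chain that supports
this kind of analysis:

1. **Fluctuation analysis** — estimating a mutation rate from the
   distribution of resistant-mutant counts across parallel cultures.
2. **Spectrum classification** — scoring sequenced mutants as
   chain-terminating, missense, or silent substitutions, indels, or
   complex events.
3. **Per-base-pair conversion** — correcting a reporter-gene
   (phenotypic) rate for mutations the reporter cannot reveal, yielding
   rates comparable across loci and organisms.
4. **Repair arithmetic** — fold effects of removing proofreading or
   mismatch repair (MMR), the percentage of errors each pathway
   corrects, and predicted rates of unconstructable double mutants.
5. **Extinction simulation** — a branching-process model of colony
   formation under lethal mutation load, with an analytic
   Galton-Watson oracle and a critical-rate estimator.
6. **Synthetic data** — seeded generators reproducing the statistical
   structure every estimator assumes, so the whole pipeline is testable
   without any external data.

## The fluctuation model

A culture grown from a few cells to `Nt` cells accumulates mutations
at random times during growth. A mutation arising early founds a large
resistant clone ("jackpot"); a late mutation founds a small one. Under
the Lea-Coulson formulation, the number of mutant cells in a culture is
compound Poisson: the number of mutation events is Poisson with mean
`m`, and each event contributes a clone whose final size has
probability `q_j = 1/(j(j+1))`. The probability generating function is
`exp(m (1-z) ln(1-z) / z)`, and the pmf follows the Ma-Sandri-Sarkar
recursion (its Panjer form):

```
p_0 = exp(-m),    p_n = (m/n) * sum_{j=0}^{n-1} p_j / (n - j + 1)
```

A note on this recursion: a widely circulated variant divides by
`(n-j)(n-j+1)` instead. That variant does not define a probability
distribution (its total mass is `exp(-0.355 m) < 1`) and disagrees with
Monte-Carlo simulation of the mutation-growth process; the form above
follows directly from the generating function and matches simulation,
so it is the one implemented (see `ld_pmf()`).

```{r}
ld_pmf(1, 4)          # P(0) = e^-1; P(1) = e^-1/2; P(2) = e^-1 (1/6 + 1/8)
```

**Plating dilution.** Strong mutators are plated at 1:10 to 1:200
dilutions. A diluted plating observes a binomial thinning of the
culture's mutant count, so the likelihood uses the thinned pmf
`q_k = sum_n p_n Binom(k; n, z)` with `z` the plating fraction. The
convolution is truncated where the binomial kernel can no longer reach
the requested counts (`n ~ (k_max + 10 sqrt(k_max) + 25)/z`), not where
the Lea-Coulson tail mass is negligible — the tail decays only like
`m/n`, so a literal tail-mass cutoff would be unreachable.

**Estimation.** `mle_m()` maximizes the log-likelihood over `log m`
with a bracketed golden-section search started at the P0 estimator
`-log(fraction of zero cultures)` (median-based when no culture is
mutant-free). `lr_interval()` inverts the likelihood-ratio statistic,
`2[l(m_hat) - l(m)] = 3.841` at 95%, by bisection on each side; the
lower endpoint is 0 at the all-zero boundary. The phenotypic rate is
`m_hat / Nt`, equating cell divisions with the final colony-forming-unit
count (growth from ~1 cell gives divisions = final cells - 1 ~ Nt).

**Numerical guards.** Counts beyond 5000 use the exact large-`n`
asymptotic `p_n ~ m/(n(n+1))` (accurate to <1% there) instead of the
O(n^2) recursion. Log-pmf entries that underflow — the optimizer probing
`m` far above the data — are replaced by the exact large-`m` leading
term `-m + k log(m z / 2) - log k!`, which keeps the likelihood finite
and decreasing so the search cannot run away along a floored plateau.

**Pooling.** Experiments whose `Nt` values all differ by less than
2-fold (and share a plating fraction) are combined: counts are
concatenated and the pooled `Nt` is the member mean. Incompatible sets
are kept separate and flagged for independent estimation.

## From phenotypic to per-base-pair rates

A resistance reporter only reveals mutations that inactivate its
protein. Chain-terminating substitutions (the 3 stop codons of 64) are
assumed fully detectable, which anchors the correction for undetected
substitutions:

```
C   = (64/3) * B_CT / B                 (substitutions only)
C'' = [(64/3) * B_CT + I] / M           (substitutions + indels)
tau = T / C''                           (effective target size, bp)
mu_b = mu_T * C'' / T
```

where `B` counts base substitutions (`B_CT` chain-terminating), `I`
indel and complex events, `M = B + I` scored events, and `T` the
reporter length. With the reference mutator spectrum — 442
substitutions of which 101 chain-terminating, plus 42 indels, from 484
mutants on a 1773-bp reporter — this gives `C = 4.87` and
`tau = 391` bp:

```{r}
cf <- correction_factors(spectrum_counts(B_CT = 101, B_mis = 341, I = 42),
                         target_locus("reporter", T = 1773))
cf
```

Two details of the counting convention matter. `M` counts mutation
*events*, not clones: a clone carrying two scored mutations contributes
both (442 + 42 = 484). Silent substitutions cannot appear among
resistant isolates; if present in input they are excluded from `B`
with a warning. The printed combined factor for this spectrum is 4.53
while the arithmetic gives 4.5386 (which rounds to 4.54) — the source
apparently truncates — so comparisons are made on `tau` (391), which is
stable to this rounding.

For targets where resistance is known to arise only at enumerated
codons, the effective target size is supplied directly
(`allele_target_size(5, 4) = 20` bp for a tetraploid cell line), and
`mu_b = mu_T / tau`. Cross-locus comparisons can apply an intrinsic-rate
multiplier (1.8 to place URA3-derived rates on the CAN1 scale); this is
kept out of `per_bp_rate()` and applied explicitly by
`robustness_table()`, whose bundled presets carry the diploid-yeast
(C'' = 6.79, T = 804) and mouse-ouabain (tau = 20) constants as opaque
published values, not recomputed here.

## Repair-pathway arithmetic

If deleting a repair pathway raises the rate `F`-fold, the pathway was
correcting a fraction `1 - 1/F` of the errors it sees:

```{r}
repair_efficiency(157)   # MMR-scale fold effect
combined_fidelity(157, 163)
```

Proofreading and MMR act in series, so their folds multiply. Rates of
inviable double mutants are predicted as the viable single-mutant rate
times the average fold of the missing pathway
(`predict_double_mutant_rate(135e-7, 157)` = 2e-3 to one significant
figure). Growth capacity is graded `+++ / ++ / + / -` with band edges
at 5e-5, 1e-3 and 2e-3 mutants per cell division; the first two edges
are observed transitions, while the `+`/`-` edge is a design choice
placed where the weakest predicted-inviable genotypes sit (no edge is
printed in the source data).

## The extinction model

The genome model has `G` genes (default 6000), a fraction `f` of them
essential (default 1/6), and a per-gene inactivation rate `mu` per
division, so each daughter cell acquires `Poisson(f G mu)` essential
hits. A hit daughter arrests: it persists and counts toward colony
size, but never divides — the source observations report arrest, not
lysis. A colony starts from one dividing founder; each generation every
dividing cell is replaced by two daughters. The dividing lineage is a
Galton-Watson process with offspring `Binomial(2, s)`,
`s = exp(-f G mu)`, so extinction probability solves
`q = (1 - s + s q)^2` and survival is positive exactly when `s > 1/2`,
i.e. `mu < ln 2 / (f G)` (6.9e-4 for the defaults — the same order as
the observed ~1e-3 threshold, reached independently).

```{r}
gm <- genome_model(per_gene_rate = 1e-3)
expected_inactivations(gm)
gw_survival_analytic(gm)
```

`critical_rate()` bisects `mu` for the simulated probability of forming
a visible colony (default 1e5 cells, the plating scale at which extinct
genotypes yield no colonies) crossing 1%.

Two numerical points. First, the simulator draws arrest counts as
`Binomial(2D, 1-s)` per generation plus exact zero-truncated Poisson
hit counts for the arrested daughters — distributionally identical to
per-daughter Poisson draws at O(arrested) cost. Second, at the exact
critical point the analytic survival is 0, but a finite visibility
threshold `N` is still reached by transient excursions with probability
`~ sqrt(2/(pi sigma^2 N))` (the critical total-progeny tail); tests
comparing simulator to oracle account for this known finite-size term
at the critical point only.

Deliberately not modeled: fitness decay from non-essential mutation
load (available as an optional division-time multiplier, off by
default), checkpoint signaling, cell-cycle stage, diploid buffering,
and the emergence of antimutator escape clones — the escape-mutant
frequency is not quantified in the source data, so simulating it would
be invention.

## What the synthetic generator does and does not establish

`simulate_cultures()` draws Poisson mutation events and clone sizes
`floor(1/U)` (exactly the `1/(j(j+1))` law), then thins binomially —
i.e., it generates from the same family the estimator assumes, with the
finite-culture cap `n_final` as the only truncation. Recovery and
coverage tests on these data therefore establish *self-consistency*
(correct likelihood, optimizer, and interval construction), not
robustness to real-world violations: phenotypic lag, differential
mutant fitness, cell death, or plating artifacts are all absent by
design. Default designs mirror the two laboratory protocols (9 excised
colonies with up to 1:200 dilution; 12 parallel 100-cell cultures with
9 plated).

`simulate_spectrum()` plants one event per clone with sites sampled
uniformly among positions compatible with the requested effect on a
bundled 1773-bp synthetic open reading frame (generated once with a
fixed seed; no real gene sequence is used or required). Indel
placements inside homopolymer runs are ambiguous; `diff_sequences()`
reports the leftmost placement, and tallies — the quantities that feed
the corrections — are invariant to this choice.

## Reproducibility and limitations

All stochastic entry points take explicit seeds, and every simulation
in the test suite runs at a fixed seed. The likelihood-ratio intervals
achieve 95% +/- 2% empirical coverage at `m` between 0.5 and 8 with 9
cultures (verified at 1000 datasets per point); coverage degrades for
`m` well outside the range where fluctuation assays are informative.
Strain-by-strain published rates bundled in `inst/extdata` are
transcriptions of printed, rounded values used as fold-ratio inputs and
formatting fixtures — the underlying raw colony counts are unpublished,
so those rates are not reproducible from data and are not treated as
acceptance quantities. Phenotypic-lag and differential-fitness variants
of the fluctuation model, Bayesian estimation, and multi-locus joint
fits are out of scope.
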