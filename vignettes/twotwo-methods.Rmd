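---
title: "Divergence-time estimation from 2+2 sample configurations: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divergence-time estimation from 2+2 sample configurations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twotwo)
```

## The estimation problem

Two populations diverged from a common ancestral population; we sample one
diploid individual from each and ask when the populations split, how much
genetic drift each branch accumulated, and how large the ancestral population
was. With two gene copies per population, every bi-allelic site with a known
ancestral allele falls into one of nine sample configurations
$O_{i,j}$, $i,j \in \{0,1,2\}$, counted over all $m_{tot}$ examined sites
(monomorphic sites included — they calibrate the mutational scale).

## Model and assumptions

The model is deliberately minimal:

* **No migration after the split**, and a panmictic ancestral population.
* **Arbitrary daughter demography.** Nothing is assumed about population
  size changes within the daughter branches: each branch is summarized by a
  drift parameter $\alpha_k$ (probability the sampled pair does *not*
  coalesce before the split) and $\nu_k$ (mean within-branch coalescence
  time when it does). This is why the method tolerates daughter bottlenecks
  and growth that break many SFS-based methods.
* **Independent sites, infinite sites, small per-branch mutation
  probability.** The probability of observing a configuration is then linear
  in branch lengths: $\mu \times$ (expected length of the branches producing
  it). No Poisson correction is applied; the forward maps refuse parameter
  sets whose polymorphic probabilities leave $[0,1)$, and the per-genealogy
  converter refuses genealogies with $\mu \times$ total length $> 0.1$.
* **Separate split times $t_1$, $t_2$ per branch.** For contemporaneous
  samples they estimate the same quantity (a useful internal consistency
  check); for a modern–ancient comparison they differ by design, and the
  modern branch's estimate is the robust one when the ancient sample carries
  residual damage (singleton-type errors in individual 1 enter only
  $m_{1,0}$ and hence only $\hat T_1$ and $\hat V_1$).

The ancestral population enters through
$\tau_k = \mu E[T4_k]$, the mutation-scaled expected time a four-lineage
coalescent started at the split spends with $k$ lineages. The **TT**
estimator assumes a constant ancestral size, forcing
$(\tau_2,\tau_3,\tau_4) = (\theta, \theta/3, \theta/6)$ with
$\theta = \mu N_A$ ($N_A$ in chromosomes) and making the seven polymorphic
moment equations exactly invertible; because the multinomial cell
probabilities are freely parameterized by the model in this regime, the
moment solutions are also maximum-likelihood estimates. The **TTo** variant
replaces the constant-size assumption by externally obtained drift
parameters: ascertaining sites whose derived allele occurs in an outgroup
removes all new-mutation terms, identifies $\alpha_1, \alpha_2$ on their
own, and the general model then yields $\tau_2$, $\tau_3$ and
$B_k = \mu t_k + \tau_4$, with $\tau_4$ approximated by
$\frac{3}{2}\tau_3^2/\tau_2$ (exact when the ancestor is constant, since
$E[T4_3]/E[T4_2] = 1/3$ and $E[T4_4]/E[T4_3] = 1/2$).

## Parameters, units, defaults

| quantity | units | default | why |
|---|---|---|---|
| `mu` | mutations / site / generation | 1.25e-8 | current consensus human rate; override everywhere |
| `G` | years / generation | 30 | conventional human generation time |
| `alpha1`, `alpha2` | probability | — | drift; 1 = no drift |
| `T`, `V`, `theta`, `tau` | mutation units | — | internal scale; divide by `mu` for generations |
| `N_A` | chromosomes internally | — | reported to users as diploids, $\hat\theta/(2\mu)$ |
| block size | base pairs | 5 Mb | long enough to decorrelate linkage for the jackknife |

Population sizes are *diploid individuals* in every user-facing interface
(simulator configurations, reported $\hat N_A$); the chromosome count
$N = 2N_{dip}$ appears only inside the coalescent mathematics.

## Numerical and design choices

* **Negative estimates are reported, never clamped.** A negative $\hat T$ or
  $\hat V$ is a diagnostic of model violation (e.g. a severe ancestral
  bottleneck makes $\tau_4 \ll \theta/6$); estimators attach flags
  (`negative_T1`, `alpha1_gt_1`, ...) instead of truncating.
* **Degenerate cells give structured errors.** $m_{1,1} = 0$ aborts with
  "insufficient shared polymorphism"; a non-positive $V$-denominator
  ($2m_{2,1} \le m_{1,1}$, the $\alpha \to 1$ boundary where $\nu$ is
  unidentifiable) returns `NA` for that component with a warning and leaves
  the rest intact; $\hat\tau_2 \le 0$ suppresses only the $\tau_4$-dependent
  outputs.
* **The $V$ estimators are pinned by the round-trip identity**
  $\hat V_1 = \hat p_{1,0}/2 + (\hat p_{1,2} - 2\hat\alpha_1\hat
  p_{2,0})/(2(1-\hat\alpha_1))$, chosen so that estimation composed with the
  forward map is the exact identity on expected counts — the property the
  test suite sweeps over random parameter sets.
* **Ascertained drift estimator grouping.** We use
  $\hat\alpha_1^* = 2(m^*_{1,0}+m^*_{1,2}+m^*_{1,1}) /
  [2(m^*_{1,0}+2m^*_{2,0}+m^*_{2,1})+m^*_{1,1}]$: expanding the ascertained
  model, the denominator has expectation $b_1 + \frac43 b_2 + b_3$
  independently of drift, and this numerator is the unique matching form
  with expectation $\alpha_1(b_1 + \frac43 b_2 + b_3)$ — other groupings of
  the same cells are not consistent estimators (simulation: they converge to
  0.51 when the truth is 0.745).
* **Two algebraic variants** exist for $\hat\tau_2^*$ and $\hat\tau_3^*$
  (one through $m_{2,1}$, one through $m_{1,2}$); they agree exactly under a
  symmetric history, and their average is reported with both variants
  retained as a diagnostic of asymmetry.
* **Ascertainment rule**: a site counts as "derived in the outgroup" with
  one or two copies (`rule = "any"`, the default); `rule = "fixed"`
  (homozygous derived) is available for stricter schemes. The choice trades
  ascertained-site count against contamination by lineage sorting.
* **Tree-ness verdicts** are left to the user: the primitive outputs are
  $Y_1$, $Y_2$ and their jackknife Z-scores; $|Z| > 3$ is a reasonable
  working threshold, mirroring D-statistic practice.
* **Jackknife weighting** follows the weighted delete-one jackknife with
  block site totals as weights, which reduces exactly to the classical
  delete-one formula for equal blocks; leave-one-out replicates on which a
  statistic is undefined are dropped (with a warning) and the weights
  renormalized over the usable blocks.

## What the simulator emulates — and what it does not

`simulate_counts()` draws `R` independent genealogies of the 2+2 sample
(plus an outgroup pair when configured) under a two-population split with
piecewise-constant ancestral size (schedule, backwards from the split:
$N_{anc}$ for `phi` generations, $\lambda N_{anc}$ for `tau_b`, then
$N_{anc}$) and an optional single admixture pulse (each lineage in the
recipient daughter jumps to the donor with probability `gamma` at time
`delta`). Each genealogy contributes $\mu \times$ branch length to every
configuration; the average over genealogies is the per-site distribution,
which is either scaled by `m_tot` (`mode = "expected"`) or sampled
multinomially. Under the independent-sites assumption this is statistically
equivalent to simulating one genealogy per site, at a tiny fraction of the
cost, which is what makes genome-scale `m_tot` and $R = 10^5$–$10^6$
genealogies cheap. The compiled core uses R's RNG, so a single `set.seed()`
(or the `seed` field of the configuration) makes every output bit-for-bit
reproducible; a pure-R single-genealogy implementation
(`simulate_genealogy()`) serves as an independent cross-check in the tests.

Deliberately **not** emulated: recombination (sites are exchangeable, so
linkage affects only sampling variance — which is exactly what the block
jackknife absorbs on real data), continuous migration (only a pulse),
sequencing error, ancestral-state misassignment, and more than three
populations. Passing tests on simulated data therefore validate the
estimation mathematics and the robustness claims about demography, not
robustness to data-quality artifacts; on real genomes the polarization and
filtering steps dominate the error budget and must be handled upstream.

Monte-Carlo scale: the validation suite and the reproduction script use
$R = 2\times10^5$ to $10^6$ genealogies per scenario, giving sub-percent
standard errors on every configuration probability (the simulator warns when
any probability's MC standard error exceeds 1% of its value).

## Behavior under model violations

Three behaviors, all reproduced by the test suite from fresh simulations:

* **Ancestral bottlenecks bias TT downwards.** A bottleneck shortly before
  the split shrinks $\tau_3, \tau_4$ relative to $\tau_2$, so the implied
  constant-ancestor correction over-subtracts; the bias grows with
  bottleneck duration. The TT split-time estimate on exact expected counts
  is a deterministic function of the ancestral $\tau$-moments alone (the
  drift parameters cancel), which is why the daughter sizes barely matter in
  these scenarios.
* **TTo with externally known drift removes most of that bias**, because it
  never assumes a $\tau$-ratio; only the final $\tau_4$ approximation keeps
  a residual.
* **Recent full replacement of one daughter by the other collapses the
  effective split toward zero.** With all sizes equal this limit is exactly
  a single constant-size population, where the TT estimator is provably
  unbiased at $\hat t = 0$ (the single-population four-sample spectrum
  satisfies the constant-model equations with $t = 0$); any nonzero estimate
  in this scenario must come from size differences between the merged
  daughters and the ancestral population, a sensitivity worth keeping in
  mind when interpreting estimates between heavily admixed populations.

## Known limitations

* $\hat V$ (within-branch coalescence time) is noisy whenever drift is weak
  ($\alpha$ near 1): its influence on the probabilities carries a
  $(1-\alpha)$ factor, so the data barely constrain it.
* The TTo $\hat V^*$ formula is exact only under a constant ancestral
  population; under other histories it absorbs a residual
  $\propto \tau_2 - 3\tau_3$.
* The $\tau_4$ approximation transfers any misfit directly into the split
  times, since $\hat T_k = \hat B_k - \hat\tau_4$.
* Outgroup ascertainment assumes a strictly bifurcating topology; gene flow
  between the outgroup lineage and one daughter shifts $Y_2$ away from zero
  (sign indicating the recipient) and invalidates the drift estimates —
  test first, estimate second.
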