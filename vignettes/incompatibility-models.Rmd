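---
title: "Models of genetic incompatibility accumulation under partial selfing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models of genetic incompatibility accumulation under partial selfing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selfersim)
```

## The question

Reproductive isolation between allopatric populations builds up through
the fixation of mutations that are harmless (or beneficial) at home but
incompatible with the genetic background of a diverging population.
`selfersim` models how the mating system — specifically the selfing
rate $\sigma$ — changes the pace of this process for three canonical
incompatibility types:

* **underdominant** mutations (single locus, heterozygote fitness
  $1 - s_u$, derived homozygote $1 + s$): a one-locus fitness valley;
* **compensatory** pairs (each derived allele deleterious alone,
  jointly neutral): a two-locus valley;
* **Bateson–Dobzhansky–Muller incompatibilities** (BDMi: derived
  alleles harmless alone, deleterious together): no valley within the
  focal population, but segregating variants can meet and be selected
  against before either fixes.

A single population of $N$ hermaphrodites is simulated or analysed; the
quantity of interest is the mean number of generations $T$ until the
first incompatibility allele (or haplotype) fixes, decomposable as
$T = T_\text{wait} + T_\text{fix}$.

## Mating system

Partial selfing enters the models in three ways.

1. **Homozygosity.** At equilibrium the fixation index is
   $F = \sigma / (2 - \sigma)$; heterozygote frequencies are reduced by
   $1 - F$.
2. **Drift.** The effective size is $N_e = N / (1 + F)$ (Pollak), so a
   fully selfing population has half the effective size of an
   outcrossing one.
3. **Effective recombination.** Recombination only matters in
   heterozygotes, so selfing suppresses effective shuffling.

`mating_system(N, sigma)` carries $N$, $\sigma$, $F$ and $N_e$.

## Deterministic core

The two-locus state is the vector of the ten genotype classes
$G_{ij}$, $i \le j$, over the four haplotypes A1B1, A1B2, A2B1, A2B2.
The cis (`G14`) and trans (`G23`) double heterozygotes have equal
fitness but different gamete output, so they are tracked separately.
One generation is

`meiosis()` → `syngamy()` → `mutate_genotypes()` → `select_genotypes()`,

all exact recursions on the frequency simplex. Two derivation choices
deserve a note:

* The selfed-offspring transition is derived from Mendelian gamete
  segregation of each parental genotype (each selfed offspring is the
  union of two independent gametes of one parent). The resulting
  transition is column-stochastic; frequency conservation is asserted
  to $10^{-12}$ in the tests at random states.
* The single-locus allele-frequency change used throughout is
  $\Delta x = x(1-x)\left[(1-F)\{(2s_u+s)x - s_u\} + F s\right]$,
  obtained from the genotype frequencies at inbreeding equilibrium,
  with weak selection and $\bar W \approx 1$. This form reproduces the
  classical outcrossing limit $s_u x(1-x)(2x-1)$ at $F=0$, $s=0$, the
  full-selfing limit $s\,x(1-x)$, and the threshold selfing rate
  $\sigma_\text{lim} = 2 s_u/(s + 2 s_u)$ above which a rare mutant is
  positively selected; it is also the drift term that makes the
  diffusion approximation agree with the exact finite-$N$ chain (below).
  Mutation is applied at the genotype level immediately after syngamy;
  this is equivalent to mutating gametes up to $O(\mu^2)$ and keeps the
  selfed-offspring transition in its exact Mendelian form.

## Diffusion predictions

`fixation_probability_underdominant()` evaluates
$P_\text{fix} = \int_0^{p} G(x)\,dx \big/ \int_0^1 G(x)\,dx$ with
$G(x) = \exp\!\left(-\int_0^x 2M/V\right)$, $M = \Delta x$,
$V = x(1-x)/2N_e$, $p = 1/2N$. Because $M/V$ is polynomial, the inner
integral is closed-form; the outer integrals use adaptive quadrature at
relative tolerance $10^{-8}$. Conditional spread times use the
Kimura–Ohta sojourn integrals on a grid clamped to
$[1/4N,\,1 - 1/4N]$ (4001 points), which is accurate to well under a
percent at $N = 1000$ and a few percent at $N = 30$.

The package's independent oracle for these formulas is
`wf_exact_fixation_prob()`: the full absorbing Markov chain on genotype
compositions $(n_{12}, n_{22})$ of $N$ diploids, solved by dense linear
algebra. It involves no diffusion or weak-selection approximation and
is feasible up to $N \approx 60$. At $N = 50$ the diffusion and the
chain agree within a few percent across the
$\sigma \times s_u \times s$ grid used in the tests.

Closed-form time approximations:

* **Gamma-distributed underdominant effects.** If $4 N s_u \sim$
  Gamma(mean $\gamma$, shape $\beta$), the fixation rate relative to
  outcrossing is $(1-\sigma)^{-\beta}$ and the waiting-dominated time
  ratio is $(1-\sigma)^{\beta}$, independent of $\gamma$. The exponent
  in the diffusion kernel depends on the product
  $4 N s_u (1 - \sigma)$ alone, which is where this law comes from;
  it holds when $\gamma(1-\sigma)$ is large compared with the width of
  the nearly-neutral window ($4Ns_u \lesssim 10$). At $\gamma = 100$,
  $\sigma = 0.9$ that product is 10, so a deviation of order tens of
  percent is expected there — visible in the validation runs and
  inherent to the approximation, not to the engines.
* **Compensatory, strong effects, fully linked, neutral diagonal**
  ($r = 0$, $k_c = 0$, $N_e s_c \gg 1$):
  $T_{0,0} = \{h_c(1-F) + F\}\, s_c / (2\mu^2)$. Single mutants are
  held at mutation–selection balance $\mu / h_\text{eff} s_c$ with
  $h_\text{eff} = h_c(1-F)+F$; a second mutation on such a haplotype
  creates the neutral double mutant, which fixes with probability
  $1/2N$. The $F=1$ to $F=0$ ratio is $1/h_c$, and the time increases
  with $\sigma$ for all $h_c < 1$.
* **Small $r$ or selected diagonal**: $T_{r,k} = T_{0,0} \times
  \sqrt{\pi}\,e^R\,\mathrm{erf}(\sqrt R)/(2\sqrt R)$ with
  $R = N(1-\sigma)(r + h_c k_c s_c)$. The factor tends to 1 as
  $R \to 0$ and grows roughly like $e^R$: recombination and
  double-heterozygote selection shut the diagonal path, and selfing
  (through $1-\sigma$) rescues it. The $\sqrt{\cdot}$ placement is
  fixed by the $R \to 0$ limit and by monotonicity in $\sigma$, both
  asserted in tests.
* **Neutral BDMi**: at low mutation rate $T = 1/2\mu + 4N_e$; under
  recurrent mutation the single-locus Kimura time
  $T_K = 4N_e\,(\gamma_E + \psi(4N_e\mu))/(4N_e\mu - 1)$ (removable
  singularity $4N_e \pi^2/6$ at $4N_e\mu = 1$) gives the corrected
  two-type reference $T = T_K - 1/2\mu$, the neutral baseline for all
  BDMi comparisons.
* **Weak compensatory effects** fix in two steps with reversed
  dominance: a $(-s_c, h_c)$ fixation followed by a
  $(+s_c, 1-h_c)$ fixation in the rescaled background
  (`compensatory_time_weak()`). Both steps use the per-locus mutation
  rate as supplied; no factor for two mutational targets is applied,
  matching the single-path reading of the two-step decomposition.

## Stochastic engines

Three engines share the life cycle and differ in state representation:

* `run_single_locus()`: three genotype classes, multinomial (or
  Dirichlet-multinomial) resampling of $N$ individuals each
  generation; C++ inner loop driven by R's RNG, so `set.seed()` gives
  byte-identical replicate streams. Per-replicate seeds are
  `seed + replicate - 1`.
* `run_two_locus()`: the ten genotype classes. Stopping rules: all
  individuals A2B2/A2B2 (compensatory) or either derived allele fixed
  (BDMi); fixation is detected by exact integer allele counts, never a
  frequency tolerance. Starts monomorphic ancestral with recurrent
  irreversible mutation, matching a population that has not yet begun
  to diverge.
* `run_multilocus()`: individual-based, diploid bit-vector genomes of
  $L$ loci; selfing with probability $\sigma$, otherwise two parents
  drawn with replacement; per-junction crossovers at rate $r$ (counts
  drawn from the exact binomial, positions uniform without
  replacement — equivalent to independent junctions); per-locus
  Bernoulli mutation; offspring viability selection by accept–reject
  with multiplicative fitness over loci (underdominant) or disjoint
  interacting pairs (compensatory/BDMi). Viability accept–reject on
  each offspring gives exactly the same offspring distribution as the
  frequency-class engines' selection-then-multinomial step, which is
  why the $L = 2$ cross-engine distributions match (asserted by a KS
  test). The engine uses an internal xoshiro256++ generator seeded
  from R's RNG.

**Drift and background selection.** Background selection is not
modelled mechanistically. Instead the drift step can use a
Dirichlet-multinomial whose concentration $\alpha$ inflates the
variance of genotype-frequency changes by $(N+\alpha)/(1+\alpha)$,
i.e. $N_e = N(1+\alpha)/(N+\alpha)$; `dirichlet_alpha_for_Ne()` inverts
this exactly. Profiles of the $N_e$ reduction with selfing are exposed
as configurable curves (`bgs_ne_profile()`): linear $1 - c\sigma$,
curved $1 - c\sigma^\kappa$ ($\kappa > 1$: only high selfing is
penalised, the high-recombination regime), or a user table. Defaults
$c = 0.6$, $\kappa = 6$ put the full-selfing multiplier at 0.4 — a
configuration choice of the order of strong background selection, not
a fitted value. Because the mating scheme already produces the organic
$1/(1+F)$ reduction by itself, $\alpha$ by default encodes only the
*extra* reduction; `bgs_drift_model(..., convention = "total")` treats
the profile as total $N_e/N$ instead, since published $N_e(\sigma)$
curves may include the selfing reduction. The Dirichlet perturbation is
applied to the post-selection genotype frequencies each generation.

**Conflict selection.** `conflict_selection()` implements
$s = s_0(1-\sigma)$, a phenomenological stand-in for sexual or genomic
conflicts that vanish under selfing; it is resolved at run time from
the population's selfing rate when a `bdmi_model()` carries `s0`.

## Censored fixation times

Long runs are censored at `max_generations`. Following standard
practice for gamma-like fixation-time distributions, the corrected mean
is obtained by fitting a gamma distribution by maximum likelihood with
censored observations contributing survival terms
(`censored_gamma_mean()`, backed by `fitdistrplus::fitdistcens` with a
method-of-moments start on values rescaled by the naive mean). With no
censoring the gamma MLE matches the first moment exactly, so the sample
mean is returned; with censoring the corrected mean is always at least
the naive mean. Recovery of a known mean from a heavily censored
synthetic sample (shape 2, 30% censored, $n = 2000$) is within 10% in
the tests.

## Validation experiments and problem sizes

The acceptance-level checks rerun compact versions of the headline
designs. The full-scale parameter sets of the corresponding published
experiment designs are kept unchanged in `experiment_grid()`; the validation runs scale them
down as follows, chosen a priori from the package's own analytics
rather than tuned to outcomes:

* **Gamma-DFE law** (`dfe_ratio_experiment()`): $L = 100$, $N = 1000$,
  $\gamma = 100$, $\beta \in \{0.5, 1\}$,
  $\sigma \in \{0, 0.5, 0.9\}$, 100 replicates per cell, fresh
  architecture per replicate. The desk-scale $\mu = 4\times10^{-6}$
  was chosen so that the analytic waiting time
  $1/(2NL\mu\,\overline{P}_\text{fix})$ exceeds the conditional spread
  time by an order of magnitude at $\sigma = 0$ (the regime in which
  the $(1-\sigma)^\beta$ law is derived) while a full run stays within
  minutes. Observed ratios are compared with $(1-\sigma)^\beta$
  through bootstrap 95% CIs.
* **Compensatory orderings**
  (`compensatory_ordering_experiment()`): $N = 200$, $s_c = 0.05$,
  $h_c = 0.5$, $\mu = 10^{-3}$, threshold $4\times10^4$ generations,
  80 replicates. These keep $N_e s_c = 10$ (strong-effect regime) and
  the single-mutant balance frequency at 0.04. The $k_c = 1$ and
  $r = 0.1$ cells are expected to censor almost always — their
  predicted times exceed the threshold by orders of magnitude — and
  enter the orderings at the censoring value, which only weakens the
  contrast being asserted.
* **Conflict reversal** (`conflict_experiment()`): $N = 1000$,
  $4N\mu = 1$, $s_0 = 8\times10^{-3}$ so that $N s_0 = 8 > 4$, 200
  replicates per cell, no background selection (the reversal direction
  does not require it at this selection strength).

## What the synthetic data do and do not show

All inputs are model-generated; there is no external data. The
generators emulate idealised Wright–Fisher populations: constant census
size, non-overlapping generations, a fixed selfing rate, irreversible
biallelic mutation, free or fixed linkage, and (for the multilocus
engine) equal per-locus mutation rates with quenched per-locus effects.
Passing tests therefore demonstrate internal consistency of the
implementation with the stated models and approximations — not that
real populations behave this way. Demography, selfing-rate evolution,
standing variation at divergence, gene flow, heterosis and hybrid-zone
dynamics are all outside the models' scope.

## Numerical choices and degenerate inputs

* Frequency vectors are validated to sum to 1 within $10^{-8}$ and
  mapped through exact recursions; no renormalisation is hidden.
* Quadrature: relative tolerance $10^{-8}$; sojourn grids clamp to
  $[1/4N, 1-1/4N]$.
* `dirichlet_alpha_for_Ne(N, N)` returns the multinomial sentinel
  (`Inf`) rather than a huge concentration.
* Fitness matrices must be strictly positive; selection normalises, so
  absolute scale is irrelevant (asserted by a scaling-invariance test).
* Fixation detection uses exact integer counts; censored replicates
  report `generations = max_generations` with a flag.
* `kimura_recurrent_time()` switches to the analytic limit within
  $10^{-8}$ of $4N_e\mu = 1$.
* Validity guards warn (never silently return nonsense) outside the
  stated regimes: $N_e s_c > 5$ for the weak-compensatory
  approximation, $\mu \ge 0.1$ for genotype-level mutation,
  $4N_e\mu \ge 1$ for the low-mutation BDMi form.

## Known limitations

* The diffusion fixation-time integrals lose accuracy below
  $N \approx 30$ (boundary clamping); the exact chain covers that
  range instead.
* The multilocus engine caps $L$ at 1024 loci and models no
  interference in crossover placement.
* The Dirichlet-multinomial device reproduces the *variance* of a
  reduced-$N_e$ population, not higher moments of linked selection.
* Two-locus analytics for BDMi fixation times do not exist (only the
  neutral reference); comparisons there are simulation-based.
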