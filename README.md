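# selfersim

Population-genetics models of how genetic incompatibilities accumulate
in allopatric populations that reproduce by partial self-fertilisation.

Whether selfing lineages speciate faster or slower than outcrossing
ones depends on how the mating system interacts with drift, selection
and linkage during the fixation of incompatibility mutations.
`selfersim` is for theoretical and evolutionary population geneticists
who want to compute or simulate that process explicitly, for three
canonical architectures of reproductive isolation:

* **underdominant** mutations — genotype fitnesses
  $(1,\; 1 - s_u,\; 1 + s)$: a single-locus fitness valley;
* **compensatory** mutation pairs — $w_{11} = w_{44} = 1$,
  $w_{22} = w_{33} = 1 - s_c$, single heterozygotes $1 - h_c s_c$,
  double heterozygotes $1 - h_c k_c s_c$: a two-locus valley whose
  diagonal path is tunable;
* **Bateson–Dobzhansky–Muller incompatibilities (BDMi)** — derived
  alleles neutral or beneficial alone ($s$, $h$), deleterious together
  ($s_b$, $h_b$, $k_b h_b$), optionally with "conflict" selection
  $s = s_0(1 - \sigma)$ that vanishes under selfing.

Selfing at rate $\sigma$ enters through Wright's fixation index
$F = \sigma/(2-\sigma)$, Pollak's effective size $N_e = N/(1+F)$, and
the exact two-locus genotype recursions for meiosis, selfed and
outcrossed syngamy, irreversible mutation and selection
($G^{sel}_{ij} = w_{ij} G_{ij} / \sum w G$). On top of the
deterministic core the package provides:

* diffusion-based fixation probabilities
  $P_\text{fix} = \int_0^{1/2N} G / \int_0^1 G$ with
  $G(x) = \exp(-\int 2M/V)$, conditional sojourn times, and closed-form
  fixation-time approximations (gamma-DFE scaling $(1-\sigma)^\beta$;
  compensatory $T_{0,0} = \{h_c(1-F)+F\}s_c/2\mu^2$ with its
  $\sqrt\pi e^R \mathrm{erf}(\sqrt R)/2\sqrt R$ recombination factor;
  Kimura's recurrent-mutation time and the neutral BDMi reference);
* an exact finite-$N$ absorbing-Markov-chain solver used as the
  independent oracle for the diffusion results;
* stochastic Wright–Fisher engines in C++: single-locus and two-locus
  genotype-class simulators with multinomial or Dirichlet-multinomial
  drift (the latter emulates background selection by targeting any
  $N_e \le N$), and an individual-based multilocus simulator with
  bit-vector genomes, recombination and per-locus gamma-distributed
  underdominant effects ($4Ns_u \sim$ Gamma($\gamma$, $\beta$));
* right-censored gamma maximum-likelihood correction of mean fixation
  times, preset experiment grids mirroring the published figure
  designs, and self-describing TSV output.

## Worked example

Time to fixation of a pair of strongly deleterious compensatory
mutations ($N_e s_c = 10$) in an outcrossing population, fully linked
loci and a neutral diagonal path, against the analytic approximation:

```r
library(selfersim)
m  <- compensatory_model(s_c = 0.05, h_c = 0.5, k_c = 0)
ms <- mating_system(200, 0)
print(ms)
#> Mating system: N = 200, sigma = 0 (F = 0, Ne = 200)
fitness_compensatory(m)
#> Two-locus fitness matrix (w_ij):
#>   G11   G12   G13   G14   G22   G23   G24   G33   G34   G44
#> 1.000 0.975 0.975 1.000 0.950 1.000 0.975 0.950 0.975 1.000

cfg <- sim_config(m, ms, mu = 1e-3, r = 0, max_generations = 4e4,
                  replicates = 40, seed = 1)
rec <- run_two_locus(cfg)
sm  <- replicate_summary(rec, censor_limit = 4e4)
sm$mean
#> [1] 5170
compensatory_time_strong_linked(m, 200, 0,    1e-3)  # T00, sigma = 0
#> [1] 12500
compensatory_time_strong_linked(m, 200, 0.99, 1e-3)  # T00, sigma = 0.99
#> [1] 24752.48
```

The 40 simulated replicates cross the valley in about 5,200
generations on average; the analytic $T_{0,0}$ gives the right order
of magnitude (it is an asymptotic mutation-limited approximation and
overshoots at this mutation rate) and, more importantly, the right
direction of the mating-system effect: at $\sigma = 0.99$ the predicted
time roughly doubles, because a selfing population cannot exploit the
neutral diagonal path through the double heterozygote. Simulating the
same configuration at `mating_system(200, 0.99)` confirms the slowdown
(mean ≈ 15,000 generations with occasional censoring).

The same machinery runs from the shell:

```sh
exec/selfersim simulate compensatory --N 200 --sigma 0 --mu 1e-3 --r 0 \
  --sc 0.05 --hc 0.5 --kc 0 --replicates 40 --max-gen 40000 --seed 1 \
  --out comp.tsv
exec/selfersim predict compensatory --N 200 --mu 1e-3 --sc 0.05 --out pred.tsv
```

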