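---
title: "Simulating pseudo-overdominance in diploids and autotetraploids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating pseudo-overdominance in diploids and autotetraploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(podsim)
```

## The question

Pseudo-overdominance (POD) arises when recessive deleterious mutations
accumulate on complementary haplotypes in a low-recombination region: each
haplotype carries a heavy load, but heterozygotes mask all of it, so apparent
heterozygote advantage maintains the haplotypes as balanced polymorphisms.
Polyploids magnify the masking — at a haplotype frequency of 0.4 a diploid
offspring is fully homozygous with probability $p^2 + (1-p)^2 = 0.52$, a
tetraploid with probability $p^4 + (1-p)^4 \approx 0.16$ — so tetrasomic
autotetraploids should enter POD over a wider slice of parameter space than
diploids, and sustain it at much higher fitness. `podsim` is a forward
Wright–Fisher simulator built to map that parameter space and to decide, per
run, whether POD dynamics are operating.

## The model

**Demography and genome.** A constant-size population of $N$ individuals,
each carrying a single chromosome of $L$ base pairs at ploidy 2 or 4.
Founders are mutation-free and there is no burn-in: the object of study is
the approach to equilibrium itself, matching the bottleneck of a freshly
formed polyploid. Every generation, $N$ offspring are produced; each
offspring draws two parents independently with replacement, with probability
proportional to fitness (selfing occurs at the incidental rate of about
$1/N$). The mean fitness of the $2N$ drawn parents is recorded separately
from the population mean — their divergence is one of the POD signatures.

**Meiosis.** Diploid meiosis recombines the two homologues and transmits one
product. Tetraploid meiosis is tetrasomic with strict bivalent pairing: the
four homologues form two bivalents, all three pairings equally likely;
recombination happens within each bivalent; the gamete receives one product
per bivalent. Because the two gamete chromosomes always descend from
different bivalents, double reduction is impossible. With no recombination
this scheme transmits $k$ of $d$ mutant copies with hypergeometric
$(4, d, 2)$ probabilities — the package's gamete-distribution oracle, and the
source of the analytic results above: among crosses between heterozygous
tetraploid parents the fully homozygous offspring fraction peaks at 25% for
triplex × triplex, against 50% for a diploid heterozygote cross.

**Mutation and recombination.** Crossover counts are Poisson with mean
$\rho(L-1)$, breakpoints uniform on inter-site boundaries, no interference
or gene conversion — the simplest model consistent with a constant per-bp
rate. New mutations arrive per chromosome as Poisson($\mu L$) at uniform
positions. Bookkeeping is infinite-alleles: every mutation event is a
distinct allele even at an occupied site, and homozygosity is judged per
allele id, so two hits at one position never fake a homozygote.

**Fitness.** Multiplicative across mutations:
$w = \prod_i (1 + s_i)$ over homozygous mutations and $(1 + h_i s_i)$ over
any partial dosage, clamped at zero. The main simulations use constant
$s \le 0$ with $h = 0$ (fully recessive). The empirical alternative draws
$|s| \sim \mathrm{Gamma}(\alpha = 0.16,\ \beta = 0.0092)$ (read as shape and
scale, mean $|s| \approx 0.0015$; a `beta_is_mean` switch supports the
(mean, shape) convention used by some simulators, under which mean
$|s| = 0.0092$) and sets the dominance coefficient deterministically from
$s$:
$$h = \frac{1}{1/\theta_{\mathrm{intercept}} - \theta_{\mathrm{rate}}\, s},
\qquad \theta_{\mathrm{intercept}} = 0.978,\ \theta_{\mathrm{rate}} = 50328,$$
so a neutral mutation is nearly additive-dominant ($h = 0.978$) and strongly
deleterious mutations approach full recessivity. Since $s \le 0$ the
denominator is at least $1/\theta_{\mathrm{intercept}}$ and $h$ stays in
$(0, \theta_{\mathrm{intercept}}]$.

A deliberate approximation: any partial dosage in a tetraploid (1–3 of 4
copies) gets the same heterozygous factor $(1 + hs)$. This reduces exactly
to diploid semantics and to the fully recessive main model at $h = 0$; a
dosage-graded mapping would live behind the same single function
(`individual_fitness`) if it were ever swapped in.

**Fixation.** A mutation present on all $\mathrm{ploidy} \times N$
chromosomes is converted to a substitution and removed from every genome;
reported fitness covers segregating mutations only. This implies a
discontinuity — fixing a recessive deleterious allele multiplies every
individual's reported fitness by $1/(1+s)$ — which is documented rather than
smoothed, and is precisely why a stalled fixation rate is one of the POD
criteria below.

## Trajectories and the POD classifier

Every `record_every` generations (default 10) the simulator records the
median allele frequency over segregating mutations (NA, not 0, when nothing
segregates, so mutation-free early generations cannot fake a low-frequency
signal), mean population fitness, parental mean fitness, the segregating
count and the cumulative substitution count. Statistics describe the
offspring population after the fixation sweep.

POD is called from four qualitative criteria, each given an explicit numeric
operationalisation in `pod_config()` because the underlying description is
qualitative; every threshold is exposed and documented:

* **i — elevated intermediate median allele frequency**: late-window mean of
  the per-generation median ≥ 0.25 (`af_threshold`).
* **ii — decelerated fitness decline**: least-squares slope of log mean
  fitness in the late window at least `decel_ratio` (default 0.8) times the
  early-window slope when the latter is negative. The default was calibrated
  on the exemplar regime (below): tetraploid fitness decline is shallow and
  late, so its late/early slope ratio sits nearer 1 than the diploid's,
  while steady mutation-accumulation and high-recombination regimes have a
  ratio of exactly 1 — 0.8 separates the two with margin on both sides.
* **iii — continually rising segregating count**: late-window slope ≥
  `seg_slope_min` (default 1e-3 mutations/generation, i.e. at least one net
  new balanced polymorphism per thousand generations).
* **iv — stalled fixation**: late-window fixation rate at most `fix_ratio`
  (default 0.5) of the early-window rate; a zero early rate demands a zero
  late rate.

Windows default to generations 500–2500 (early) and the last 2000 recorded
generations (late). The verdict is the conjunction of all four, which
correctly rejects the high-recombination mimic regime where allele
frequencies are elevated but fitness collapses and fixations continue.
`make_fixture_trajectory()` generates noiseless or jittered archetypes of
all four regimes so the classifier is testable without the simulator.

## What the generator emulates — and what it does not

The simulator *is* the data generator: there is no external data. It
emulates the study conditions — a single 1 Mb chromosome, constant per-bp
rates, constant $N \in \{100, 200, 500\}$, $s$ from $-0.0005$ to $-0.02$ or
the empirical DFE, $\mu, \rho \in [10^{-10}, 10^{-7}]$, 10 replicates of
20,000 generations. It does not model: neutral linked variation (so
associative-overdominance signatures on diversity are out of scope),
beneficial mutations, epistasis, multivalent pairing or double reduction,
ploidies other than 2 and 4, non-constant demography, or recombination
modifiers. Conclusions from passing tests therefore concern the dynamics of
deleterious load under tetrasomic masking, not genome-scale patterns in real
polyploid data.

## Numerical and scale choices

* **Desk scaling.** Trajectory statistics are invariant in distribution
  under $L \mapsto L/f$, $\mu \mapsto f\mu$, $\rho \mapsto f\rho$ (the
  per-chromosome totals $\mu L$ and $\rho L$ are what matter; positions are
  exchangeable). The package verifies this as a property (Kolmogorov–Smirnov
  on end-state distributions) and uses factor-10 scaled runs
  ($L = 10^5$) for its own experiments: the exemplar regime
  ($N = 100$, $\mu = 10^{-7}$, $s = -0.005$, $\rho = 10^{-10}$ at full
  scale) is run for 8000 generations × 10 replicates when classifying, and
  5 replicates with the final 1000 generations averaged when estimating the
  equilibrium median allele frequency. Those sizes were chosen as the
  smallest at which the equilibrium plateau (reached here by generation
  ~5000) is unambiguous; `scale_factor = 1` reproduces full-size runs.
* **RNG discipline.** All randomness flows through R's RNG, consumed in a
  fixed documented order (parents, then per gamete: bivalent pairing,
  per-bivalent crossovers and segregation, then mutations), so a
  `(params, seed)` pair reproduces a run bit-exactly, and the stepwise R
  API (`wf_generation` + `sweep_fixations`) replays the compiled run loop
  exactly. Sweep runs derive per-cell seeds by hashing
  (base seed, N, s, μ, ρ, ploidy, replicate), making results independent of
  execution order.
* **Ties and degenerate cases.** Haplotypes are ordered by (position, id)
  with fresh ids sorting last at a shared position; the median of an even
  number of frequencies averages the two central values; log-fitness is
  floored at 1e-12 before regression; an all-zero-fitness generation raises
  an extinction error rather than renormalising; fitness is clamped at 0
  (relevant only for $|s|$ near 1, outside the study grid).

## Observed behaviour at the exemplar parameters

At the exemplar regime the package's own runs (the same ones its tests and
acceptance script execute) show: tetraploid median allele frequency climbing
to a plateau of roughly 0.33–0.47 across replicates (mean ≈ 0.37) with mean
fitness staying above ~0.87 and essentially no fixations; diploids at the
same parameters equilibrate near 0.32 with far lower fitness (~0.55–0.75)
and a visibly larger mass of low-fitness homozygous offspring. Lowering the
recombination rate never lowers — and typically raises — equilibrium mean
fitness across the POD region, and at a low mutation rate
($\mu = 5\times10^{-9}$) tetraploids hold elevated allele frequencies where
diploids do not: the two headline contrasts of the study, reproduced
directionally by the test suite.

## Known limitations

The dominance model for partial tetraploid dosages is a single-factor
approximation (above). The classifier thresholds are operationalisations of
qualitative criteria; they were calibrated against the exemplar and the
archetype fixtures, not against every cell of the full heatmap, and no
claim is made that they match the original study's per-cell judgements
everywhere. Parental-mean fitness can fall below population mean fitness in
individual generations by sampling noise (the enrichment holds on average,
and is tested that way). Memory use grows with the segregating count, which
under POD grows roughly linearly in time; full-scale 20,000-generation runs
across the entire grid are intended for cluster use via `run_sweep()` with
`scale_factor = 1`.
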