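---
title: "A threshold model of sex-determination evolution along a temperature gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A threshold model of sex-determination evolution along a temperature gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsdsim)
```

## The model

`gsdsim` simulates the evolution of genetic sex determination (GSD) in a
metapopulation arranged along a linear temperature gradient, using an
individual-based, forward-in-time model inspired by the housefly
sex-determination system. Three loci interact:

* **F**, an autosomal feminizing locus (a *transformer*-like switch). Each
  of the two alleles carries two evolvable quantitative traits: a baseline
  expression level $z_{F0} \ge 0$ and a sensitivity $s_{FM} \in [0, 1]$ to
  the masculinizing product.
* **M_Y**, a Y-linked masculinizing locus (an *Mdmd*-like factor) with an
  evolvable expression level. A "Y chromosome" in this model is exactly a
  sex-chromosome copy carrying the M_Y locus.
* **M_A**, a single autosomal locus at which a masculinizing allele can
  arise de novo during meiosis.

The net activity contributed by one F allele in an individual with total
masculinizer product $\hat z_M$ developing at normalized temperature $T$ is

$$ z_F = \left(z_{F0}\,(1 + \beta T) + \varepsilon\right)\,
         \left(1 - s_{FM}\, \hat z_M\right), $$

where $\beta \ge 0$ is the linear rate at which temperature raises F
expression and $\varepsilon$ is Gaussian expression noise (one independent
draw per allele, standard deviation `sigma_eps`). The first factor is the
amount of F product made; the second is the proportion that escapes
degradation by M product. $\hat z_M$ sums the expression of all
masculinizer alleles carried (at most two Y-linked and two autosomal).
Summing $z_F$ over the two F alleles gives the developmental signal
$\hat z_F$, and sex follows a double threshold: female if
$\hat z_F > \theta_F$, male if $\hat z_F < \theta_M$, and an infertile
intersex for intermediate values ($\theta_M < \theta_F$ always).

Two numerical floors keep the arithmetic physical, and both are applied
per allele: a noise draw cannot make the amount of product negative, and
degradation cannot exceed the product present (the factor
$1 - s_{FM}\hat z_M$ is floored at zero when $s_{FM}\hat z_M > 1$). Both
choices are exercised directly in the unit tests.

### Life cycle

Generations do not overlap. Each cycle runs, in order:

1. **Reproduction.** Within every deme holding at least one adult female
   and one adult male, `offspring_per_deme` (B) offspring are produced;
   each draws a mother uniformly from the deme's females and a father
   uniformly from its males, with replacement (polygynous random mating).
   Intersexes never reproduce.
2. **Meiosis and mutation.** Each gamete receives one allele per locus
   (the three loci assort independently). Every transmitted evolvable
   trait mutates with probability `p_mut`; a fraction `p_null` of
   mutations are irreversible null mutations that set the trait to zero
   forever, the rest add a Gaussian step (sd `sigma_mut`) clipped to the
   trait's range. A gamete whose transmitted autosomal slot carries no
   *expressed* allele gains a fresh M_A allele (expression `z_m_init`)
   with probability `mu_d`. An expressed M_A lineage is never overwritten;
   a decayed (null) allele can be replaced, so the de novo influx is
   genuinely recurrent. Without this reactivation rule, selectively inert
   null M_A alleles drift to fixation at the slot within roughly a
   thousand generations and silently switch the mutational pressure off,
   which contradicts the model's premise of recurrent M_A origination.
3. **Development and viability selection.** Sex is determined at the natal
   deme's temperature. The Y chromosome carries two fitness effects:
   YY homozygotes survive with relative viability $s_{YY} \in [0, 1]$,
   and sexually antagonistic Y-linked variation multiplies fitness by
   $1 + s_a$ in Y-bearing males and $1 - s_a$ in Y-bearing females
   (applied once per carrier; intersexes experience only the YY cost).
   The two effects combine multiplicatively. These factors are *relative*
   fitnesses: survival probability is the individual's factor divided by
   the largest attainable factor, $1 + s_a$ (soft selection). Treating
   the factors as absolute survival probabilities would silently cap the
   male advantage at one and turn sexually antagonistic selection into a
   pure cost, making Y retention impossible — the regulated deme sizes
   make relative, not absolute, fitness the operative quantity. A config
   switch (`sa_on_mating`) instead applies the antagonistic factor as a
   mating-success weight during reproduction, with only the YY component
   acting on survival; the default keeps both on survival.
4. **Dispersal.** Each survivor migrates with probability `d`
   (`dispersal_rate`); interior migrants move to the left or right
   neighbour with equal probability, edge migrants to their single
   neighbour.
5. **Regulation and maturation.** Each deme retains at most `capacity`
   (K) juveniles, sampled uniformly without replacement; survivors become
   the next generation's adults. Regulation runs after dispersal.

Temperature is linear in deme index: $T = 0$ in deme 0 (the cold,
"northern" end) and $T = 1$ in the last deme.

### Initial conditions

`initialize_population()` builds the ancestral XY system that all
experiments start from: every deme at capacity with a 1:1 sex ratio,
females `F/F; X/X`, males `F/F; X/Y` with a single expressed M_Y, all F
alleles sharing `z_f0_init` and `s_fm_init`, and no autosomal
masculinizers. With the default thresholds this system is exactly
functional: one allele's activity lies between the thresholds, two
unsuppressed alleles exceed $\theta_F$, and full suppression by one M
falls below $\theta_M$.

## Parameters and defaults

| key | meaning | default |
|---|---|---|
| `n_demes` | demes along the gradient | 20 |
| `capacity` (K) | adults per deme after regulation | 200 |
| `offspring_per_deme` (B) | fecundity pool per deme | 400 |
| `dispersal_rate` (d) | per-individual migration probability | 0.05 |
| `generations` (G) | cycles per run | 5000 |
| `theta_f`, `theta_m` | feminization / masculinization thresholds | 1.2, 0.2 |
| `beta` | temperature slope of F expression | 0 |
| `sigma_eps` | sd of per-allele expression noise | 0.05 |
| `p_mut` | per-trait, per-gamete mutation probability | 0.01 |
| `p_null` | null fraction of mutations | 0.05 |
| `sigma_mut` | sd of quantitative mutational steps | 0.01 |
| `mu_d` | de novo M_A activation rate per gamete | 0 |
| `z_m_init` | expression of a fresh M_A allele | 1.0 |
| `s_yy` | YY-homozygote viability | 1.0 |
| `s_a` | sexually antagonistic Y effect | 0 |
| `z_f0_init`, `s_fm_init`, `z_my_init` | ancestral trait values | 1, 1, 1 |

Expression units are arbitrary; only ratios to the thresholds matter.
Two defaults deserve comment, since they shape every campaign:

* **`sigma_mut = 0.01`.** The thresholds are escapable: in a deme where a
  single feminizer allele falls just short of $\theta_F$, selection
  steadily pushes its expression upward, and with large mutational steps
  the lineage crosses the threshold within a thousand-odd generations,
  dissolving any spatial cline into a uniform female-heterogamety system.
  Stable clines on the multi-thousand-generation timescale the package
  simulates require quantitative steps that are small relative to the
  threshold gaps, hence 0.01 expression units (1% of the ancestral
  expression per mutation, at 1% of gametes). Null mutations, not
  quantitative steps, remain the dominant source of qualitatively new
  alleles (insensitive F_I, unexpressed F_0), which matches the model's
  emphasis on loss-of-function variation.
* **`sigma_eps = 0.05`.** Noise sharpens nothing here; it makes
  development marginally stochastic near the thresholds. 0.05 units keeps
  misclassification of the ancestral genotypes rare (the female signal
  sits $\approx 11$ allele-level standard deviations above $\theta_F$)
  while still exercising the noise machinery.

## What the simulations emulate — and what they do not

The generator reproduces the study conditions of the three simulation
campaigns packaged in `build_campaign()`:

* **regimes** — no temperature dependence, no Y fitness effects; thresholds
  and `mu_d` sampled per run. Threshold ranges
  ($\theta_M \sim U(0.1, 0.6)$, $\theta_F \sim U(0.8, 1.9)$) are chosen so
  the ancestral XY system is developmentally functional at the start; a
  feminization threshold above twice the ancestral expression would make
  every founder female intersex and the run would merely record an
  extinction.
* **cline** — sweeps $\beta$ and $\theta_F$ at $\theta_M = 0.2$,
  $\mu_D = 0.001$, with the first run pinned to the reference point
  $\theta_F = 1.20$, $\beta = 0.76$, $\mu_D = 0.014$.
* **y_effects** — fixes $\theta_F = 1.2$, $\theta_M = 0.3$, $\beta = 0.5$
  and sweeps `mu_d`, `s_a`, `s_yy`.

These are simulations of an idealized system: free recombination between
the three loci, a single autosomal M locus, no age structure, no
overlapping generations, no mate choice beyond the optional
mating-success weighting, and a strictly linear gradient. Passing tests
demonstrate the internal evolutionary logic — which SD systems are
reachable and stable under which threshold orderings and fitness
effects — not quantitative agreement with any natural population.

## Analysis layer

* `classify_f_allele()` bins F alleles into regular (`F`), insensitive
  expressed (`F_I`), and unexpressed (`F_0`) classes with tolerance
  `eps_class = 0.01` (evolved continuous traits never reach exact zero
  without a null mutation; a sensitivity or expression below 1% of the
  ancestral value is functionally zero). `F_0` takes precedence: an
  unexpressed allele cannot feminize, whatever its sensitivity.
* `genotype_class()` and `modal_genotype_pair()` reduce a population to
  its most frequent female and male genotype classes (ties broken
  lexicographically — rare in practice and documented rather than
  randomized so results are reproducible).
* `classify_sd_system()` names the SD system formed by a genotype pair if
  and only if the pair is *recurrent*: brute-force enumeration of all
  offspring allele combinations must regenerate exactly the two parental
  classes with the correct sexes and no intersexes. Offspring sex is
  evaluated at the class level, where an expressed masculinizer fully
  silences regular F alleles. In pairs containing no regular F allele, M
  has no phenotypic function and its slots are masked (`*/*`) before the
  recurrence check, mirroring the taxonomy's "degenerate M" systems.
* `detect_housefly_like()` operationalizes the joint-cline criterion:
  window-averaged paternal M_Y frequency in males above 0.5 at the cold
  end and below at the warm end, with both paternal M_A (males) and
  maternal F_I (females) showing the opposite pattern. "Major allele"
  means a window-mean frequency above 0.5; the equilibrium window
  defaults to the final 10% of recorded generations.
* Origin-filtered frequencies (maternal F alleles in females, paternal
  alleles in males) follow the sex-specific transmission of the factors:
  a dominant feminizer is transmitted like a W chromosome, masculinizers
  like a Y, so these margins are where the clines are sharpest.

## Engines, determinism, and problem sizes

`run_simulation()` executes each life-cycle iteration either through a
fused compiled step (`engine = "cpp"`, the default) or by composing the
exported R operations (`engine = "r"`). Both implement the identical
model and draw all randomness from R's global RNG, so a configuration
plus seed determines every result bitwise for a given engine; the test
suite checks the two engines against each other statistically. A
20-deme, K = 200 metapopulation advances at roughly 2–3 ms per
generation with the compiled engine.

The replicate campaigns in the test suite and acceptance script run
desk-scale versions of the experiments: 10 demes, K = 200, B = 400,
1,500–3,000 generations, 10–50 replicates per condition, with equilibrium
summaries averaged over the final 10% of recorded generations. These
sizes were chosen as the smallest at which the qualitative outcomes
(modal SD system, cline shape, masculinizer loss/retention, housefly-like
polymorphism) are reproducible across seeds.

## Known limitations

* The spatial clines are quasi-stationary rather than eternal: because
  expression is evolvable, cold-deme populations eventually escape the
  feminization threshold (the dominant feminizer's expression ratchets
  upward under intersex selection) and convert to a uniform
  female-heterogamety system. With the default mutation parameters this
  takes well beyond the simulated horizon at low `mu_d`, but it is the
  expected end state of sufficiently long runs.
* The sexually antagonistic effect is modeled per carrier, not per Y
  copy; with the YY viability cost applied separately, a per-copy
  ("additive") reading would differ only for YY homozygotes, where the
  printed combined factors are matched by the per-carrier form.
* Deme extinction is possible (e.g. all-intersex regimes); the simulator
  flags whole-metapopulation extinction and stops early rather than
  modelling recolonization.
* The M field of the genotype shorthand cannot express every conceivable
  four-allele combination concisely; composite tokens (`M_Y+M_A`) cover
  the configurations that occur in practice.
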