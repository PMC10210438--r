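# gsdsim

Individual-based, forward-in-time simulation of how genetic
sex-determination (GSD) systems evolve and diverge along an environmental
gradient.

Many species segregate several sex-determination systems at once — the
housefly is the classic case, with Y-linked male determiners at high
latitudes giving way to autosomal male determiners plus a dominant
insensitive feminizer toward the tropics. `gsdsim` is for evolutionary
geneticists who want to explore when such polymorphisms arise: it models a
feminizing switch locus **F** whose expression is temperature-dependent,
antagonized by Y-linked (**M_Y**) and autosomal (**M_A**) masculinizing
loci, in a metapopulation of demes arranged along a linear temperature
gradient.

## The model in brief

Each F allele contributes net activity

```
z_F = (z_F0 (1 + beta T) + eps) * (1 - s_FM * zM_hat)
```

at normalized temperature `T`, where `z_F0` (baseline expression) and
`s_FM` (sensitivity to masculinizer product) are evolvable allelic traits,
`zM_hat` is the carrier's total masculinizer product, and `eps` is
expression noise. The summed activity of the two F alleles sets sex by a
double threshold: female above `theta_f`, male below `theta_m`, infertile
intersex in between. Gametes mutate (including irreversible null
mutations that create insensitive `F_I` and unexpressed `F_0` variants),
empty autosomal slots gain de novo M_A alleles at rate `mu_d`, and the Y
can carry viability (`s_yy`) and sexually antagonistic (`s_a`) fitness
effects. Generations are non-overlapping: reproduction within demes,
development plus viability selection, nearest-neighbour dispersal, then
density regulation. An analysis layer classifies the evolved systems from
recurrent genotype pairs and detects housefly-like joint clines.

See the methods vignette (`vignettes/sex-determination-model.Rmd`) for
the full model description and parameter table.

## Worked example

Evolve the reference cline regime (feminization threshold 1.2, strong
temperature dependence, recurrent de novo M_A) for 2,000 generations on a
10-deme gradient:

```r
library(gsdsim)

cfg <- sim_config(seed = 42, n_demes = 10, capacity = 200,
                  offspring_per_deme = 400, generations = 2000,
                  record_every = 20, theta_f = 1.2, theta_m = 0.2,
                  beta = 0.76, mu_d = 0.014)
sim <- run_simulation(cfg)
eq  <- equilibrium_summary(sim$trajectory, window = 0.1)
round(eq[, c("deme", "temp", "freq_fi_mat_f", "freq_ma_pat_m")], 3)
```

```
 deme  temp freq_fi_mat_f freq_ma_pat_m
    0 0.000         0.002         0.980
    1 0.111         0.005         0.982
    2 0.222         0.113         0.960
    3 0.333         0.743         0.872
    4 0.444         0.899         0.833
    9 1.000         0.995         0.932
```

The dominant insensitive feminizer `F_I` (measured among maternally
inherited alleles in females) forms a steep cline: essentially absent at
the cold end, where a single allele's activity falls short of the
feminization threshold, and nearly fixed at the warm end, where
temperature-boosted expression exceeds it. The Y-linked masculinizer has
been replaced by its autosomal counterpart throughout (`freq_my_pat_m`
is 0 everywhere), as expected without Y-linked fitness effects.

```r
an <- analyze_simulation(sim)
an$sd_system_cold
#> <gsd_sd_system> male_heterogamety_MA (recurrent; regime thetaM<zF<thetaF)
#>   F: F/F; X/X; 0/0
#>   M: F/F; X/X; 0/M
an$sd_system_warm
#> <gsd_sd_system> unclassified (not recurrent; regime thetaM<thetaF<zF)
#>   F: F_0/F_I; X/X; M/M
#>   M: F/F_0; X/X; M/M
```

The cold end is a clean male-heterogamety system (males heterozygous for
one expressed autosomal masculinizer). The warm end is caught mid-turnover
toward female heterogamety: females are heterozygous for `F_I`, but the
males' regular F allele has not yet fully decayed to `F_0`, so the modal
pair is not yet a closed (recurrent) system — re-running longer completes
the transition.

Adding Y-linked sexually antagonistic effects (`s_a`) and YY viability
costs (`s_yy`) under recurrent M_A origination produces the housefly-like
joint polymorphism — M_Y retained in cold demes, M_A plus F_I taking over
warm demes — which `detect_housefly_like()` scores from the three edge
clines.

## Command line

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/gsdsim.R simulate --config my_run.yaml --seed 1 --out out/
Rscript inst/cli/gsdsim.R analyze --trajectory out/trajectory.tsv --out summary.tsv
Rscript inst/cli/gsdsim.R sweep --campaign cline --scale 0.01 --seed 1 --out sweep/
Rscript inst/cli/gsdsim.R validate-config --config my_run.yaml
```

Configurations are flat YAML key-value files; `config_defaults()` lists
every key. Outputs are TSV trajectories plus a resolved-config dump and
an MD5 manifest, so identical seeds reproduce identical files.

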