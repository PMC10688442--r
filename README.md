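# evorescue

Individual-based simulation of **evolutionary rescue** — adaptation that
saves a declining population from extinction after severe environmental
change — when two textbook assumptions are dropped: density-independent
growth and constant genetic variance. The package is aimed at theoretical
population biologists and conservation modellers who want extinction and
rescue probabilities that account for negative density dependence, drift
and the erosion of standing genetic variation, including the
self-reinforcing decline known as the extinction vortex.

## The model

Diploid, semelparous individuals carry *m* = 25 unlinked biallelic loci;
each allele copy adds ±1/(2√m) to the genotype *g*, the phenotype is
*z* = *g* + *e* with *e* ~ N(0, σ²ₑ), and intrinsic fitness is Gaussian
stabilizing selection around the optimum θ:

    W = Wmax · exp(−(z − θ)² / 2w²),     R = W · e^(−αN)

with the Ricker factor e^(−αN) imposing negative density dependence. An
environmental shift moves θ from 0 to 2.8 at founding. Each female mates
with a uniformly chosen male and bears Poisson(2R) offspring with free
Mendelian segregation; generations do not overlap. Additive genetic
variance is σ²ₐ = Σ 2p(1−p)/m, so drift, fixation and genetic erosion
emerge from the life cycle rather than being assumed.

On top of the simulator the package provides:

- the 2×2×2 factorial experiment (α ∈ {0, 0.0035}; N₀ ∈ {100, 20};
  high/low founding diversity) with deterministic per-trial seeding
  (`rescue_design()`, `run_design()`);
- extinction and two rescue classifications — mean expected offspring
  R̄ > 1, or census above founding size, for three consecutive
  generations (`trial_outcome()`, `rescue_summary()`);
- a constant-genetic-variance analytic reference with a Ricker term and
  its carrying capacity (`project_gh_ricker()`, `equilibrium_size()`,
  `estimate_k0()`);
- reversed-time extinction-vortex statistics r, ν and 1−k aligned on time
  to extinction (`reverse_time()`, `ensemble_vortex()`);
- logistic effect sizes of treatments and initial maladaptation on
  population fates (`fit_logistic()`, `density_effect_sizes()`).

## Worked example

One density-dependent, low-diversity trial:

```r
library(evorescue)
params <- sim_params(N0 = 20, alpha = 0.0035, diversity = "low",
                     horizon = 15, seed = 42)
tr <- run_trial(params)
print(tr)
#> rescue_trajectory: 9 censuses (t = 0..8), status = extinct
#>   N0 = 20, final N = 0, initial maladaptation = 2.740
round(head(tr$records, 3), 3)
#>   t  N   gbar   zbar  Wbar  Rbar sigma_a2 fixed_pos fixed_neg
#> 1 0 20  0.060  0.275 0.874 0.815    0.252         6         6
#> 2 1 21 -0.019 -0.134 0.682 0.634    0.244         6         6
#> 3 2 15 -0.187 -0.189 0.598 0.567    0.242         6         6
```

This population was founded 2.74 genotype units below the optimum, with
mean intrinsic fitness near 0.87 but density-discounted expected
offspring R̄ ≈ 0.82 < 1: it declines, drifts (a seventh locus fixes by
generation 4), never adapts and is extinct at generation 8.

A reduced factorial experiment over 50 generations:

```r
d <- rescue_design(reps = 200, horizon = 50, base_seed = 1)
e <- run_design(d, keep_trajectories = FALSE)
print(e)
#> rescue_experiment: 1600 trials (8 treatments x 200 reps), horizon 50
#>   extinct 60.2%, censored 23.2%, fitness-rescued 47.8%
s <- rescue_summary(e$outcomes)
subset(s, criterion == "size" & size == "large",
       c(diversity, density, prob_rescue, mean_time, prob_extinct_after))
#>    diversity density prob_rescue mean_time prob_extinct_after
#> 9       high      DI       0.875  11.46286                  0
#> 10      high     NDD       0.655  19.51908                  0
#> 13       low      DI       0.575  16.31304                  0
#> 14      low      NDD       0.185  29.29730                  0
```

Among large founding populations, turning density dependence on drops the
probability of size-based rescue (e.g. 0.875 → 0.655 at high diversity)
and roughly doubles the time to recover founding size — the central
qualitative result: density dependence removes much of the protection
that initial size and diversity otherwise confer.

A command-line wrapper over the same functions ships in
`inst/cli/evorescue.R` (`simulate`, `summarize`, `vortex`, `project`,
`effects`, `replicate-paper`), driven by a flat YAML configuration whose
defaults encode the study parameter set.

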