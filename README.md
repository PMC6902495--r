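# augseq

Design, monitoring and simulation of two-arm group-sequential clinical
trials in which **early (short-term) measurements of the primary outcome
augment the long-term outcome at interim analyses**.

The setting: participants are followed up at, say, 3, 6 and 12 months on
the same outcome scale, with the 12-month measurement definitive. At an
interim look most recruited participants have only early data. If the
early and late measurements are correlated, throwing the early data away
wastes information; `augseq` implements the augmented treatment-effect
estimator that uses it, and everything a trial statistician needs around
it. It was built for trials of surgical procedures (the motivating example
compares arthroscopic debridement with and without a sub-acromial balloon
spacer on the 0–100 Constant–Murley shoulder score), where stopping early
for futility is the main design goal, but applies to any two-arm trial
with repeated normal outcomes.

## The statistic at the core

For outcomes $(X_{ij1},\dots,X_{ijK})$, multivariate normal with SDs
$\sigma_k$ and correlations $\rho_{kk'}$ (endpoint $K$ = long-term), and
$N_1\ge\dots\ge N_K$ participants per arm providing each endpoint, the
estimated long-term treatment difference is

$$B=\bar D_K+\sum_{k<K}\rho_{kK}\frac{\sigma_K}{\sigma_k}
\frac{N_k-N_K}{N_K}\big(\bar D_{k\setminus K}-\bar D_k\big),
\qquad
\mathrm{var}(B)=\frac{2\sigma_K^2}{N_K}\Big[1-\sum_{k<K}\rho_{kK}^2
\tfrac{N_k-N_K}{N_k}+2\rho_{1K}\rho_{2K}\rho_{12}\big(1-\tfrac{N_K}{N_2}\big)\Big]$$

(the variance shown for $K=3$). The mean-centred corrections are unbiased
under any early-endpoint effect pattern and can only add information. The
z-statistic $S_w=B/\mathrm{sd}(B)$ is monitored against error-spending
lower (futility, binding) and upper (efficacy) boundaries computed on the
canonical joint distribution by stagewise numerical integration; looks are
scheduled by information, $I_w=1/\mathrm{var}(B)$, not calendar time.

## Worked example

A small design with two early looks: per-arm counts (N1, N2, N3) of
(20, 15, 10) then (25, 20, 15), final N = 30 per arm, assumed
correlations 0.5 between each early and the final endpoint (0 between the
early pair), SD 18.

```r
library(augseq)

m <- endpoint_model(sigmas = rep(18, 3),
                    corr = matrix(c(1, 0, 0.5,
                                    0, 1, 0.5,
                                    0.5, 0.5, 1), 3))
plan <- spending_plan(alphaL = c(0.200, 0.600, 0.975),
                      alphaU = c(0.000, 0.001, 0.025))
sched <- information_schedule(c(
  expected_information(look_counts(c(20, 15, 10)), m),
  expected_information(look_counts(c(25, 20, 15)), m),
  final_information(30, 18)))

round(sched$info, 3)
#> [1] 0.019 0.028 0.046
round(information_fraction(sched$info, sched$info[3]))
#> [1]  42  60 100

compute_boundaries(plan, sched)
#> Group-sequential boundaries (binding futility):
#>  analysis       info   lower  upper
#>         1 0.01949318 -0.8416    Inf
#>         2 0.02763958  0.2474 3.0902
#>         3 0.04629630  1.9581 1.9581
```

The expected information at the looks is 0.019 and 0.028 — 42% and 60% of
the final 30/648 ≈ 0.046 — and the spending vectors translate into a
lower boundary of −0.842 at look 1 (no efficacy stopping there), 0.247 and
3.09 at look 2, and a final critical value of 1.96. An interim analysis on
a synthetic interim snapshot:

```r
fx <- generate_fixture(m, counts = c(20, 15, 10), seed = 2024)
run_interim_analysis(fx, look = 1, compute_boundaries(plan, sched), assumed = m)
#> Interim analysis, look 1
#>   S = 1.2392 vs boundaries (l = -0.8416, u = Inf)
#>   verdict: continue
```

S = 1.24 sits between the boundaries, so this trial continues; below
−0.842 it would have stopped for futility (binding), and the overrunning
analysis (`overrun_analysis()`) would then give the definitive estimate
once everyone reached 12 months. The fixed-design benchmark:

```r
fixed_design_sample_size(delta = 10, sigma = 20)
#> $n_per_group 85   $n_total 170
```

Operating characteristics by simulation (staggered-centre Poisson
recruitment, sequential nuisance re-estimation, information-triggered
looks):

```r
design <- trial_design(spending_plan(c(0.24, 0.72, 0.975), c(0, 0.001, 0.025)),
                       rbind(c(55, 40, 20), c(70, 55, 35)),
                       n_per_arm = 85, assumed = endpoint_model(rep(20, 3), 0.5))
oc <- operating_characteristics(design,
                                scenario_truth(design$assumed, 10),
                                n_reps = 10000, seed = 1)
```

yields overall power ≈ 88% at a 10-point difference for that futility
spending, with cumulative null futility stopping tracking (0.24, 0.72) —
the numbers the acceptance suite checks.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "augseq", package = "augseq"))')
Rscript $CLI boundaries --config inst/extdata/worked_design.json --out report.json
Rscript $CLI generate-data --config inst/extdata/worked_design.json --seed 7 --out trial.csv
Rscript $CLI analyze --config inst/extdata/worked_design.json --data trial.csv --look 1 --out decision.json
Rscript $CLI simulate --config scenario.json --reps 10000 --seed 1 --out oc.json
```

Exit code 0 on success, 2 on validation errors; unknown flags and config
keys are rejected, not ignored.

## Layout

- `R/` — estimator and variance (`effect.R`), nuisance estimation,
  error-spending boundary recursion (`boundaries.R`), interim decision
  engine, event-driven information monitoring (`information-path.R`),
  trial simulator, JSON/CSV I/O and the CLI.
- `vignettes/design-methods.Rmd` — the model, the scheduling/analysis
  asymmetries, numerical choices, and what the simulator does and does not
  emulate.
- `tests/testthat/` — unit, property and acceptance tests, including
  Monte-Carlo oracles for the variance formula and the boundary recursion.
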