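# replisim

Monte-Carlo simulation of **replication regimes** in an idealized
scientific community, for researchers in metascience, research policy and
quantitative psychology who want to compare the cost and knowledge yield
of pre- versus post-publication replication.

## The model in brief

A community runs a first round of 100 studies against a 10 × 10 landscape
of candidate phenomena in which each cell holds a true effect with
probability P(H₁) = .09. Each study samples *n* observations from
N(μ_cell, σ) and applies a two-tailed one-sample *t*-test (α = .05,
σ = 2, *n* ∈ {18, 34} for power .5/.8) or a Jeffreys–Zellner–Siow Bayes
factor (BF₁₀ > 3 evidence for an effect, BF₀₁ > 3 for its absence;
σ = 1.5, *n* = 34). Notable results are then handled by one of two
regimes:

* **private** — every investigator replicates their own notable results
  and publishes only what replicates (cost: 100 + #notables);
* **public** — notable results are published unreplicated and the
  community replicates those it finds interesting (cost: 100 +
  #interesting notables).

Interest is stochastic: each finding draws a citation count n_k from a
generalized Pareto distribution fitted to psychology citation data
(k = 0.115, σ = 8.71, θ = 0) and is deemed interesting with probability

```
P(I_k) = 1 / (1 + exp(-(n_k - q)/t))
```

where q is the 90th-percentile citation threshold (≈ 22.96) and
t ∈ {1, 5, 10} the temperature of the decision rule. Knowledge is counted
as interesting, successfully replicated findings that reflect the ground
truth. Research can be discovery-oriented (targets drawn over the whole
grid) or theory-testing (effects clustered in a 4 × 4 window; the
theory's predicted window sits (1 − ρ) × 9 cells away, with theory
quality ρ ∈ [0, 1]). Perturbations inject p-hacking (α = .2), optional
stopping (up to 5 batches of 1/5/10 extra participants), outright fraud,
or a world with no true effects.

## A worked example

```r
library(replisim)

priv <- run_condition(scenario_config(
  mode = "discovery", regime = "private",
  interest = interest_model(temperature = 5),
  n_replications = 1000, seed = 2026))
pub <- run_condition(scenario_config(
  mode = "discovery", regime = "public",
  interest = interest_model(temperature = 5),
  n_replications = 1000, seed = 2026))

priv
#> <condition_summary> discovery / frequentist / private regime |  t = 5 | 1000 replications | seed 2026
#>   total_experiments            111.893 (sd    3.932, se  0.124)
#>   n_notable_first_round         11.893 (sd    3.932, se  0.124)
#>   n_published                    6.201 (sd    3.024, se  0.096)
#>   n_replications_run            11.893 (sd    3.932, se  0.124)
#>   n_successful_interesting       0.917 (sd    0.999, se  0.032)
#>   n_true_interesting             0.887 (sd    0.989, se  0.031)
#>   total_participants          3804.362 (sd  133.690, se  4.228)
pub
#> <condition_summary> discovery / frequentist / public regime |  t = 5 | 1000 replications | seed 2026
#>   total_experiments            101.587 (sd    1.227, se  0.039)
#>   n_notable_first_round         11.893 (sd    3.932, se  0.124)
#>   n_published                   11.893 (sd    3.932, se  0.124)
#>   n_replications_run             1.587 (sd    1.227, se  0.039)
#>   n_successful_interesting       0.811 (sd    0.904, se  0.029)
#>   n_true_interesting             0.785 (sd    0.892, se  0.028)
#>   total_participants          3453.958 (sd   41.724, se  1.319)
```

Both regimes surface the same amount of knowledge (≈ 0.8–0.9 true,
interesting, replicated effects per 100 first-round studies at this
temperature — the regime does not affect discovery success; the small
gap here is within two Monte-Carlo standard errors), but the private
regime runs ≈ 10 more experiments per community to get it: it
replicates all ≈ 11.9 notable results, while the public community
replicates only the ≈ 1.6 it finds interesting.

Preset grids covering the standard study conditions (both power levels,
Bayesian inference, theory quality sweeps, the symmetric-null variant,
p-hacking, optional stopping, fraud, no-effect worlds, and the
interest-threshold sweep) live in `scenario_catalog()`:

```r
run_scenario("fig7_theory_freq", out_dir = "results")  # CSV + JSON output
```

or from a shell:

```sh
Rscript inst/cli/replisim.R run --preset fig7_theory_freq --out results
Rscript inst/cli/replisim.R samplesize 0.5 0.05 0.8   # -> 34
Rscript inst/cli/replisim.R quantile 0.115 8.71 0 0.9 # -> 22.96159
Rscript inst/cli/replisim.R bf 2 34                   # -> 0.8411691
```

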