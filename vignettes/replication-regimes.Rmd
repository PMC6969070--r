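---
title: "Modeling replication regimes in an idealized scientific community"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling replication regimes in an idealized scientific community}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replisim)
```

## The question

Should findings be replicated *before* they are published (a **private**
regime, in which each investigator replicates their own notable results
and publishes only what replicates), or *after* (a **public** regime, in
which notable results are published unreplicated and the community
replicates only those it finds interesting)? `replisim` implements a
Monte-Carlo model of an idealized scientific community that makes the
trade-off quantitative: it measures the **cost** of each regime as the
total number of experiments run, and its **knowledge gain** as the number
of interesting, successfully replicated findings that reflect the ground
truth.

## The model

One simulated "replication" of the community proceeds in three stages,
repeated (by default) 1000 times with a fresh world each time.

### 1. The landscape of true effects

The world is a 10 × 10 grid of candidate phenomena; the two dimensions can
be read as candidate manipulations and outcome measures. Each cell is a
true effect (mean 1) with probability $P(\mathrm{H}_1) = .09$, the
estimated base rate of true psychological hypotheses, or a null (mean 0).

* **Discovery mode** (`generate_discovery_landscape()`): cells are
  independent; experiments target cells uniformly at random with
  replacement, so the same effect can be discovered more than once.
* **Theory mode** (`generate_theory_landscape()` +
  `place_theory_window()`): all true effects are clustered in a 4 × 4
  window placed uniformly among the 7 × 7 feasible positions, and
  experiments target cells uniformly inside a *predicted* 4 × 4 window.
  Theory quality $\rho \in [0, 1]$ displaces the predicted window
  $(1-\rho) \times 9$ rows and columns from the true one (half counts
  round away from zero, so $\rho = .5$ gives offset 5), in a random
  feasible direction per dimension, clipped to the grid. A perfect theory
  ($\rho = 1$) searches exactly where the effects are; a poor theory
  ($\rho = .1$) searches where there are none.

Design choices made where the procedure was genuinely open:

* The number of clustered effects is drawn as Binomial(100, .09) — the
  same marginal as discovery mode — and capped at the window capacity of
  16 (the cap binds for fewer than 1% of draws and is logged). Keeping
  the marginal identical makes cost comparisons between the two modes
  interpretable.
* The count is drawn after window placement; since the two draws are
  independent the order has no observable consequence.
* "Centroid" is represented by the window's top-left anchor (0-based);
  displacement direction is random per dimension because only the
  magnitude and the fit-inside-the-grid constraint are determined.

### 2. Studies and inference

Each study draws $n$ observations from
$\mathcal{N}(\mu_{\text{cell}}, \sigma)$ and tests the mean against zero,
two-tailed.

* **Frequentist**: $\sigma = 2$ (so a true effect is $d = 0.5$) and
  $\alpha = .05$. Sample sizes come from the exact noncentral-$t$ power
  solver (`required_sample_size()`): $n = 34$ for power .8, $n = 18$ for
  power .5.
* **Bayesian**: $\sigma = 1.5$ and $n = 34$; evidence is the one-sample
  Jeffreys–Zellner–Siow Bayes factor (`jzs_bf10()`), a Cauchy prior on
  effect size with scale $r$. $\mathrm{BF}_{10} > 3$ is evidence for an
  effect; $\mathrm{BF}_{01} > 3$ evidence for its absence. The prior
  scale is not pinned by the model description; we default to $r = 1$,
  the original default of the method's source literature, and expose it
  in `test_config()`. At $r = 1$ the probability of
  $\mathrm{BF}_{10} > 3$ for a true effect ($d = 2/3$, $n = 34$) is
  0.883, consistent with the intended "power" of about .8; smaller
  scales (e.g. $r = \sqrt{2}/2$) give slightly higher values.

The JZS Bayes factor is computed by adaptive quadrature of the
Zellner–Siow $g$-mixture on $(0, \infty)$ with relative tolerance
$10^{-8}$; non-convergence is an error, never a silent value. A
zero-variance sample is likewise an error rather than an infinite Bayes
factor. The test suite checks the quadrature against an independent route
(the Cauchy mixture of noncentral-$t$ predictive densities) to four
significant digits. Because $\mathrm{BF}_{10}$ is strictly increasing in
$|t|$ at fixed $n$ (a tested property), the simulation engine classifies
studies in bulk by comparing $|t|$ with the critical values where the
Bayes factor crosses 3 and 1/3 (`bf_critical_t()`, cached per
condition); per-study Bayes factors are computed exactly by
`run_study()` when needed.

### 3. Community interest and the regimes

Scientific interest is modeled from the citation distribution of
psychology articles, fit by a generalized Pareto distribution (shape
$k = 0.115$, scale $\sigma = 8.71$, location $\theta = 0$). Each finding
receives one continuous citation draw $n_k$ from this distribution, and
is deemed interesting with probability

$$P(I_k) = \frac{1}{1 + e^{-(n_k - q)/t}},$$

where $q$ is the citation value at the 90th percentile of the fitted
distribution (22.96; the sensitivity sweep `supp_q_sweep` spans the 10th
to the 90th percentile) and the temperature $t \in \{1, 5, 10\}$ controls
how graded the threshold is. Interest is independent of truth: citations
model attention, not replicability. Citation draws are continuous —
rounding to integer counts would change nothing material, as the logistic
rule is continuous — and each finding draws once at its decision point;
outcomes are distributionally identical to attaching the draw at
creation.

A first round of 100 studies is classified into *notable* results
(significant effects; plus convincing nulls in the symmetric Bayesian
variant, where falsified predictions count against a theory). Then:

* **Private regime** (`apply_private_regime()`): every notable result is
  replicated once by its investigator (same cell, same design); both
  studies are published only if the replication reaches the same evidence
  category; the community's interest rule is applied to the published
  findings. Cost: 100 + number of notables. In the symmetric variant,
  convincing nulls are replicated irrespective of interest.
* **Public regime** (`apply_public_regime()`): every notable result is
  published; each receives an interest draw; interesting findings are
  replicated once by the community. Cost: 100 + number of interesting
  notables. Since the interesting findings are a subset of the notables,
  the public regime can never cost more than the private one on the same
  first round — the size of the saving is the quantitative question.

Replications use the same $n$, $\sigma$ and test as the original study;
each finding gets exactly one replication attempt. Replication success
requires only the same evidence category, with no same-direction
requirement — consistent with the double-false-positive rate being
$\alpha^2 = .0025$ (a direction requirement would halve it). Knowledge is
counted per study event, not per unique cell, so the discovery count can
exceed the number of distinct true phenomena.

### Perturbations of the idealized community

* **p-hacking** (`perturbation("p_hack")`): the effective type-I error
  rate rises to $\alpha = .2$ for first-round tests and for
  private-regime replications by the same investigator; community
  replications in the public regime stay honest at the nominal
  $\alpha$. (The fraud simulation, where only community replications are
  honest, anchors this asymmetry.)
* **Optional stopping** (`perturbation("optional_stopping")`): a
  non-significant study adds batches of $N_{ph} \in \{1, 5, 10\}$
  participants and retests the full accumulated sample, up to five
  batches or until significance. This applies to first-round studies
  only (replications are single-shot by default). It inflates the
  realized type-I rate from .05 to about .08/.11/.13 for batch sizes
  1/5/10 and inflates participant counts — which the engine tracks
  separately, so the experiment-count cost metric is unaffected.
* **Fraud** (`perturbation("fraud")`): every first-round result is
  declared significant regardless of the data. Only the public regime is
  simulated (a fraudster would fake the private replication too), and
  community replications are honest.
* **No true effects**: set `grid_spec(p_h1 = 0)`; notables are then a
  pure type-I process.

## Randomness and reproducibility

All randomness flows through R's global RNG. `run_condition()` seeds a
generator from `config$seed`, draws one substream seed per Monte-Carlo
replication, and records it in the per-replication metrics, so any single
replication can be re-run in isolation. Running both regimes at the same
seed yields *identical first rounds*, which makes cost comparisons paired
rather than independent — the engine tests exploit this.

## Aggregates and their uncertainty

`run_condition()` returns per-replication metrics (total experiments,
notable/published/replicated counts, interesting successful replications,
those that are also true, participants) and aggregates with mean, SD and
Monte-Carlo standard error $\mathrm{SE} = \mathrm{SD}/\sqrt{R}$. At the
default $R = 1000$ the headline cost quantities carry SEs of about 0.1
experiments, so the reported contrasts (≈10 extra private experiments in
discovery mode; ≈40% extra relative effort for a perfect theory; ≥50%
in the symmetric Bayesian variant) are resolved far beyond their
tolerance.

## What the generator does and does not emulate

The synthetic community captures: a skewed, truth-independent interest
distribution; power/alpha calibrated inference; spatial clustering of
effects under theory guidance; and the cost asymmetry between the
regimes. It does not capture: citation dynamics over time, heterogeneous
effect sizes (all true effects are exactly 1), correlated cells beyond
the single 4 × 4 cluster, multi-round replication chains, publication
embargoes, or strategic investigator behavior. Passing tests therefore
certify the model's internal logic and calibration — not that real
scientific communities behave this way.

## Problem sizes used in the test suite

Module tests run conditions at 300–800 Monte-Carlo replications, where
the checked contrasts are already resolved at several standard errors;
the acceptance-style checks use the full 1000 replications of the study
design. Distributional oracles (type-I calibration, interest-rate
integrals, the optional-stopping inflation) use $2\times 10^4$ to
$2\times 10^5$ simulated studies, chosen so that three Monte-Carlo
standard errors are well inside each assertion's tolerance.

## A worked example

```{r example, eval = FALSE}
library(replisim)

priv <- run_condition(scenario_config(
  mode = "discovery", regime = "private",
  interest = interest_model(temperature = 5),
  n_replications = 1000, seed = 2026))
pub <- run_condition(scenario_config(
  mode = "discovery", regime = "public",
  interest = interest_model(temperature = 5),
  n_replications = 1000, seed = 2026))

priv$aggregate
pub$aggregate
```

Or run a whole preset grid and write CSV/JSON outputs:

```{r preset, eval = FALSE}
run_scenario("fig4_freq_p8", out_dir = "results")
```

## Known limitations

* The Bayesian prior scale ambiguity (above) shifts the Bayesian power
  within roughly [0.85, 0.92] over conventional scale choices; all
  qualitative contrasts are insensitive to it.
* The expected notable count in discovery mode is 11.82 by the exact
  noncentral-t power at $n = 34$ (0.8078), slightly above the
  back-of-envelope $0.8 \times 9 + 0.05 \times 91 = 11.75$ that treats
  power as exactly .8.
* Cost is measured in experiments; under optional stopping the extra
  participants are tracked but deliberately excluded from the cost
  metric so that regime comparisons remain in the same units.
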