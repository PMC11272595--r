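# circlequest

Simulation and analysis of hidden-circle information-sampling decision
tasks.

In this task family, a circle of fixed radius *r* is hidden on a screen.
Participants localize its centre by paying for binary point samples — a
tap reveals whether the sampled point lies inside or outside the circle —
and then place the circle where they believe it is. Each trial starts from
a credit reserve R0; every sample costs ηs credits and every pixel of
placement error costs ηe credits, so sampling trades uncertainty reduction
against its price. In companion passive designs, participants accept or
reject offers that combine reward, physical effort, and spatial
uncertainty. The paradigm probes how people balance the value of
information against its cost, and how that balance changes when reward and
effort sensitivity are blunted in specific contexts.

`circlequest` provides:

* a discrete Bayesian **ideal observer** over candidate circle centres
  with an expected-error (EE) uncertainty measure,
* the **credit economy**: trial scores, expected-value dynamics
  EV(s) = R0 − s·ηs − EE(s)·ηe, optimal sample counts s\*, and
  deviation-from-optimal,
* exponential **information-extraction-rate** fitting of EE trajectories,
* factorial **trial schedules** and banded **stimulus generators** for the
  four experiments,
* **synthetic cohorts**: logistic choosers with configurable
  reward/uncertainty/effort sensitivities, context attenuation, and a
  greedy information-optimal active-sampling policy with a subjective
  stopping rule,
* an **estimation pipeline**: per-subject logistic sensitivities with
  separation-robust fallback, confidence-calibration slopes, oversampling
  and cost-sensitivity metrics, normality-gated group contrasts, and
  robust volume–sensitivity regression with intracranial-volume
  adjustment.

## Worked example

Update an ideal observer with two dots, run one active-sampling trial for
a synthetic control participant under the high-reserve / high-cost
economy, and fit its extraction rate:

```r
library(circlequest)
set.seed(20)
sp <- search_space()                       # 1280 x 715 px, r = 130, grid step 4
b  <- init_posterior(sp)
b  <- update_posterior(b, 600, 350, "inside")
ee(b)
#> <EE 86.82 px at centroid (600.0, 350.0), support 3330>
b  <- update_posterior(b, 690, 420, "outside")
ee(b)
#> <EE 76.10 px at centroid (561.9, 319.8), support 1797>

econ  <- trial_economics(R0 = 130, eta_s = 5)
agent <- agent_params("control")
tr    <- active_sampling_episode(agent, econ, sp, true_center = c(640, 360))
tr
#> <cq_trajectory: 7 samples, final EE 11.7 px, error 13.4 px, score 79.0>

fit_extraction_rate(list(tr))
#>   trial_id     alpha ee_inf      sse converged flagged
#> 1        1 0.2335601  1e-09 6.373609      TRUE   FALSE
```

Each additional sample here removed about 23% of the remaining reducible
uncertainty (`alpha`), and the agent stopped once a further sample no
longer bought 5 credits' worth of expected-error reduction.

## Analysis workflow

The repository is organised as an analysis workflow over the package:
numbered drivers under `analysis/` simulate cohorts and write tables to
`results/`:

```sh
Rscript analysis/01_simulate.R              # cohorts for exps 1, 2, 4 -> results/runs/
Rscript analysis/02_active_sampling.R       # oversampling, cost sensitivity, speed-efficiency
Rscript analysis/03_passive_sensitivities.R # logistic sensitivities, contrasts, recovery
Rscript analysis/04_volume_regression.R     # ICV adjustment + robust volume regression
```

Raw run directories under `results/runs/` are regenerable and not version
controlled; the summary tables in `results/` are.

## Reproduction

`scripts/acceptance.R` recomputes the task's printed economy constants
from scratch against the installed package and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The full property-based acceptance suite (design counts, brute-force
oracle equivalence, extraction-rate recovery, stimulus band fidelity,
end-to-end sensitivity recovery and type-I calibration, active-sampling
phenotypes, and volume-adjustment identities) lives in
`tests/testthat/test-acceptance.R` and runs with the ordinary test suite.

A methods vignette (`vignettes/circlequest-methods.Rmd`) documents the
model, the generator's realism and limits, and the numerical choices.
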