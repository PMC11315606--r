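# threestage

Simulation and computational modelling of a two-choice, three-stage Markov
decision task used to study the balance between goal-directed (model-based,
MB) and habitual (model-free, MF) control — and its breakdown in disorders
of compulsivity. The package is aimed at computational-psychiatry
researchers who want to fit the task's dual-system models to trial-level
choice data, derive the arbitration measures those fits support, and
validate the whole pipeline on synthetic cohorts with known ground truth.

## What it implements

* **Task simulator** — the three-stage decision tree (one start state, four
  second-stage states, eight coloured-coin terminals), specific/flexible
  goal conditions, low/high transition uncertainty (0.9 vs 0.5 to the
  likely successor), and the 56-block session schedule (280 trials in
  expectation).
* **Model-free learner** — SARSA with reward-prediction errors
  δ = r(s′) + γQ(s′,a′) − Q(s,a), γ fixed at 1, values updated by αδ.
* **Model-based learner** — forward transition learning from
  state-prediction errors δ = 1 − T(s,a,s′) (update ηδ, row re-normalised),
  and backward goal-conditioned planning
  Q(s,a) = Σ T(s,a,s′)[r(s′) + max Q(s′,a′)] swept from the terminals.
* **Fitting** — per-subject maximum likelihood of (learning rate, softmax
  inverse temperature τ) for each model independently, multi-restart
  Nelder–Mead (200 restarts by default), AIC/BIC.
* **Arbitration metrics** — *system preference* (percentage of choices
  where the fitted MB model assigns the chosen action a higher likelihood
  than the fitted MF model) and *system switching* (percentage of adjacent
  choices whose dominant system changes), per goal condition and split by
  uncertainty, plus task performance and choice optimality.
* **Group statistics** — pooled two-sample t-tests (from raw vectors or
  printed mean/SD summaries), Benjamini–Hochberg FDR over the four measures
  per patient–control pair, Cohen's d, Pearson correlations, and a
  sex-covariate linear-model test.
* **Synthetic cohorts** — mixture agents blending the two systems with
  condition-dependent MB weights, for parameter-recovery and
  null-calibration studies; `run_pipeline()` goes from cohort specification
  to group statistics in one call.

## Worked example

```r
library(threestage)

tree <- build_default_tree()
agent <- agent_spec("mixture", alpha = 0.5, eta = 0.5, tau = 1,
                    w_specific = 0.8, w_flexible = 0.2)
session <- simulate_subject(agent, tree, seed = 42)

task_performance(session)          # 14.98 coins/trial
choice_optimality(session, tree)   # 86.4 %

fit_mb <- fit_model(session, tree, "mb", n_restarts = 20, seed = 1)
fit_mf <- fit_model(session, tree, "mf", n_restarts = 20, seed = 1)
fit_mb
#> <fit_result> model = MB | rate = 0.481 tau = 0.246 | NLL = 225.12 AIC = 454.23 BIC = 462.84
fit_mf
#> <fit_result> model = MF | rate = 0.565 tau = 0.123 | NLL = 263.87 AIC = 531.74 BIC = 540.35

subject_metrics(session, fit_mb, fit_mf, tree)[
  , c("preference_specific", "preference_flexible",
      "switching_specific", "switching_flexible")]
#>   preference_specific preference_flexible switching_specific switching_flexible
#> 1                64.0                70.1               38.3               41.9
```

The agent was built to lean on planning in specific blocks (w = 0.8) and on
cached values in flexible blocks (w = 0.2); the MB model wins the AIC
comparison by a wide margin (454 vs 532), and the subject's 273-trial
session earns about 15 coins per trial with 86% optimal decision sequences.
`compare_groups()` then contrasts whole cohorts of such subjects:

```r
res <- run_pipeline(list(seed = 1, n_restarts = 20,
  patient = list(label = "patient", n = 19,
                 agent = list(kind = "mixture", w_specific = 0.5, w_flexible = 0.4)),
  control = list(label = "control", n = 19,
                 agent = list(kind = "mixture", w_specific = 0.8, w_flexible = 0.2))),
  out_dir = "out")
res$stats   # one row per measure: means, SDs, t, FDR-corrected p, Cohen's d
```

Because `pooled_t()` and `cohens_d()` accept printed summaries, published
group tables can be re-derived without raw data:

```r
pooled_t(19, 23.84, 7.72, 19, 0.58, 0.69)$t   # 13.08
cohens_d(19, 44.81, 13.04, 19, 34.02, 10.36)  # 0.92
```

## Documentation

The methods vignette (`vignettes/three-stage-task-modelling.Rmd`) describes
the task, both learners, the fitting and identifiability properties, the
arbitration metrics, what the synthetic-cohort generator does and does not
emulate, and the package's numerical and design choices.
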