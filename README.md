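# survmixnet

Survival clustering with mixtures of monotone neural hazard networks.

## The problem

Clinical cohorts rarely behave like a single population: breast-cancer
registries, intensive-care cohorts and screening studies typically contain a
handful of survival *phenotypes* — subgroups whose time-to-event
distributions differ in shape, not just in scale. Classical tools force a
choice: Cox-type models give covariate effects but assume proportional
hazards and yield no subgroups; neural survival models fit flexible
individual curves but bury the population structure inside a black box.

`survmixnet` is for analysts who want both: it models a right-censored
outcome as a K-component mixture

S(t | x) = Σₖ αₖ(x) · exp(−Λₖ(t)),

where each component cumulative hazard Λₖ is a feed-forward neural network
constrained to be **positive and monotone in time** (squared weights on the
time path, tanh activations, value at t = 0 subtracted), conditioned on a
learnable latent cluster code rather than on covariates, and αₖ(x) is a
softmax assignment network reading only the covariates. The instantaneous
hazard λₖ = dΛₖ/dt is the exact derivative of the network, so the
right-censored likelihood

ℓ = Σ_{events} log Σₖ αₖ(xᵢ)λₖ(tᵢ)e^{−Λₖ(tᵢ)} + Σ_{censored} log Σₖ αₖ(xᵢ)e^{−Λₖ(tᵢ)}

is maximised *exactly* (log-domain, Adam, early stopping on a stratified
held-out split) — no time discretisation, no parametric family, no
proportional-hazards assumption. The fitted components are population-level
survival curves that can be plotted, summarised and tested directly; the
covariates only decide membership.

The package ships the full evaluation and interpretation stack: IPCW
time-dependent Brier score and concordance index at quantile horizons,
Kaplan–Meier utilities, cross-validation, hard assignment, per-cluster
summaries with log-rank tests, permutation importance of covariates, elbow
selection of K, seeded cohort simulators, CSV loading, checkpointing, and a
command-line interface (`inst/cli/survmixnet.R`).

## Worked example

```r
library(survmixnet)

sim <- simulate_clustered(sim_config(seed = 42))
sim
#> Simulated cohort: 2000 subjects, 3 covariates, 30.6% censored
#> Latent cluster sizes: 989, 1011

fit <- survmixnet(sim$x, sim$time, sim$event, k = 2, seed = 1)
fit
#> Survival mixture model: 2 component(s), neural hazard heads (2 x 50, latent 10)
#> Assignment network: 2 layer(s) x 50 nodes, dropout 0.10
#> Covariates: x1, x2, x3
#> Held-out NLL at early stop: 1.01004

ha <- hard_assign(fit, sim$x)
cluster_summaries(ha, sim$time, sim$event, x = sim$x)
#>  cluster    n population_pct censored_pct median_survival    mean_x1    mean_x2    mean_x3
#>        1  976        48.80 %      10.86 %        0.787195  0.4324321  0.6392432  0.2421460
#>        2 1024        51.20 %      49.51 %          4.4474 -0.4425743 -0.6336867 -0.2237842

pairwise_logrank(ha, sim$time, sim$event)
#>   cluster_a cluster_b statistic      p_value
#> 1         1         2  1412.574 3.89165e-309

mclust::adjustedRandIndex(ha$labels, sim$true_labels)
#> [1] 0.8854237

hz <- eval_times(sim$time, sim$event)          # 0.25/0.5/0.75 quantile horizons
pr <- predict(fit, sim$x, times = hz)
round(c(cindex = as.numeric(c_index(pr$survival[, 2], sim$time, sim$event, hz[2])),
        brier  = brier_score(pr$survival[, 2], sim$time, sim$event, hz[2])), 3)
#> cindex  brier
#>  0.859  0.128
```

Reading the output: the model recovered two phenotypes of roughly equal
size whose median survivals differ more than five-fold (0.79 vs 4.45 time
units; the short-lived cluster is also the heavily uncensored one), the
log-rank test confirms the curves are distinct, the hard labels agree with
the generating clusters (adjusted Rand index 0.89 against a stochastic
ground truth), and at the median event-time horizon the model discriminates
well (C-index 0.86) and is well calibrated (Brier 0.13).

Model selection helpers: `select_k()` (elbow rule on held-out NLL over
K), `random_search()` (the tuning grid: learning rate 1e-3/1e-4, batch
100/250, 1–3 layers × 50/100 nodes, K 2–5, latent dimension 10/50/100),
`cross_validate()` (5-fold metrics with shared horizons),
`permutation_importance()` (which covariates drive cluster membership).

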