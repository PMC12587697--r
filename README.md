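# causalblend

Individualized treatment effect estimation on binary outcomes by blending
two complementary estimators with a learned, per-unit weight:

* an **attention branch** — a memory-augmented multi-head attention
  network that predicts potential-outcome probabilities
  $\hat y(1 \mid x), \hat y(0 \mid x)$ by overriding its treatment input,
  and
* a **doubly robust (DR) branch** — cross-fitted random-forest outcome
  regressions $\hat\mu_t(x)$ and a ridge-logistic propensity $\hat e(x)$
  combined through the DR pseudo-outcome

$$\hat\tau_i = \frac{t_i - \hat e(x_i)}{\hat e(x_i)(1 - \hat e(x_i))}
  \bigl(y_i - \hat\mu_{t_i}(x_i)\bigr) + \hat\mu_1(x_i) - \hat\mu_0(x_i),$$

  with $\widehat{\mathrm{ATE}} = \frac1n\sum_i \hat\tau_i$ and a
  second-stage forest smoothing $\hat\tau(x)$.

A deterministic actor–critic agent (replay buffer, Ornstein–Uhlenbeck
exploration, Polyak targets) learns a blend weight $\alpha_i \in [0,1]$
per unit from a 7-component state (branch predictions, branch
uncertainties, propensity, overlap indicator, covariate balance), under a
causal-aware reward; the final prediction is the convex blend
$\hat y_i = \alpha_i \hat y_i^{\text{attn}} + (1-\alpha_i)\hat
y_i^{\text{DR}}$ and the individual effect is the difference of the
blended arm probabilities.

Around that core the package provides, as first-class tested modules:

* a fully specified **simulation benchmark** with known ground truth
  (confounders, an instrument, a mediator, age-modulated heterogeneous
  effects) and robustness knobs (sample size, confounding strength, noise
  scales, deliberate nuisance misspecification);
* **causal graph discovery** (linear Shapley attributions + DBSCAN parent
  screening, additive-noise/HSIC edge orientation, discrepancy-guided
  cycle removal) with expert-graph input, stability-based selection, and
  confounder/mediator/instrument role extraction;
* **MC-dropout uncertainty** with the aleatoric/epistemic decomposition,
  mixture-based 95% effect intervals, and mean-shift **concept drift**
  detection;
* the standard **metrics**: PEHE, ATE error/bias, ITE R², MAE, sd,
  coverage/calibration, accuracy/F1/AUC.

It is a tidyverse-native package: user-facing functions take a data frame
first and return tibbles, fitted objects have `tidy()`/`glance()`
methods and `autoplot()` plots.

## Worked example

```r
library(causalblend)

# the benchmark study: observed table (latent X7 withheld) + ground truth
study <- simulate_study(sim_config(n = 5000, seed = 42))
study
#> Simulated causal study: n = 5000 (seed 42 )
#>   observed columns: X0, X1, X2, X3, X4, X5, X6, X8, X9, Z, M, T, Y
#>   oracle probability-scale ATE: -0.3901

# the full stack on that study (reduced-width attention profile)
cfg <- run_config(sim = sim_config(n = 5000, seed = 42),
                  dag_source = "expert", seed = 17)
fit <- run_study(cfg)
fit
#> causal_study (variant full): 1000 test units
#>   PEHE 0.1174 | ATE error 0.02595 | ITE R2 0.4672
#>   accuracy 0.755 | F1 0.7334 | AUC 0.8136

fit$roles
#> confounders: X0, X2, X4
#> mediators:   M
#> instruments: Z

glance(fit)      # one-row metric summary
tidy(fit)        # per-test-unit alpha, arm probabilities, effect, interval
autoplot(fit)    # histogram of estimated individual effects
```

The printed numbers read as follows: on 1000 held-out units the blended
per-unit effects differ from the ground-truth probability contrasts by
0.117 RMSE (PEHE), the estimated average effect is within 0.026 of the
oracle average contrast (≈ −0.39: treatment *lowers* the outcome
probability in this design), and the blended factual probabilities
classify the observed outcomes with 75.5% accuracy.

A thin command-line wrapper over the same functions is installed at
`inst/cli/causalblend.R`, with subcommands `simulate`, `discover-graph`,
`fit`, `benchmark`, `evaluate`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "causalblend.R", package = "causalblend"))')" \
  simulate --n 5000 --seed 42 --out sim_out/
```

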