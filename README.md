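# banditbg

Basal-ganglia models of uncertainty-driven exploration in multi-armed bandit
tasks.

`banditbg` is for computational neuroscientists and decision-modelling
researchers who want to simulate, fit and benchmark a mechanistic account of
the exploration–exploitation trade-off: corticostriatal weights onto the
direct (D1, "GO") and indirect (D2, "NO-GO") pathways jointly learn the mean
`Q` and spread `S` of each action's reward distribution, and a phasic
dopamine **novelty signal** that decays with the number of times an action
has been chosen converts the spread into a posterior uncertainty that drives
exploration.

## The model in brief

Learning (idealised striatal rule, per chosen arm `c`):

    delta = R - Q_c
    Q_c <- Q_c + alpha_q * delta
    S_c <- S_c + alpha_s * (|delta| - S_c)

so `Q` converges to the mean reward and `S` to the mean absolute deviation.
Dopamine responds to an option chosen `n` times with

    D ~ N(m + k * n^pi, (a + b * (m + k * n^pi))^2)

(defaults `a = 1.380`, `b = 0.306`, `m = 0.677`, `k = 4.486`, `pi = -0.791`,
estimated from dopaminergic firing rates; the ideal inverse-square-root form
is the nested case `m = a = 0`, `pi = -1/2`). The thalamic value utility

    T_i = Q_i + lambda * D_i * S_i + e * Z

then implements a hybrid of directed (UCB-like) and random (Thompson-like)
exploration: the deterministic part of `lambda * D * S` is an uncertainty
bonus proportional to `sigma_hat_i = S_i * n_i^pi`, and its stochastic part
scales choice noise by the same uncertainty. Closed-form two-arm choice
probabilities are available for all strategies (neural and Kalman-filter
families), each verified against brute-force Monte-Carlo simulation of its
utility definition.

The package covers:

* bandit task construction (a five-task benchmark catalogue plus custom
  JSON/YAML specs), reward sampling and per-trial regret;
* GO/NO-GO and Kalman learning rules, novelty-modulated dynamic learning
  rates, posterior-uncertainty mapping;
* exploration strategies and choice probabilities, plus the classic UCB1,
  UCB2, UCB1-tuned and UCB1-normal baselines;
* maximum-likelihood fitting of novelty-decay curves (power, inverse-sqrt,
  exponential) to firing-rate tables, hierarchical per-neuron fitting, and
  the mean–s.d. regression;
* trial-by-trial behavioural model fitting (eight strategy rows) with
  BIC/AIC comparison and within-subject standard errors;
* synthetic data generators with stored ground truth, and a simulation
  harness with per-task parameter optimisation.

## Worked example

Benchmark the neural strategy with novelty-decaying learning rates against
plain UCB1 on the ten-arm Gaussian task, then fit the novelty curve to
synthetic firing rates:

```r
library(banditbg)

task <- make_task("ten_arm_gaussian_C")   # K = 10, sigma = 0.3, one best arm
neural <- sim_strategy("neural", lambda = 0.5, alpha_q = 0.2, alpha_s = 0.1,
                       pi = -0.5, rate_mode = "dynamic")
run_experiment(neural, task, n_runs = 100, master_seed = 1)
#> <bb_regret neural on ten_arm_gaussian_C: total regret 25.666 over 2000 trials (100 runs)>
run_experiment(sim_strategy("ucb1"), task, n_runs = 100, master_seed = 1)
#> <bb_regret ucb1 on ten_arm_gaussian_C: total regret 159.253 over 2000 trials (100 runs)>

g <- gen_dopamine_traces(seed = 1)        # 58 neurons x 15 presentations
fit_average_curve(g$traces, "power")
#> <bb_fit power: m = 0.4685, k = 4.336, pi = -0.6741 | lnL = -3.071, BIC = 16.974, N = 15>
reg <- mean_sd_regression(g$traces)
sprintf("a = %.3f, b = %.3f, r = %.3f", reg$a, reg$b, reg$r)
#> [1] "a = 1.330, b = 0.372, r = 0.839"
```

The first two lines say the novelty-driven agent loses about 26 units of
expected reward over a 2000-trial block where UCB1 loses about 159 — the
dynamic-rate neural strategy resolves the 0.1 reward margin much faster.
The curve fit recovers the generating power-law decay (true
`pi = -0.791`, here estimated `-0.674` from one noisy draw of the 58-neuron
design), and the mean–s.d. regression recovers the affine noise relation
(truth `a = 1.380`, `b = 0.306`).

Behavioural fitting works the same way from data frames or CSVs
(`participant_id, block, trial, choice, reward`):

```r
rows <- table1_strategies()
g <- gen_choice_dataset(5, rows$bg_hybrid,
                        c(alpha_q = 0.4, alpha_s = 0.2, lambda = 0.5, e = 1))
cmp <- model_comparison(g$data, rows[c("bg_hybrid", "bg_value")],
                        n_starts = 10)
cmp$summary
```

A thin command-line front-end over these functions ships at
`inst/cli/banditbg.R` (subcommands `synth`, `simulate`, `optimize`,
`fit-neural`, `fit-behavior`, `compare`).

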