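---
title: "Striatal learning, dopamine novelty and uncertainty-driven exploration: models and methods"
author: "banditbg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Striatal learning, dopamine novelty and uncertainty-driven exploration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(banditbg)
```

## The problem

In a stationary multi-armed bandit, an agent repeatedly chooses one of $K$
arms and receives a stochastic reward; good performance requires balancing
exploitation of the empirically best arm against exploration of uncertain
ones. Normative accounts drive exploration with the *posterior uncertainty*
$\sigma_i$ of each arm's mean-reward estimate $Q_i$: directed exploration
(UCB) adds a deterministic bonus $\theta\sigma_i$, random exploration
(Thompson sampling) scales choice noise by $\gamma\sigma_i$, and human choice
data are best described by a hybrid of the two. `banditbg` implements a
mechanistic account of how the basal ganglia could compute these quantities:
corticostriatal weights onto the direct (D1, "GO") and indirect (D2,
"NO-GO") pathways learn the mean and spread of each action's reward, and a
phasic dopamine signal that decays with the number of times an action has
been taken converts the spread into a posterior uncertainty.

## Learning rules

The basic GO/NO-GO rule updates the weights of the chosen arm $c$ with an
asymmetric piecewise-linear activation $f_\epsilon$ ($f_\epsilon(x) = x$ for
$x > 0$, $\epsilon x$ for $x < 0$, $0 < \epsilon < 1$) applied to the reward
prediction error $\delta = R - (G_c - N_c)/2$:

$$G_c \leftarrow G_c + \alpha f_\epsilon(\delta) - \beta G_c, \qquad
  N_c \leftarrow N_c + \alpha f_\epsilon(-\delta) - \beta N_c.$$

Substituting $Q = (G - N)/2$ and $S = (G + N)/2$ turns this into a delta rule
on $Q$ with rate $\alpha(1+\epsilon)/2$ and a rectified rule on $S$ with rate
$\alpha(1-\epsilon)/2$; `update_gn_basic()` and the transformed form agree to
machine precision (this identity is a test). The idealised rule
(`update_qs_idealised()`)

$$Q_c \leftarrow Q_c + \alpha_q \delta, \qquad
  S_c \leftarrow S_c + \alpha_s(|\delta| - S_c)$$

has the stationary point $Q^* = E[R]$, $S^* = E|R - E[R]|$ (the mean absolute
deviation: $2p(1-p)$ for Bernoulli rewards, $\sigma\sqrt{2/\pi}$ for Gaussian
ones). The model constraint $\alpha_q > \alpha_s$ is enforced as a validation
warning, not an error, so that boundary cases remain explorable.

A Kalman filter over a stationary Gaussian bandit
(`kalman_state()`/`update_kalman()`) serves as the normative baseline
learner; its posterior variance after $j$ observations is exactly
$(1/v_0 + j/v_r)^{-1}$, which the tests check in closed form.

## The dopamine novelty signal

The novelty component of the phasic dopamine response to an option chosen
$n$ times is modelled as a Gaussian whose mean and spread both decay with
$n$. The *ideal* form $D = (\nu + \eta Z)/\sqrt{n}$ makes
$\lambda D S$ exactly a noisy multiple of the central-limit posterior
uncertainty $S/\sqrt{n}$. The *refined* form, whose constants were estimated
from dopaminergic firing-rate recordings, is

$$D \sim N\!\big(m + k n^\pi,\ (a + b(m + k n^\pi))^2\big),$$

with package defaults $a = 1.380$, $b = 0.306$, $m = 0.677$, $k = 4.486$,
$\pi = -0.791$. The ideal form is the nested case $m = a = 0$, $k = \nu$,
$b = \eta/\nu$, $\pi = -1/2$. Posterior uncertainty generalises to
$\hat\sigma = S n^\pi$ (`posterior_uncertainty()`).

One modelling commitment deserves emphasis: **a single dopamine draw per arm
per trial** drives both the spread term and the uncertainty term of that
arm's thalamic utility

$$T_i = Q_i + \lambda D_i S_i + eZ
      = Q_i + \lambda\big((m + (a+bm)Z_i)S_i + (k + bkZ_i)\hat\sigma_i\big) + eZ'_i .$$

Because the same $Z_i$ multiplies both components, the per-arm utility noise
has standard deviation $\lambda((a+bm)S_i + bk\hat\sigma_i)$ — the *squared
sum*, not a sum of squares — and the two-arm choice probability implemented
in `choice_prob_two_arm()` is

$$p(c{=}1) = \Phi\!\left(
  \frac{Q_1 - Q_2 + \lambda m(S_1 - S_2) + \lambda k(\hat\sigma_1 - \hat\sigma_2)}
       {\sqrt{\lambda^2\big((a{+}bm)S_1 + bk\hat\sigma_1\big)^2
             + \lambda^2\big((a{+}bm)S_2 + bk\hat\sigma_2\big)^2 + 2e^2}}\right).$$

A variant that treats the two noise components as independent would drop the
cross term $2(a{+}bm)bk\,S_i\hat\sigma_i$ from each squared weight; we use the
exact single-draw variance because it is the one consistent with the
generative dopamine model, and the package's central oracle test verifies
every closed form against a Monte-Carlo simulation of its own utility
definition ($10^6$ draws, agreement within three binomial standard errors).
The two expressions coincide whenever either noise component vanishes: for
the directed configuration ($a = b = 0$) and for the ideal model, where the
probability reduces to

$$\Phi\!\left(\frac{Q_1 - Q_2 + \lambda\nu(\sigma_1 - \sigma_2)}
  {\sqrt{\lambda^2\eta^2(\sigma_1^2 + \sigma_2^2) + 2e^2}}\right),$$

which nests a pure UCB strategy at $\eta = 0$ and a pure Thompson-type
strategy at $\nu = 0$. The neural *random* strategy keeps only the noise
components (no deterministic dopamine bias) with $e = 0$.

The Kalman-family closed forms are
$\Phi\big((\Delta Q + \theta\Delta\sigma)/\sqrt{2e^2}\big)$ (directed),
$\Phi\big(\Delta Q/\sqrt{\gamma^2(\sigma_1^2+\sigma_2^2)}\big)$ (random) and
the hybrid rule
$\Phi\big(\gamma\Delta Q/\sqrt{\sigma_1^2+\sigma_2^2} + \theta\Delta\sigma\big)$,
which is defined directly as a choice rule: it cannot be derived from
per-arm utilities, so it is restricted to two-armed tasks and excluded from
$K>2$ simulations.

Negative dopamine draws are permitted (no truncation) because the closed
forms assume an untruncated Gaussian; a truncation flag exists but defaults
off. Whether the noise term reflects within-neuron variability or
across-neuron heterogeneity is left open by the data; it is implemented as a
single abstract noise source.

## Curve fitting to firing-rate data

`fit_average_curve()` fits three candidate decay functions to per-index
average rates: $m + k/\sqrt{n}$, $m + kn^\pi$ and $m + ke^{\pi n}$. The
likelihood is Gaussian with iid residuals and the residual s.d. profiled out
analytically, so maximisation reduces to least squares;
$\ln\hat L = -\tfrac{N}{2}(\ln(2\pi\,\mathrm{RSS}/N) + 1)$. BIC and AIC count
the residual s.d. as a parameter — a convention that shifts every family
equally and therefore cannot change a ranking. Optimisation is multi-start
Nelder–Mead simplex: starts are laid on a grid of shape values over
$[-3, -0.01]$ with $(m, k)$ profiled by OLS at each start. The linear
parameters are box-constrained to generous data-driven ranges ($m$ within
the observed range $\pm 2$ spreads, $k \in [0, 10\,\text{spreads}]$), which
matters only for noisy single-neuron traces where the $m/k/\pi$ likelihood
ridge would otherwise let estimates run away. Standard errors use the usual
nonlinear-least-squares curvature $\hat\sigma^2(J^\top J)^{-1}$ with the
analytic Jacobian.

`fit_per_neuron_hierarchical()` approximates a nonlinear mixed-effects model
in two stages: per-neuron ML fits, then population fixed effects as the
parameter means and random effects as their covariance (joint) or variances
(independent), with a Laplace-style plug-in marginal likelihood. This is an
approximation chosen for transparency, not a replication of any black-box
mixed-effects implementation; recovery on synthetic data — not agreement
with any particular software's BIC values — is the accuracy contract. One
consequence worth knowing: when measurement noise is large, per-neuron
estimation errors are strongly correlated along the likelihood ridge, so the
joint random-effects model can legitimately win BIC even when the true
population parameters are uncorrelated. The tests therefore exercise the
joint-vs-independent comparison at low measurement noise.

`mean_sd_regression()` regresses the across-neuron s.d. of the rate on its
mean, by OLS, one point per presentation index. Because the regressor is
itself an estimated mean, the slope carries a small errors-in-variables
attenuation (about $-0.02$ at 58 neurons); the recovery tests assess the
estimate distribution against the truth rather than relying on nominal
per-fit coverage for the slope.

## Behavioural model fitting

`table1_strategies()` defines eight trial-by-trial choice models: the
cross of two learning rules (Kalman filter; basal-ganglia idealised rule)
and four exploration types (hybrid, directed, random, value-only). Neural
rows fix the dopamine constants at the firing-rate estimates; the value row
is plain Rescorla–Wagner with unmodulated noise. `choice_negloglik()`
accumulates $-\ln p(c[t])$ with all latent states reset at block boundaries,
evaluating the closed-form probability *before* updating the learner with
the observed choice and reward. Probabilities are floored at $10^{-10}$;
fully symmetric zero-noise states (the first trial of a block under the
task-D initialisation $Q = S = 0$) resolve to $p = 0.5$.

`fit_participant()` runs bounded L-BFGS-B from random starts drawn uniformly
within box bounds: $\alpha_q, \alpha_s \in [0,1]$ (with the
$\alpha_q > \alpha_s$ preference advisory only), $\lambda \in [0, 50]$
($\lambda > 0$ for the random row), $e \in [0, 100]$, $\theta \in [-50, 50]$,
$\gamma \in (0, 50]$. The per-arm choice count uses a pseudocount of one at
block start (one virtual observation, consistent with initialising the
estimators themselves); the data do not pin down any particular $n = 0$
convention, so ours is documented rather than asserted. BIC uses the total
trial count per participant (200 under the emulated design).

Two fitting caveats are documented deliberately. First, $\lambda$ and
$\alpha_s$ share a likelihood ridge — $\lambda$ multiplies $S$ everywhere,
and over ten-trial blocks the scale of $S$ is roughly proportional to
$\alpha_s$ — so individual $\hat\lambda$ values are noisy and can hit the
box bound; identifiability is assessed at the population level (positive
true-vs-fitted correlation across participants). Second, the directed row
($a = b = 0$) is not nested in the hybrid row (which fixes $a, b$ at their
estimated values with the same four free parameters), so log-likelihood
monotonicity is only checked for the genuinely nested pairs (value within
hybrid and within directed, via $\lambda = 0$).

## Synthetic data

The generators are first-class, tested code and define the study conditions:

* `gen_dopamine_traces()` — 58 neurons × 15 presentation indices by default,
  rates drawn from the refined dopamine model at the default constants;
  optional per-neuron random effects (normal on $m$ and $\pi$, log-normal on
  $k$ to keep the mean response positive, or a joint Gaussian on
  $(m, \log k, \pi)$). Gaussian noise is a documented simplification — real
  normalised rates may be skewed — so passing recovery tests demonstrates
  correctness of the fitting machinery, not distributional realism.
* `gen_choice_dataset()` — per participant, 20 blocks of 10 trials on the
  two-armed task with block means redrawn from $N(0, 100)$ and reward
  variance 10; choices sampled from the strategy's own closed-form
  probabilities. For recovery studies the per-participant truth is drawn
  once as $\alpha_q \sim U(0.2, 0.6)$,
  $\alpha_s = \alpha_q \cdot U(0.3, 0.8)$, $\lambda \sim U(0.2, 1)$,
  $e \sim U(0.5, 2)$ — behaviourally plausible ranges on the task's reward
  scale, with heterogeneity in $\lambda$ required for the
  recovery-correlation check.

Both emit CSVs with a two-line provenance header (package version, seed,
spec hash) and are byte-reproducible under a fixed seed.

## Simulation benchmark

`run_experiment()` aggregates per-trial regret
($\max_j E[R_j] - E[R_{c[t]}]$) over independent seeded runs; run seeds
derive from the master seed, so candidates compared under one master seed
share reward streams (common random numbers), sharpening orderings at
reduced run counts. The task catalogue fixes the benchmark designs; the
ten-arm margins ($0.55/0.45$ Bernoulli, $0.9/0.8$ Bernoulli, Gaussian
$0.55/0.45$ with $\sigma = 0.3$) and horizons are package defaults,
overridable in every constructor. Horizons are $\tau = 2000$ for the
ten-arm tasks and $1000$ for the six-arm task: long enough that the
UCB1-normal forced-play phase ($n_j < \lceil 8\ln t\rceil$ per arm, about
600 of 2000 trials at ten arms) occupies a minority of the block, so that
the classic orderings can express, while keeping a full benchmark under a
few minutes of CPU. Benchmark comparisons use 200 runs per cell (the
full-scale protocol uses 1000, or 20000 for the two-arm task); standard
errors at 200 runs are small relative to every ordering asserted.

Simulation agents follow the deterministic configuration used for fair
comparison with the classic algorithms: $e = 0$, and for neural strategies
$a = b = m = 0$, $k = 1$, leaving the deterministic index
$Q_i + \lambda S_i n_i^\pi$. Dynamic learning rates decay as
$\alpha_0 (m + kn^\pi)/(m + k)$ — with the simulation constants simply
$\alpha_0 n^\pi$ — and are clipped to $[0,1]$. Estimators initialise at
$0.5$ (0 for the mean-resampling task) with a choice pseudocount of 1;
classic UCB variants instead use their own forced initial plays. Free
parameters ($\lambda$, rates, $\theta$) are tuned per task by
`optimize_strategy_params()`, a coarse grid search minimising total regret
under common random numbers, mirroring the protocol under which the
strategies are compared. The weight decay $\beta$ of the basic rule applies
to the chosen arm only by default (updates are written for the chosen arm);
a global-decay flag exists.

Plug-in agents can be added through `register_sim_agent()` without touching
the core — this is the extension point for external actor-critic models
that are out of scope here.

## Numerical choices and degenerate inputs

* Choice probabilities with a zero denominator: $0/0$ raises an error unless
  the documented tie-break flag returns 0.5 (always used inside likelihood
  evaluation); a nonzero numerator over zero yields the degenerate 0/1.
* Ties in action selection are broken uniformly at random from the caller's
  seeded stream; forced-play arms take absolute priority, lowest index
  first.
* Learning-rate clipping to $[0,1]$ after the dynamic-rate formula keeps the
  values interpretable as learning rates.
* Arm indexing is 1-based everywhere in files and reports.
* CSV rates/rewards are written with 17 significant digits so round-trips
  are lossless.

## Problem sizes used by the tests and the acceptance script

The test suite uses: 100 random trajectories for the rule-equivalence
identity; 20 chains of $2\times10^4$ trials for stationary-point
convergence; $10^6$ utility draws per state for the choice-probability
oracle (20 states per strategy); 100 replicates of the 58×15 trace design
for curve-fit recovery; 50 synthetic participants at 10 optimiser starts for
behavioural recovery; and 200 runs per benchmark cell. The acceptance script
repeats the main computations at 50 participants and 100 runs and writes the
resulting quantities as JSON. These sizes are the package's scaled-down
defaults chosen to keep a complete desk run in minutes; all of them can be
raised through the corresponding function arguments.

## Known limitations

* Stationary tasks only: the novelty signal is monotone in the choice count,
  which is the wrong uncertainty signal under drifting or switching reward
  distributions (a non-goal here).
* The hierarchical fit is a two-stage approximation; its BIC is a plug-in
  approximation to the marginal likelihood.
* $S$ converges to the mean absolute deviation, not the standard deviation,
  so $S n^{-1/2}$ is a proportional (not unbiased) posterior-uncertainty
  estimate.
* Individual-level $\hat\lambda$ is weakly identified from 200 trials (see
  above); only population-level statements are supported at that data size.
* The Kalman hybrid rule is two-arm only by construction.
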