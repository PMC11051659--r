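#' Learner state for the GO/NO-GO (direct/indirect pathway) model
#'
#' Holds the per-arm quantities tracked by the corticostriatal learning rules:
#' the GO weight G (cortex to D1, direct pathway) and NO-GO weight N (cortex
#' to D2, indirect pathway), together with their transformed representation
#' Q = (G - N)/2 (mean-reward estimate) and S = (G + N)/2 (reward-spread
#' estimate), a per-arm choice count n and the trial index t. Both
#' representations are maintained consistently; updates through either rule
#' keep G = S + Q and N = S - Q.
#'
#' The choice count starts at a pseudocount of 1 (one virtual observation,
#' matching the initialisation of the estimators themselves), which keeps
#' n^pi finite at the first choice. Set `n0` to 0 only if a forced play of
#' each arm will occur before any novelty computation.
#'
#' @param K Number of arms.
#' @param q0,s0 Initial mean and spread estimates (0.5 for the fixed
#'   benchmark tasks, 0 for the mean-resampling two-arm task).
#' @param n0 Initial per-arm choice pseudocount (default 1).
#' @return An object of class `"bb_learner"`.
#' @export
learner_state <- function(K, q0 = 0.5, s0 = 0.5, n0 = 1) {
  stopifnot(K >= 1, s0 >= 0, n0 >= 0)
  st <- list(Q = rep(as.numeric(q0), K), S = rep(as.numeric(s0), K),
             G = rep(s0 + q0, K), N = rep(s0 - q0, K),
             n = rep(as.numeric(n0), K), t = 1L, K = as.integer(K))
  class(st) <- "bb_learner"
  st
}

#' Learning-rate and decay parameters for the striatal rules
#'
#' @param alpha_q Mean-estimate learning rate in \[0, 1\].
#' @param alpha_s Spread-estimate learning rate in \[0, 1\]. The model
#'   constraint alpha_q > alpha_s is checked with a warning (not an error).
#' @param alpha0_q,alpha0_s Initial rates for the dynamic (novelty-decaying)
#'   variant; default to `alpha_q`/`alpha_s`.
#' @param epsilon Asymmetry factor of the piecewise-linear activation in the
#'   basic rule, in (0, 1).
#' @param beta Weight-decay factor of the basic rule, >= 0.
#' @param rate_mode `"fixed"` or `"dynamic"`.
#' @return An object of class `"bb_lparams"`.
#' @export
learning_params <- function(alpha_q = 0.1, alpha_s = 0.05,
                            alpha0_q = alpha_q, alpha0_s = alpha_s,
                            epsilon = 0.5, beta = 0,
                            rate_mode = c("fixed", "dynamic")) {
  rate_mode <- match.arg(rate_mode)
  stopifnot(alpha_q >= 0, alpha_q <= 1, alpha_s >= 0, alpha_s <= 1,
            epsilon > 0, epsilon < 1, beta >= 0)
  if (alpha_q <= alpha_s)
    warning("model constraint alpha_q > alpha_s is violated")
  structure(list(alpha_q = alpha_q, alpha_s = alpha_s,
                 alpha0_q = alpha0_q, alpha0_s = alpha0_s,
                 epsilon = epsilon, beta = beta, rate_mode = rate_mode),
            class = "bb_lparams")
}

# piecewise-linear activation: identity for positive input, slope epsilon for
# negative input
.f_eps <- function(x, epsilon) ifelse(x > 0, x, epsilon * x)

#' Basic GO/NO-GO learning update
#'
#' One trial of the basic corticostriatal rule. The reward prediction error is
#' delta = R - (G_c - N_c)/2; the GO weight of the chosen arm is reinforced by
#' the positively-rectified error and the NO-GO weight by the negatively
#' rectified error, both through the asymmetric piecewise-linear activation
#' f_eps (slope 1 for positive input, epsilon for negative), with multiplicative
#' decay beta keeping the weights bounded:
#' \deqn{G_c \leftarrow G_c + \alpha f_\epsilon(\delta) - \beta G_c,\qquad
#'       N_c \leftarrow N_c + \alpha f_\epsilon(-\delta) - \beta N_c.}
#' The learning rate used is `alpha_q + alpha_s` of `params` (the basic rule's
#' alpha, such that the transformed rule has rates alpha(1+eps)/2 and
#' alpha(1-eps)/2). By default decay applies to the chosen arm only; set
#' `global_decay = TRUE` to decay every arm.
#'
#' @param state A [learner_state()].
#' @param chosen 1-based chosen arm.
#' @param reward Scalar reward received.
#' @param params A [learning_params()]; its `epsilon`, `beta` and the rate
#'   `alpha = alpha_q + alpha_s` are used (this parameterisation makes the
#'   transformed rule's rates exactly `alpha_q` and `alpha_s`... see Details).
#' @param global_decay Apply beta decay to unchosen arms too (default FALSE).
#'
#' @details With alpha the basic rule's learning rate and epsilon its
#' asymmetry, the substitution Q = (G - N)/2, S = (G + N)/2 yields the
#' transformed rule with rates alpha_q = alpha(1+eps)/2 on |Q| and
#' alpha_s = alpha(1-eps)/2 on S. `update_gn_basic` takes the basic rule's
#' alpha as `params$alpha_q + params$alpha_s` so that the two rules can be
#' driven from one parameter object; the equivalence holds when
#' `epsilon = (alpha_q - alpha_s)/(alpha_q + alpha_s)`.
#'
#' @return Updated learner state (Q, S, G, N, n, t all advanced).
#' @export
update_gn_basic <- function(state, chosen, reward, params,
                            global_decay = FALSE) {
  stopifnot(inherits(state, "bb_learner"), inherits(params, "bb_lparams"))
  if (!is.finite(reward)) stop("non-finite reward")
  if (chosen < 1 || chosen > state$K) stop("arm index out of range")
  alpha <- params$alpha_q + params$alpha_s
  eps <- params$epsilon
  beta <- params$beta
  delta <- reward - (state$G[chosen] - state$N[chosen]) / 2
  g_new <- state$G[chosen] + alpha * .f_eps(delta, eps) -
    beta * state$G[chosen]
  n_new <- state$N[chosen] + alpha * .f_eps(-delta, eps) -
    beta * state$N[chosen]
  if (global_decay && beta > 0) {
    state$G <- state$G * (1 - beta)
    state$N <- state$N * (1 - beta)
  }
  state$G[chosen] <- g_new
  state$N[chosen] <- n_new
  state$Q <- (state$G - state$N) / 2
  state$S <- (state$G + state$N) / 2
  state$n[chosen] <- state$n[chosen] + 1
  state$t <- state$t + 1L
  state
}

#' Idealised Q/S learning update
#'
#' One trial of the idealised striatal rule, a delta rule on the mean estimate
#' and a convex-combination rule on the spread estimate:
#' \deqn{\delta = R - Q_c,\quad Q_c \leftarrow Q_c + \alpha_q \delta,\quad
#'       S_c \leftarrow S_c + \alpha_s(|\delta| - S_c).}
#' At stationarity Q converges to the mean reward and S to the mean absolute
#' deviation of the reward distribution. Unchosen arms are untouched; the
#' chosen arm's count increments by one.
#'
#' @param state A [learner_state()].
#' @param chosen 1-based chosen arm.
#' @param reward Scalar reward.
#' @param params A [learning_params()].
#' @param rates Optional length-2 numeric `c(alpha_q, alpha_s)` overriding the
#'   fixed rates (used by the dynamic-rate variant).
#' @return Updated learner state.
#' @export
update_qs_idealised <- function(state, chosen, reward, params, rates = NULL) {
  stopifnot(inherits(state, "bb_learner"))
  if (!is.finite(reward)) stop("non-finite reward")
  if (chosen < 1 || chosen > state$K) stop("arm index out of range")
  if (is.null(rates)) rates <- c(params$alpha_q, params$alpha_s)
  delta <- reward - state$Q[chosen]
  state$Q[chosen] <- state$Q[chosen] + rates[1] * delta
  state$S[chosen] <- state$S[chosen] + rates[2] * (abs(delta) - state$S[chosen])
  state$G <- state$S + state$Q
  state$N <- state$S - state$Q
  state$n[chosen] <- state$n[chosen] + 1
  state$t <- state$t + 1L
  state
}

#' Novelty-modulated dynamic learning rates
#'
#' Learning rates that decay with the choice count following the dopamine
#' novelty-response curve, normalised to equal the initial rates at n = 1:
#' \deqn{\alpha_q[n] = \alpha_{0,q}\,\frac{m + k n^\pi}{m + k},\qquad
#'       \alpha_s[n] = \alpha_{0,s}\,\frac{m + k n^\pi}{m + k}.}
#' Both results are clipped to \[0, 1\].
#'
#' @param n Choice count (>= 1, after pseudocount).
#' @param params A [learning_params()] supplying `alpha0_q`, `alpha0_s`.
#' @param dmodel A [dopamine_model()] supplying `m`, `k`, `pi`.
#' @return Numeric `c(alpha_q, alpha_s)`.
#' @export
dynamic_learning_rates <- function(n, params, dmodel) {
  if (any(n < 1)) stop("choice count must be >= 1 (after pseudocount)")
  if (dmodel$m + dmodel$k == 0) stop("m + k must be positive")
  ratio <- (dmodel$m + dmodel$k * n ^ dmodel$pi) / (dmodel$m + dmodel$k)
  pmin(pmax(c(params$alpha0_q * ratio, params$alpha0_s * ratio), 0), 1)
}

#' Posterior uncertainty from reward spread and choice count
#'
#' Converts the learned reward-spread estimate S into a posterior uncertainty
#' about the mean reward, \eqn{\hat\sigma = S n^\pi}. With pi = -1/2 this is
#' the central-limit S/sqrt(n); the data-derived value pi = -0.791 gives a
#' faster decay.
#'
#' @param S Spread estimate(s), >= 0.
#' @param n Choice count(s), >= 1 (after pseudocount).
#' @param pi Power parameter (negative for decaying uncertainty).
#' @return \eqn{S n^\pi}, vectorised over inputs.
#' @export
posterior_uncertainty <- function(S, n, pi = -0.5) {
  if (any(S < 0)) stop("spread estimate S must be nonnegative")
  if (any(n < 1)) stop("choice count must be >= 1 (after pseudocount)")
  S * n ^ pi
}

#' Kalman filter state for a stationary Gaussian bandit
#'
#' Conjugate-normal tracking of each arm's mean reward: posterior mean Q and
#' posterior variance per arm, with a shared prior and known reward variance.
#' There is no diffusion term (the task is stationary within a block).
#'
#' @param K Number of arms.
#' @param prior_mean Prior mean of each arm's mean reward.
#' @param prior_var Prior variance (> 0).
#' @param reward_var Reward (observation) variance (> 0).
#' @return An object of class `"bb_kalman"`.
#' @export
kalman_state <- function(K, prior_mean = 0, prior_var = 100, reward_var = 10) {
  stopifnot(K >= 1, prior_var > 0, reward_var > 0)
  structure(list(Q = rep(as.numeric(prior_mean), K),
                 var = rep(as.numeric(prior_var), K),
                 prior_mean = prior_mean, prior_var = prior_var,
                 reward_var = reward_var, K = as.integer(K)),
            class = "bb_kalman")
}

#' Kalman filter update for the chosen arm
#'
#' Standard conjugate update with gain g = var_c / (var_c + reward_var):
#' the posterior mean moves by g times the prediction error and the posterior
#' variance shrinks to (1 - g) var_c. Other arms are unchanged.
#'
#' @param state A [kalman_state()].
#' @param chosen 1-based chosen arm.
#' @param reward Observed reward.
#' @return Updated Kalman state.
#' @export
update_kalman <- function(state, chosen, reward) {
  stopifnot(inherits(state, "bb_kalman"))
  if (chosen < 1 || chosen > state$K) stop("arm index out of range")
  if (!is.finite(reward)) stop("non-finite reward")
  if (state$var[chosen] <= 0 || state$reward_var <= 0)
    stop("variances must be positive")
  g <- state$var[chosen] / (state$var[chosen] + state$reward_var)
  state$Q[chosen] <- state$Q[chosen] + g * (reward - state$Q[chosen])
  state$var[chosen] <- (1 - g) * state$var[chosen]
  state
}
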