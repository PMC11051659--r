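#' Exploration strategy parameters
#'
#' Bundles the learning rule and exploration type with the weighting
#' parameters of the corresponding value utility:
#' \describe{
#'   \item{Kalman family}{`directed` (UCB): V = Q + theta*sigma + e*Z;
#'     `random` (Thompson): V = Q + gamma*sigma*Z; `value`: V = Q + e*Z;
#'     `hybrid`: no explicit utility exists -- only the two-arm closed-form
#'     choice probability (see [choice_prob_two_arm()]).}
#'   \item{Basal-ganglia (neural) family}{thalamic utility
#'     T = Q + lambda*D*S + e*Z with D a dopamine novelty draw
#'     ([sample_dopamine()]); `directed` uses a noiseless dopamine model
#'     (a = b = 0), `random` drops the deterministic dopamine bias and fixes
#'     e = 0, `value` reduces to Rescorla-Wagner with unmodulated noise.}
#' }
#' Noise convention: the `e*Z` term uses an independent standard-normal draw
#' per arm, so the two-arm utility difference has variance 2e^2.
#'
#' @param learning_rule `"basal_ganglia"` or `"kalman"`.
#' @param exploration `"hybrid"`, `"directed"`, `"random"` or `"value"`.
#' @param theta Directed-exploration weight (Kalman family).
#' @param gamma Random-exploration weight (Kalman family), > 0.
#' @param e Unmodulated noise s.d., >= 0.
#' @param lambda Dopaminergic gain (neural family); must be > 0 for the
#'   neural random strategy.
#' @param dopamine A [dopamine_model()] (neural family).
#' @param learning A [learning_params()] (neural family).
#' @return An object of class `"bb_strategy"`.
#' @export
strategy_params <- function(learning_rule = c("basal_ganglia", "kalman"),
                            exploration = c("hybrid", "directed", "random",
                                            "value"),
                            theta = 0, gamma = 1, e = 0, lambda = 1,
                            dopamine = dopamine_model(),
                            learning = learning_params()) {
  learning_rule <- match.arg(learning_rule)
  exploration <- match.arg(exploration)
  stopifnot(e >= 0, lambda >= 0)
  if (learning_rule == "basal_ganglia" && exploration == "random") {
    if (lambda <= 0) stop("neural random exploration requires lambda > 0")
    if (e != 0) stop("neural random exploration requires e = 0")
  }
  structure(list(learning_rule = learning_rule, exploration = exploration,
                 theta = theta, gamma = gamma, e = e, lambda = lambda,
                 dopamine = dopamine, learning = learning),
            class = "bb_strategy")
}

#' Value utilities for the Kalman-filter strategies
#'
#' Draws one utility per arm from the strategy's utility definition using the
#' current R random stream. The Kalman hybrid strategy has no explicit utility
#' (its choice rule exists only as a two-arm probability) and raises an error.
#'
#' @param state A [kalman_state()].
#' @param params A [strategy_params()] with `learning_rule = "kalman"`.
#' @return Numeric vector of per-arm utilities.
#' @export
kalman_utilities <- function(state, params) {
  stopifnot(inherits(state, "bb_kalman"), inherits(params, "bb_strategy"))
  if (params$exploration == "hybrid")
    stop("the Kalman hybrid strategy has no explicit value utility")
  sigma <- sqrt(state$var)
  K <- state$K
  switch(params$exploration,
    directed = state$Q + params$theta * sigma + params$e * stats::rnorm(K),
    random   = state$Q + params$gamma * sigma * stats::rnorm(K),
    value    = state$Q + params$e * stats::rnorm(K))
}

#' Thalamic value utilities for the basal-ganglia strategies
#'
#' Computes per-arm utilities T from the learner state, a dopamine draw per
#' arm, and unmodulated noise. Two algebraically identical code paths exist:
#' \describe{
#'   \item{`"dopamine"`}{T_i = Q_i + lambda * D_i * S_i + e * Z'_i with
#'     D_i = Dbar(n_i) + (a + b*Dbar(n_i)) Z_i.}
#'   \item{`"decomposed"`}{T_i = Q_i + lambda * ((m + (a + b m) Z_i) S_i +
#'     (k + b k Z_i) sigma_hat_i) + e Z'_i with
#'     sigma_hat_i = S_i n_i^pi.}
#' }
#' Both consume the same standard-normal draws (Z_i shared by the spread and
#' uncertainty components of one arm -- a single dopamine draw drives both;
#' Z'_i independent) and agree to machine precision. For
#' `exploration = "random"` the deterministic dopamine bias is dropped:
#' T_i = Q_i + lambda * Z_i * ((a + b m) S_i + b k sigma_hat_i).
#'
#' @param state A [learner_state()] with all S_i >= 0 and n_i >= 1.
#' @param params A [strategy_params()] with `learning_rule = "basal_ganglia"`.
#' @param path `"dopamine"` or `"decomposed"`.
#' @param Z,Znoise Optional standard-normal vectors (one per arm) injected for
#'   testing the path equivalence; drawn from the R random stream if NULL.
#' @return Numeric vector of per-arm utilities.
#' @export
neural_utilities <- function(state, params, path = c("dopamine", "decomposed"),
                             Z = NULL, Znoise = NULL) {
  stopifnot(inherits(state, "bb_learner"), inherits(params, "bb_strategy"))
  path <- match.arg(path)
  if (any(state$S < 0)) stop("spread estimates must be nonnegative")
  if (any(state$n < 1)) stop("choice counts must be >= 1 (after pseudocount)")
  K <- state$K
  if (is.null(Z)) Z <- stats::rnorm(K)
  if (is.null(Znoise)) Znoise <- stats::rnorm(K)
  dm <- params$dopamine
  co <- .dop_coefs(dm)
  lam <- params$lambda
  shat <- posterior_uncertainty(state$S, state$n, co$pi)

  if (params$exploration == "random") {
    return(state$Q + lam * Z * (co$noise_S * state$S + co$noise_U * shat))
  }
  if (path == "dopamine") {
    mu <- novelty_mean(state$n, dm)
    sdv <- if (dm$form == "ideal") dm$eta * state$n^(-0.5)
           else novelty_sd(mu, dm)
    D <- mu + sdv * Z
    state$Q + lam * D * state$S + params$e * Znoise
  } else {
    state$Q + lam * ((co$bias_S + co$noise_S * Z) * state$S +
                       (co$bias_U + co$noise_U * Z) * shat) +
      params$e * Znoise
  }
}

#' Closed-form two-arm choice probability
#'
#' Probability of choosing arm 1 over arm 2 for each strategy, as the standard
#' normal CDF of a signal-to-noise ratio:
#' \describe{
#'   \item{Kalman directed (UCB)}{\eqn{\Phi\left((Q_1-Q_2+\theta(\sigma_1-\sigma_2)) / \sqrt{2e^2}\right)}}
#'   \item{Kalman random (Thompson)}{\eqn{\Phi\left((Q_1-Q_2) / \sqrt{\gamma^2(\sigma_1^2+\sigma_2^2)}\right)}}
#'   \item{Kalman hybrid}{\eqn{\Phi\left(\gamma(Q_1-Q_2)/\sqrt{\sigma_1^2+\sigma_2^2} + \theta(\sigma_1-\sigma_2)\right)}
#'     (defined directly as a choice rule; no explicit utility exists).}
#'   \item{Kalman value}{\eqn{\Phi\left((Q_1-Q_2)/\sqrt{2e^2}\right)}}
#'   \item{Neural hybrid / directed}{\eqn{\Phi\left((Q_1-Q_2+\lambda m(S_1-S_2)+\lambda k(\hat\sigma_1-\hat\sigma_2)) / d\right)}
#'     with per-arm dopamine-noise weight
#'     \eqn{w_i = \lambda((a+bm)S_i + bk\hat\sigma_i)} and denominator
#'     \eqn{d = \sqrt{w_1^2 + w_2^2 + 2e^2}}. A single dopamine draw per arm
#'     drives both the spread and uncertainty components, so the two noise
#'     components of one arm are perfectly correlated and the denominator
#'     carries the squared sum \eqn{w_i^2} (not separate squared terms); the
#'     two reduce to the same expression whenever either component vanishes,
#'     e.g. for the directed rows (a = b = 0) and for the ideal model
#'     (a = m = 0), where the expression becomes
#'     \eqn{\Phi((Q_1-Q_2+\lambda\nu(\sigma_1-\sigma_2)) /
#'     \sqrt{\lambda^2\eta^2(\sigma_1^2+\sigma_2^2)+2e^2})}.}
#'   \item{Neural random}{\eqn{\Phi\left((Q_1-Q_2)/\sqrt{w_1^2+w_2^2}\right)}
#'     (e = 0; uncertainty scales stochasticity without biasing preference).}
#'   \item{Neural value}{\eqn{\Phi\left((Q_1-Q_2)/\sqrt{2e^2}\right)}}
#' }
#' Here \eqn{\hat\sigma_i = S_i n_i^\pi} ([posterior_uncertainty()]).
#'
#' A zero denominator with nonzero numerator yields a degenerate 0/1 choice;
#' a zero denominator with zero numerator is undefined and raises an error
#' unless `tie_break = TRUE`, in which case 0.5 is returned (used during
#' likelihood evaluation where fresh blocks start fully symmetric).
#'
#' @param state A [learner_state()] (neural family) or [kalman_state()]
#'   (Kalman family) with exactly 2 arms.
#' @param params A [strategy_params()].
#' @param tie_break Return 0.5 for the undefined 0/0 case (default FALSE).
#' @return Probability of choosing arm 1, in (0, 1) when the denominator is
#'   positive.
#' @export
choice_prob_two_arm <- function(state, params, tie_break = FALSE) {
  stopifnot(inherits(params, "bb_strategy"))
  if (state$K != 2) stop("closed-form choice probabilities require K = 2")

  if (params$learning_rule == "kalman") {
    stopifnot(inherits(state, "bb_kalman"))
    sigma <- sqrt(state$var)
    dQ <- state$Q[1] - state$Q[2]
    switch(params$exploration,
      directed = {
        num <- dQ + params$theta * (sigma[1] - sigma[2])
        den <- sqrt(2 * params$e^2)
        .phi_ratio(num, den, tie_break)
      },
      random = {
        num <- dQ
        den <- sqrt(params$gamma^2 * (sigma[1]^2 + sigma[2]^2))
        .phi_ratio(num, den, tie_break)
      },
      hybrid = {
        tot <- sqrt(sigma[1]^2 + sigma[2]^2)
        if (tot == 0) {
          if (dQ == 0 && params$theta == 0) {
            if (tie_break) return(0.5)
            stop("undefined choice probability: zero total uncertainty")
          }
          return(as.numeric(dQ > 0))
        }
        stats::pnorm(params$gamma * dQ / tot +
                       params$theta * (sigma[1] - sigma[2]))
      },
      value = .phi_ratio(dQ, sqrt(2 * params$e^2), tie_break))
  } else {
    stopifnot(inherits(state, "bb_learner"))
    co <- .dop_coefs(params$dopamine)
    lam <- params$lambda
    shat <- posterior_uncertainty(state$S, state$n, co$pi)
    dQ <- state$Q[1] - state$Q[2]
    w <- lam * (co$noise_S * state$S + co$noise_U * shat)
    switch(params$exploration,
      hybrid = ,
      directed = {
        num <- dQ + lam * co$bias_S * (state$S[1] - state$S[2]) +
          lam * co$bias_U * (shat[1] - shat[2])
        den <- sqrt(w[1]^2 + w[2]^2 + 2 * params$e^2)
        .phi_ratio(num, den, tie_break)
      },
      random = .phi_ratio(dQ, sqrt(w[1]^2 + w[2]^2), tie_break),
      value = .phi_ratio(dQ, sqrt(2 * params$e^2), tie_break))
  }
}

# Phi(num/den) with explicit handling of the degenerate denominator
.phi_ratio <- function(num, den, tie_break) {
  if (den > 0) return(stats::pnorm(num / den))
  if (num == 0) {
    if (tie_break) return(0.5)
    stop("undefined choice probability: zero numerator and denominator")
  }
  as.numeric(num > 0)
}

#' Classic UCB indices (UCB1, UCB2, UCB1-tuned, UCB1-normal)
#'
#' Computes the per-arm index of the classic finite-time upper-confidence-bound
#' algorithms from per-arm sufficient statistics. Arms whose variant-specific
#' forced-play condition is pending are flagged in `must_play` (and receive an
#' index of `Inf`); [select_action()] gives such arms absolute priority.
#' \describe{
#'   \item{ucb1}{\eqn{\bar x_j + \sqrt{2\ln t / n_j}}; each arm must be played
#'     once first.}
#'   \item{ucb1_tuned}{\eqn{\bar x_j + \sqrt{(\ln t / n_j)\min(1/4, V_j)}}
#'     with \eqn{V_j = s^2_j + \sqrt{2\ln t/n_j}} and \eqn{s^2_j} the biased
#'     sample variance.}
#'   \item{ucb1_normal}{forced play while \eqn{n_j < \lceil 8\ln t\rceil};
#'     otherwise \eqn{\bar x_j + \sqrt{16\,\frac{q_j - n_j\bar x_j^2}{n_j-1}
#'     \frac{\ln(t-1)}{n_j}}} with \eqn{q_j} the sum of squared rewards.}
#'   \item{ucb2}{\eqn{\bar x_j + \sqrt{\frac{(1+\alpha)\ln(e t/\tau(r_j))}
#'     {2\tau(r_j)}}} with epoch schedule \eqn{\tau(r) = \lceil(1+\alpha)^r\rceil};
#'     the caller is responsible for playing a selected arm
#'     \eqn{\tau(r_j+1)-\tau(r_j)} times before advancing its epoch (the
#'     simulation harness does this).}
#' }
#'
#' @param history List with numeric per-arm vectors `n` (play counts), `mean`
#'   (sample means), `sumsq` (sums of squared rewards) and, for `ucb2`,
#'   integer `epoch` (per-arm epoch counters r_j).
#' @param t Current trial number (total plays so far + 1).
#' @param variant One of `"ucb1"`, `"ucb2"`, `"ucb1_tuned"`, `"ucb1_normal"`.
#' @param alpha_ucb The UCB2 epoch parameter (0 < alpha_ucb < 1).
#' @return List with `index` (numeric per arm) and `must_play` (logical per
#'   arm).
#' @export
classic_ucb_index <- function(history, t,
                              variant = c("ucb1", "ucb2", "ucb1_tuned",
                                          "ucb1_normal"),
                              alpha_ucb = 0.1) {
  variant <- match.arg(variant)
  n <- history$n
  xbar <- history$mean
  K <- length(n)
  must <- switch(variant,
    ucb1_normal = n < ceiling(8 * log(max(t, 2))),
    n < 1)
  idx <- rep(Inf, K)
  ok <- !must
  if (any(ok)) {
    idx[ok] <- switch(variant,
      ucb1 = xbar[ok] + sqrt(2 * log(t) / n[ok]),
      ucb1_tuned = {
        v <- pmax(history$sumsq[ok] / n[ok] - xbar[ok]^2, 0) +
          sqrt(2 * log(t) / n[ok])
        xbar[ok] + sqrt(log(t) / n[ok] * pmin(0.25, v))
      },
      ucb1_normal = {
        ss <- pmax(history$sumsq[ok] - n[ok] * xbar[ok]^2, 0)
        xbar[ok] + sqrt(16 * ss / (n[ok] - 1) * log(t - 1) / n[ok])
      },
      ucb2 = {
        tau_r <- ceiling((1 + alpha_ucb) ^ history$epoch[ok])
        xbar[ok] + sqrt((1 + alpha_ucb) *
                          log(pmax(exp(1) * t / tau_r, 1.0001)) / (2 * tau_r))
      })
  }
  list(index = idx, must_play = must)
}

#' Select an action from utilities or indices
#'
#' Must-play arms (forced-play rules of the classic UCB variants) take
#' absolute priority, lowest arm index first. Otherwise the argmax is chosen,
#' with exact ties broken uniformly at random from the current R random
#' stream.
#'
#' @param values Numeric per-arm utilities or indices.
#' @param must_play Optional logical per-arm forced-play flags.
#' @return 1-based chosen arm index.
#' @export
select_action <- function(values, must_play = NULL) {
  if (length(values) == 0) stop("empty utility vector")
  if (!is.null(must_play) && any(must_play)) return(which(must_play)[1])
  if (any(!is.finite(values))) stop("non-finite utilities")
  top <- which(values == max(values))
  if (length(top) == 1) top else top[sample.int(length(top), 1)]
}
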