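#' Dopamine novelty-response model
#'
#' The phasic dopamine response to an option decays with the number of times
#' that option has been chosen. Two forms are supported:
#' \describe{
#'   \item{ideal}{\eqn{D(n) = (\nu + \eta Z)/\sqrt{n}}, i.e. a normal draw
#'     with mean \eqn{\nu/\sqrt{n}} and s.d. \eqn{\eta/\sqrt{n}} -- the form
#'     that converts reward spread exactly into central-limit posterior
#'     uncertainty.}
#'   \item{refined}{\eqn{D(n) \sim N(\bar D(n), (a + b\bar D(n))^2)} with
#'     mean response \eqn{\bar D(n) = m + k n^\pi} -- the power-law mean with
#'     affine mean--s.d. relation estimated from dopaminergic firing-rate
#'     data. Defaults are those estimates: a = 1.380, b = 0.306, m = 0.677,
#'     k = 4.486, pi = -0.791.}
#' }
#' The ideal form is exactly the refined form with m = 0, a = 0, k = nu,
#' b = eta/nu, pi = -0.5 (see [as_refined()]).
#'
#' @param form `"refined"` or `"ideal"`.
#' @param nu,eta Ideal-form scale parameters (>= 0).
#' @param m Baseline mean response (refined).
#' @param k Novelty mean scale (refined).
#' @param pi Power parameter, < 0 for a decaying novelty response.
#' @param a Baseline response s.d. (refined).
#' @param b Mean-s.d. slope (refined).
#' @param lambda Dopaminergic gain used when the signal modulates the
#'   thalamic value utility (>= 0).
#' @return An object of class `"bb_dopamine"`.
#' @examples
#' dm <- dopamine_model()             # refined, data-derived constants
#' novelty_mean(1, dm)                # m + k
#' novelty_sd(novelty_mean(1, dm), dm)
#' @export
dopamine_model <- function(form = c("refined", "ideal"),
                           nu = 1, eta = 1,
                           m = 0.677, k = 4.486, pi = -0.791,
                           a = 1.380, b = 0.306, lambda = 1) {
  form <- match.arg(form)
  stopifnot(lambda >= 0)
  if (form == "ideal") {
    stopifnot(nu >= 0, eta >= 0)
    # nested refined parameterisation; b = eta/nu is undefined at nu = 0, in
    # which case the n-based forms below bypass the affine mean-s.d. relation
    mod <- list(form = "ideal", nu = nu, eta = eta,
                m = 0, k = nu, pi = -0.5, a = 0,
                b = if (nu > 0) eta / nu else NA_real_, lambda = lambda)
  } else {
    mod <- list(form = "refined", nu = NA_real_, eta = NA_real_,
                m = m, k = k, pi = pi, a = a, b = b, lambda = lambda)
  }
  class(mod) <- "bb_dopamine"
  mod
}

#' Reduce an ideal dopamine model to its refined parameterisation
#'
#' The ideal inverse-square-root model is nested in the refined power-law
#' model: m = 0, a = 0, k = nu, b = eta/nu, pi = -0.5. This helper performs
#' that reduction explicitly (the constructor already stores the reduced
#' parameters, so this is the identity on refined models).
#'
#' @param model A [dopamine_model()].
#' @return A refined-form `"bb_dopamine"` with identical behaviour.
#' @export
as_refined <- function(model) {
  stopifnot(inherits(model, "bb_dopamine"))
  out <- model
  out$form <- "refined"
  out
}

#' Mean dopamine novelty response
#'
#' \eqn{\bar D(n) = m + k n^\pi} (ideal form: \eqn{\nu n^{-1/2}}). Strictly
#' decreasing in n for k > 0, pi < 0.
#'
#' @param n Choice count(s), >= 1.
#' @param model A [dopamine_model()].
#' @return Mean response, vectorised over `n`.
#' @export
novelty_mean <- function(n, model) {
  stopifnot(inherits(model, "bb_dopamine"))
  if (any(n < 1)) stop("choice count must be >= 1")
  model$m + model$k * n ^ model$pi
}

#' Standard deviation of the dopamine novelty response
#'
#' Affine in the mean response: \eqn{a + b \bar D}. Under valid parameters
#' this is nonnegative for every reachable mean response; a negative result
#' signals an invalid parameter combination and raises an error.
#'
#' @param D_bar Mean response value(s).
#' @param model A [dopamine_model()].
#' @return Response s.d., vectorised over `D_bar`.
#' @export
novelty_sd <- function(D_bar, model) {
  stopifnot(inherits(model, "bb_dopamine"))
  if (any(!is.finite(D_bar))) stop("non-finite mean response")
  if (model$form == "ideal" && model$nu == 0)
    stop("ideal model with nu = 0 has no mean-s.d. relation; ",
         "the response s.d. is eta/sqrt(n)")
  sd <- model$a + model$b * D_bar
  if (any(sd < 0)) stop("invalid parameter combination: negative response s.d.")
  sd
}

#' Sample a dopamine novelty response
#'
#' Draws \eqn{D = \bar D(n) + (a + b\bar D(n)) Z}, Z standard normal, from
#' the current R random stream. The normal has unbounded support; negative
#' draws are kept by default because the closed-form choice probabilities
#' assume an untruncated noise term. `truncate = TRUE` clips draws at zero
#' (breaking those closed forms; off by default).
#'
#' @param n Choice count(s), >= 1.
#' @param model A [dopamine_model()].
#' @param truncate Clip draws at zero (default FALSE).
#' @return Sampled response(s), one per element of `n`.
#' @export
sample_dopamine <- function(n, model, truncate = FALSE) {
  mu <- novelty_mean(n, model)
  sd <- if (model$form == "ideal") model$eta * n^(-0.5)
        else novelty_sd(mu, model)
  d <- mu + sd * stats::rnorm(length(mu))
  if (truncate) d <- pmax(d, 0)
  d
}

# coefficients of the thalamic utility decomposition
# T = Q + lambda*((bias_S + noise_S*Z)*S + (bias_U + noise_U*Z)*sigma_hat) + eZ'
# (refined: bias_S = m, bias_U = k, noise_S = a + bm, noise_U = bk;
#  ideal:   bias_S = 0, bias_U = nu, noise_S = 0, noise_U = eta, pi = -1/2)
.dop_coefs <- function(model) {
  if (model$form == "ideal")
    list(bias_S = 0, bias_U = model$nu, noise_S = 0, noise_U = model$eta,
         pi = -0.5)
  else
    list(bias_S = model$m, bias_U = model$k,
         noise_S = model$a + model$b * model$m,
         noise_U = model$b * model$k, pi = model$pi)
}
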