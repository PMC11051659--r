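#' Candidate novelty-decay curve families
#'
#' Evaluates the three candidate functions describing how the normalised
#' dopaminergic firing rate decays with the presentation count n:
#' \describe{
#'   \item{inverse_sqrt}{\eqn{f(n) = m + k/\sqrt{n}} (2 free parameters).}
#'   \item{power}{\eqn{f(n) = m + k n^\pi} (3 free parameters); the
#'     inverse-square-root family is this family with \eqn{\pi} pinned at
#'     -0.5.}
#'   \item{exponential}{\eqn{f(n) = m + k e^{\pi n}} (3 free parameters,
#'     \eqn{\pi < 0}).}
#' }
#'
#' @param n Presentation indices (>= 1).
#' @param pars Named or positional numeric: `m`, `k` and (3-parameter
#'   families) `pi`.
#' @param family `"inverse_sqrt"`, `"power"` or `"exponential"`.
#' @return Fitted-curve values at `n`.
#' @export
novelty_curve <- function(n, pars,
                          family = c("power", "inverse_sqrt", "exponential")) {
  family <- match.arg(family)
  m <- pars[[1]]; k <- pars[[2]]
  switch(family,
    inverse_sqrt = m + k / sqrt(n),
    power = m + k * n ^ pars[[3]],
    exponential = m + k * exp(pars[[3]] * n))
}

.curve_npar <- function(family) if (family == "inverse_sqrt") 2L else 3L

# regressor whose OLS coefficients profile out (m, k) at fixed shape pi
.curve_regressor <- function(n, pi, family) {
  switch(family,
    inverse_sqrt = n ^ (-0.5),
    power = n ^ pi,
    exponential = exp(pi * n))
}

# RSS of the family at full parameter vector; the shape parameter is confined
# to [lo, hi] and (m, k) to data-driven boxes that keep ill-posed fits (noisy
# single-neuron traces) from running away along the m/k/shape ridge
.curve_rss <- function(pars, n, y, family, lo = -3, hi = -0.01,
                       m_box = NULL, k_max = Inf) {
  if (family != "inverse_sqrt") {
    if (pars[3] < lo || pars[3] > hi) return(1e12 + sum(pars^2))
  }
  if (!is.null(m_box) && (pars[1] < m_box[1] || pars[1] > m_box[2]))
    return(1e12 + sum(pars^2))
  if (pars[2] < 0 || pars[2] > k_max) return(1e12 + sum(pars^2))
  sum((y - novelty_curve(n, pars, family))^2)
}

#' Fit a novelty-decay curve to averaged firing rates
#'
#' Averages the normalised rates across neurons at each presentation index and
#' fits the requested curve family by Gaussian maximum likelihood with iid
#' residuals, the residual s.d. profiled out analytically
#' (\eqn{\ln\hat L = -N/2(\ln(2\pi\,RSS/N) + 1)}), which reduces the
#' optimisation to least squares. The shape parameter is searched over
#' \[-3, -0.01\] by multi-start Nelder-Mead simplex: starts are laid on a grid
#' of shape values with the linear parameters (m, k) profiled by ordinary
#' least squares at each start, and the best final RSS is kept.
#'
#' BIC and AIC count the residual s.d. as a parameter (this affects every
#' family equally, so family rankings are invariant to the convention).
#' Standard errors come from the usual nonlinear-least-squares curvature,
#' \eqn{\hat\sigma^2 (J^\top J)^{-1}} with J the analytic Jacobian at the
#' optimum and \eqn{\hat\sigma^2 = RSS/(N - p)}.
#'
#' @param traces Data frame with columns `neuron_id`, `n` (presentation
#'   index, 1-based) and `rate` (see [gen_dopamine_traces()] for the schema).
#' @param family Curve family (see [novelty_curve()]).
#' @param n_starts Number of simplex starts (default 50).
#' @param pin_pi Optional fixed value of the shape parameter for the
#'   3-parameter families; (m, k) are then profiled exactly by ordinary least
#'   squares. Pinning the power family at -0.5 reproduces the
#'   inverse-square-root fit.
#' @return An object of class `"bb_fit"`: list with `family`, `par` (named),
#'   `se`, `vcov`, `df`, `logLik`, `BIC`, `AIC`, `n_obs`, `n_params` (free
#'   curve parameters + 1 for the residual s.d.), `sigma`, `rss`,
#'   `converged`, `n_starts` and the averaged data (`n`, `y`).
#' @export
fit_average_curve <- function(traces,
                              family = c("power", "inverse_sqrt",
                                         "exponential"),
                              n_starts = 50, pin_pi = NULL) {
  family <- match.arg(family)
  stopifnot(all(c("neuron_id", "n", "rate") %in% names(traces)))
  if (any(!is.finite(traces$rate))) stop("rates must be finite")
  y <- tapply(traces$rate, traces$n, mean)
  n <- as.numeric(names(y))
  y <- as.numeric(y)
  .fit_curve_points(n, y, family, n_starts, pin_pi = pin_pi)
}

# core fitter on (index, value) points; shared by average and per-neuron fits
.fit_curve_points <- function(n, y, family, n_starts, pin_pi = NULL) {
  p_curve <- .curve_npar(family)
  N <- length(n)
  if (N < p_curve + 1)
    stop("need at least ", p_curve + 1, " distinct presentation indices")

  # data-driven boxes for the linear parameters (see .curve_rss)
  spread <- max(max(y) - min(y), 1e-6)
  m_box <- c(min(y) - 2 * spread, max(y) + spread)
  k_max <- 10 * spread

  ols_at <- function(pi) {
    x <- .curve_regressor(n, pi, family)
    cf <- stats::coef(stats::lm.fit(cbind(1, x), y))
    c(min(max(cf[1], m_box[1]), m_box[2]), min(max(cf[2], 0), k_max))
  }

  if (family == "inverse_sqrt") {
    # linear in (m, k): exact OLS solution, no iterative search needed
    par <- ols_at(NA)
    rss <- sum((y - (par[1] + par[2] * n^(-0.5)))^2)
    best <- list(par = par, value = rss)
    conv <- TRUE
    starts <- list(par)
  } else if (!is.null(pin_pi)) {
    par <- c(ols_at(pin_pi), pin_pi)
    rss <- sum((y - novelty_curve(n, par, family))^2)
    best <- list(par = par, value = rss)
    conv <- TRUE
    starts <- list(par)
  } else {
    pis <- seq(-3, -0.01, length.out = max(n_starts, 2))
    starts <- lapply(pis, function(p) c(ols_at(p), p))
    best <- NULL
    conv <- FALSE
    for (s in starts) {
      fit <- stats::optim(s, .curve_rss, n = n, y = y, family = family,
                          m_box = m_box, k_max = k_max,
                          method = "Nelder-Mead",
                          control = list(maxit = 500, reltol = 1e-12))
      if (is.null(best) || fit$value < best$value) best <- fit
      if (fit$convergence == 0) conv <- TRUE
    }
    if (!conv) stop("curve optimiser failed to converge from all starts")
  }

  par <- best$par
  names(par) <- if (family == "inverse_sqrt") c("m", "k") else c("m", "k", "pi")
  rss <- best$value
  logLik <- -N / 2 * (log(2 * pi * rss / N) + 1)
  if (!is.null(pin_pi)) p_curve <- 2L   # pinned shape is not a free parameter
  p_total <- p_curve + 1L

  # analytic Jacobian of the mean function at the optimum (free params only)
  J <- if (!is.null(pin_pi)) {
    cbind(1, .curve_regressor(n, pin_pi, family))
  } else {
    switch(family,
      inverse_sqrt = cbind(1, n^(-0.5)),
      power = cbind(1, n^par["pi"], par["k"] * n^par["pi"] * log(n)),
      exponential = cbind(1, exp(par["pi"] * n),
                          par["k"] * n * exp(par["pi"] * n)))
  }
  df <- N - p_curve
  s2 <- rss / max(df, 1)
  vcov <- tryCatch(s2 * solve(crossprod(J)),
                   error = function(e) matrix(NA_real_, p_curve, p_curve))
  se <- sqrt(pmax(diag(vcov), 0))
  names(se) <- names(par)[seq_along(se)]

  structure(list(family = family, par = par, se = se, vcov = vcov, df = df,
                 logLik = logLik,
                 BIC = p_total * log(N) - 2 * logLik,
                 AIC = 2 * p_total - 2 * logLik,
                 n_obs = N, n_params = p_total, sigma = sqrt(rss / N),
                 rss = rss, converged = conv, n_starts = length(starts),
                 n = n, y = y),
            class = "bb_fit")
}

#' @export
print.bb_fit <- function(x, ...) {
  cat(sprintf("<bb_fit %s: %s | lnL = %.3f, BIC = %.3f, N = %d>\n", x$family,
              paste(sprintf("%s = %.4g", names(x$par), x$par),
                    collapse = ", "),
              x$logLik, x$BIC, x$n_obs))
  invisible(x)
}

#' Two-stage hierarchical curve fit across neurons
#'
#' Approximates a nonlinear mixed-effects fit in two stages: each neuron's
#' trace is fitted by maximum likelihood ([fit_average_curve()] machinery on
#' that neuron's own points), then the population fixed effects are the means
#' of the per-neuron parameters and the random effects their covariance
#' matrix (`mode = "joint"`) or variances only (`mode = "independent"`).
#' The marginal log-likelihood is approximated by a Laplace-style plug-in:
#' the sum of per-neuron conditional log-likelihoods plus the log-density of
#' each neuron's parameters under the fitted population Gaussian. BIC counts
#' the fixed effects, the random-effect (co)variances and the residual s.d.
#' This is an approximation for recovery studies, not a replication of any
#' particular mixed-effects implementation.
#'
#' @param traces Data frame (`neuron_id`, `n`, `rate`).
#' @param family Curve family.
#' @param mode `"joint"` (full parameter covariance) or `"independent"`
#'   (diagonal).
#' @param n_starts Simplex starts per neuron (default 20).
#' @return List with `fixed` (population means), `random` (covariance
#'   matrix), `per_neuron` (data frame of per-neuron parameters),
#'   `logLik`, `BIC`, `AIC`, `n_obs`, `n_params`, `mode`, `family`,
#'   `dropped` (ids of neurons with insufficient points).
#' @export
fit_per_neuron_hierarchical <- function(traces,
                                        family = c("power", "inverse_sqrt",
                                                   "exponential"),
                                        mode = c("joint", "independent"),
                                        n_starts = 20) {
  family <- match.arg(family)
  mode <- match.arg(mode)
  p_curve <- .curve_npar(family)
  ids <- unique(traces$neuron_id)
  fits <- list()
  dropped <- character(0)
  for (id in ids) {
    tr <- traces[traces$neuron_id == id, ]
    if (length(unique(tr$n)) < p_curve + 1) {
      dropped <- c(dropped, as.character(id))
      next
    }
    fits[[as.character(id)]] <-
      .fit_curve_points(as.numeric(tr$n), as.numeric(tr$rate), family,
                        n_starts)
  }
  if (length(dropped))
    warning("dropped ", length(dropped), " neuron(s) with insufficient points")
  if (length(fits) < 3) stop("need at least 3 fittable neurons")

  P <- do.call(rbind, lapply(fits, function(f) f$par))
  fixed <- colMeans(P)
  Sig <- stats::cov(P)
  if (mode == "independent") Sig <- diag(diag(Sig), nrow = ncol(P))

  # Laplace-style plug-in marginal likelihood
  cond_ll <- sum(vapply(fits, function(f) f$logLik, numeric(1)))
  Sig_reg <- Sig + diag(1e-10, ncol(P))
  ld <- determinant(Sig_reg, logarithm = TRUE)$modulus
  Sinv <- solve(Sig_reg)
  quad <- sum(apply(P, 1, function(th) {
    d <- th - fixed
    drop(t(d) %*% Sinv %*% d)
  }))
  pop_ll <- -0.5 * (nrow(P) * (ncol(P) * log(2 * pi) + ld) + quad)
  logLik <- cond_ll + as.numeric(pop_ll)

  n_obs <- sum(vapply(fits, function(f) f$n_obs, numeric(1)))
  n_rand <- if (mode == "joint") p_curve * (p_curve + 1) / 2 else p_curve
  n_params <- p_curve + n_rand + 1
  per_neuron <- data.frame(neuron_id = rownames(P), P, row.names = NULL)

  list(fixed = fixed, random = Sig, per_neuron = per_neuron,
       logLik = logLik, BIC = n_params * log(n_obs) - 2 * logLik,
       AIC = 2 * n_params - 2 * logLik,
       n_obs = n_obs, n_params = n_params, mode = mode, family = family,
       dropped = dropped)
}

#' Mean--s.d. regression of firing-rate variability on mean response
#'
#' At each presentation index, computes the across-neuron mean and standard
#' deviation of the normalised rate, then regresses the s.d. on the mean by
#' ordinary least squares, estimating the affine relation
#' \eqn{s.d. = a + b \cdot \bar D} and its Pearson correlation.
#'
#' @param traces Data frame (`neuron_id`, `n`, `rate`); needs >= 3 indices
#'   with >= 2 contributing neurons each.
#' @return List with `a` (intercept), `b` (slope), `r` (Pearson correlation),
#'   `se_a`, `se_b`, `df`, and the per-index `mean`/`sd` table.
#' @export
mean_sd_regression <- function(traces) {
  stopifnot(all(c("neuron_id", "n", "rate") %in% names(traces)))
  counts <- tapply(traces$rate, traces$n, length)
  keep <- names(counts)[counts >= 2]
  if (length(keep) < 3)
    stop("need >= 3 presentation indices with >= 2 neurons each")
  sub <- traces[as.character(traces$n) %in% keep, ]
  mu <- tapply(sub$rate, sub$n, mean)
  sd_ <- tapply(sub$rate, sub$n, stats::sd)
  mu <- as.numeric(mu); sd_ <- as.numeric(sd_)
  if (stats::var(mu) == 0) stop("degenerate regressor: mean response constant")
  fit <- stats::lm(sd_ ~ mu)
  cf <- summary(fit)$coefficients
  list(a = unname(cf[1, 1]), b = unname(cf[2, 1]),
       r = stats::cor(mu, sd_),
       se_a = unname(cf[1, 2]), se_b = unname(cf[2, 2]),
       df = fit$df.residual,
       table = data.frame(n = as.numeric(names(tapply(sub$rate, sub$n, mean))),
                          mean = mu, sd = sd_))
}
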