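#' The eight behavioural strategy rows
#'
#' Returns the catalogue of trial-by-trial choice models fitted to two-armed
#' behavioural data: every combination of learning rule (Kalman filter vs
#' basal ganglia) and exploration type (hybrid, directed, random, value).
#' Neural rows carry the dopamine novelty-response constants estimated from
#' firing-rate data as fixed parameters (a = 1.380, b = 0.306, m = 0.677,
#' k = 4.486, pi = -0.791 where applicable); the value rows zero out the
#' exploration machinery (the neural value row is plain Rescorla-Wagner
#' learning with unmodulated choice noise). Each row records its free
#' parameters and their box bounds used by [fit_participant()].
#'
#' @return Named list of row definitions. Row names:
#'   `kalman_hybrid`, `kalman_directed`, `kalman_random`, `kalman_value`,
#'   `bg_hybrid`, `bg_directed`, `bg_random`, `bg_value`.
#' @export
table1_strategies <- function() {
  dop <- c(a = 1.380, b = 0.306, m = 0.677, k = 4.486, pi = -0.791)
  kal <- list(prior_mean = 0, prior_var = 100, reward_var = 10)
  list(
    kalman_hybrid = list(
      label = "kalman_hybrid", learning_rule = "kalman",
      exploration = "hybrid", fixed = list(kalman = kal),
      free = c("gamma", "theta"),
      lower = c(gamma = 1e-6, theta = -50), upper = c(gamma = 50, theta = 50)),
    kalman_directed = list(
      label = "kalman_directed", learning_rule = "kalman",
      exploration = "directed", fixed = list(kalman = kal),
      free = c("theta", "e"),
      lower = c(theta = -50, e = 1e-6), upper = c(theta = 50, e = 100)),
    kalman_random = list(
      label = "kalman_random", learning_rule = "kalman",
      exploration = "random", fixed = list(kalman = kal),
      free = c("gamma"),
      lower = c(gamma = 1e-6), upper = c(gamma = 50)),
    kalman_value = list(
      label = "kalman_value", learning_rule = "kalman",
      exploration = "value", fixed = list(kalman = kal, theta = 0),
      free = c("e"),
      lower = c(e = 1e-6), upper = c(e = 100)),
    bg_hybrid = list(
      label = "bg_hybrid", learning_rule = "basal_ganglia",
      exploration = "hybrid", fixed = list(dop = dop),
      free = c("alpha_q", "alpha_s", "lambda", "e"),
      lower = c(alpha_q = 0, alpha_s = 0, lambda = 0, e = 0),
      upper = c(alpha_q = 1, alpha_s = 1, lambda = 50, e = 100)),
    bg_directed = list(
      label = "bg_directed", learning_rule = "basal_ganglia",
      exploration = "directed",
      fixed = list(dop = c(a = 0, b = 0, m = 0.677, k = 4.486, pi = -0.791)),
      free = c("alpha_q", "alpha_s", "lambda", "e"),
      lower = c(alpha_q = 0, alpha_s = 0, lambda = 0, e = 0),
      upper = c(alpha_q = 1, alpha_s = 1, lambda = 50, e = 100)),
    bg_random = list(
      label = "bg_random", learning_rule = "basal_ganglia",
      exploration = "random", fixed = list(dop = dop, e = 0),
      free = c("alpha_q", "alpha_s", "lambda"),
      lower = c(alpha_q = 0, alpha_s = 0, lambda = 1e-6),
      upper = c(alpha_q = 1, alpha_s = 1, lambda = 50)),
    bg_value = list(
      label = "bg_value", learning_rule = "basal_ganglia",
      exploration = "value",
      fixed = list(dop = c(a = 0, b = 0, m = 0, k = 0, pi = 0), alpha_s = 0),
      free = c("alpha_q", "e"),
      lower = c(alpha_q = 0, e = 0), upper = c(alpha_q = 1, e = 100))
  )
}

.PROB_FLOOR <- 1e-10

#' Trial-by-trial negative log-likelihood of a choice dataset
#'
#' Computes \eqn{-\sum_t \ln p(c[t])} for one participant under a strategy
#' row, resetting all latent learner states at every block boundary. On each
#' trial the choice probability is the closed-form two-arm expression of
#' [choice_prob_two_arm()], evaluated before the learner is updated with the
#' observed choice and reward. Probabilities are floored at 1e-10 inside the
#' log; fully symmetric states with zero noise (e.g. the first trial of a
#' block) resolve to probability 0.5.
#'
#' Learner initialisation follows the two-armed mean-resampling task design:
#' neural rows start each block at Q = S = 0 with choice pseudocount 1;
#' Kalman rows start at the task prior (mean 0, variance 100) with reward
#' variance 10.
#'
#' @param data Data frame for one participant with columns `block`, `trial`,
#'   `choice` (1 or 2) and `reward`.
#' @param row A strategy row from [table1_strategies()].
#' @param pars Named numeric vector of the row's free parameters.
#' @param details If TRUE, also return per-trial probabilities and a flag for
#'   active probability flooring.
#' @return Negative log-likelihood (scalar), or a list when `details = TRUE`.
#' @export
choice_negloglik <- function(data, row, pars, details = FALSE) {
  stopifnot(all(c("block", "trial", "choice", "reward") %in% names(data)))
  if (!all(data$choice %in% c(1, 2))) stop("choices must be 1 or 2")
  pars <- .merge_row_pars(row, pars)
  blocks <- split(seq_len(nrow(data)), data$block)
  choice <- data$choice
  reward <- data$reward
  # z[i] = num/den of trial i; pnorm is applied once, vectorised, at the end
  z <- numeric(nrow(data))

  # the exploration-type branch is hoisted out of the trial loop: each trial
  # reduces to the scalar ratio z = num/den with pnorm applied once per block
  if (row$learning_rule == "kalman") {
    kal <- row$fixed$kalman
    theta <- pars[["theta"]]; gamma <- pars[["gamma"]]; e <- pars[["e"]]
    expl <- row$exploration
    den_e <- sqrt(2) * e
    rv <- kal$reward_var
    for (idx in blocks) {
      Q1 <- kal$prior_mean; Q2 <- kal$prior_mean
      v1 <- kal$prior_var; v2 <- kal$prior_var
      for (i in idx) {
        s1 <- sqrt(v1); s2 <- sqrt(v2)
        dQ <- Q1 - Q2
        if (expl == "directed") {
          num <- dQ + theta * (s1 - s2); den <- den_e
        } else if (expl == "random") {
          num <- dQ; den <- gamma * sqrt(v1 + v2)
        } else if (expl == "hybrid") {
          tot <- sqrt(v1 + v2)
          num <- if (tot > 0) gamma * dQ / tot + theta * (s1 - s2) else 0
          den <- 1
        } else {
          num <- dQ; den <- den_e
        }
        z[i] <- if (den > 0) num / den
                else if (num == 0) 0 else sign(num) * Inf
        if (choice[i] == 1) {
          g <- v1 / (v1 + rv)
          Q1 <- Q1 + g * (reward[i] - Q1)
          v1 <- (1 - g) * v1
        } else {
          g <- v2 / (v2 + rv)
          Q2 <- Q2 + g * (reward[i] - Q2)
          v2 <- (1 - g) * v2
        }
      }
    }
  } else {
    dop <- row$fixed$dop
    pw <- dop[["pi"]]
    aq <- pars[["alpha_q"]]; as_ <- pars[["alpha_s"]]
    lam <- pars[["lambda"]]; e <- pars[["e"]]
    expl <- row$exploration
    # per-arm dopamine-noise weight coefficients
    cS <- lam * (dop[["a"]] + dop[["b"]] * dop[["m"]])
    cU <- lam * dop[["b"]] * dop[["k"]]
    bS <- lam * dop[["m"]]
    bU <- lam * dop[["k"]]
    e2 <- 2 * e^2
    den_e <- sqrt(2) * e
    biased <- expl %in% c("hybrid", "directed")
    is_value <- expl == "value"
    for (idx in blocks) {
      Q1 <- 0; Q2 <- 0; S1 <- 0; S2 <- 0; n1 <- 1; n2 <- 1
      for (i in idx) {
        dQ <- Q1 - Q2
        if (is_value) {
          num <- dQ; den <- den_e
        } else {
          u1 <- S1 * n1 ^ pw; u2 <- S2 * n2 ^ pw
          w1 <- cS * S1 + cU * u1; w2 <- cS * S2 + cU * u2
          if (biased) {
            num <- dQ + bS * (S1 - S2) + bU * (u1 - u2)
            den <- sqrt(w1 * w1 + w2 * w2 + e2)
          } else {
            num <- dQ; den <- sqrt(w1 * w1 + w2 * w2)
          }
        }
        z[i] <- if (den > 0) num / den
                else if (num == 0) 0 else sign(num) * Inf
        if (choice[i] == 1) {
          delta <- reward[i] - Q1
          Q1 <- Q1 + aq * delta
          S1 <- S1 + as_ * (abs(delta) - S1)
          n1 <- n1 + 1
        } else {
          delta <- reward[i] - Q2
          Q2 <- Q2 + aq * delta
          S2 <- S2 + as_ * (abs(delta) - S2)
          n2 <- n2 + 1
        }
      }
    }
  }
  p1_vec <- stats::pnorm(z)
  p_trial <- ifelse(choice == 1, p1_vec, 1 - p1_vec)
  floored <- p_trial < .PROB_FLOOR
  nll <- -sum(log(pmax(p_trial, .PROB_FLOOR)))
  if (details) list(nll = nll, p_trial = p_trial, floor_active = any(floored))
  else nll
}

.merge_row_pars <- function(row, pars) {
  full <- c(alpha_q = NA_real_, alpha_s = NA_real_, lambda = NA_real_,
            e = NA_real_, theta = NA_real_, gamma = NA_real_)
  for (nm in names(row$fixed))
    if (nm %in% names(full)) full[nm] <- row$fixed[[nm]]
  pv <- unlist(pars)
  if (!all(row$free %in% names(pv)))
    stop("missing free parameter(s): ",
         paste(setdiff(row$free, names(pv)), collapse = ", "))
  full[names(pv)] <- pv
  full
}

#' Fit one participant by multi-start bounded maximum likelihood
#'
#' Minimises [choice_negloglik()] over the row's free parameters with
#' L-BFGS-B from `n_starts` random initial points drawn uniformly within the
#' row's box bounds. The best converged start is returned; all start outcomes
#' are kept for diagnostics. Seeding the R random stream (or passing `seed`)
#' makes the whole fit deterministic.
#'
#' @param data One participant's choice data (`block`, `trial`, `choice`,
#'   `reward`).
#' @param row A strategy row from [table1_strategies()].
#' @param n_starts Number of random starts (>= 1; 50 mirrors the full fitting
#'   protocol, 10 is a practical default).
#' @param seed Optional integer seed applied before drawing starts.
#' @return An object of class `"bb_fitres"`: list with `label`, `par`,
#'   `fixed`, `logLik`, `BIC`, `AIC`, `n_obs`, `n_free_params`, `n_starts`,
#'   `best_start`, `convergence` (TRUE if any start converged), `starts`
#'   (data frame of all start outcomes) and `floor_active`.
#' @export
fit_participant <- function(data, row, n_starts = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_starts >= 1)
  lower <- row$lower[row$free]
  upper <- row$upper[row$free]
  np <- length(row$free)
  obj <- function(x) {
    names(x) <- row$free
    choice_negloglik(data, row, x)
  }
  best <- NULL
  best_i <- NA_integer_
  rows_out <- vector("list", n_starts)
  any_conv <- FALSE
  for (s in seq_len(n_starts)) {
    x0 <- lower + stats::runif(np) * (upper - lower)
    fit <- tryCatch(
      stats::optim(x0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 150, factr = 1e9)),
      error = function(err) list(par = x0, value = Inf, convergence = 99))
    conv <- identical(fit$convergence, 0L) || identical(fit$convergence, 0)
    any_conv <- any_conv || conv
    rows_out[[s]] <- data.frame(start = s, nll = fit$value, converged = conv)
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      best_i <- s
    }
  }
  if (!any_conv && !is.finite(best$value))
    stop("all optimisation starts failed")
  par <- best$par
  names(par) <- row$free
  det <- choice_negloglik(data, row, par, details = TRUE)
  n_obs <- nrow(data)
  ic <- information_criteria(-det$nll, np, n_obs)
  structure(list(label = row$label, par = par, fixed = row$fixed,
                 logLik = -det$nll, BIC = ic[["BIC"]], AIC = ic[["AIC"]],
                 n_obs = n_obs, n_free_params = np, n_starts = n_starts,
                 best_start = best_i, convergence = any_conv,
                 starts = do.call(rbind, rows_out),
                 floor_active = det$floor_active),
            class = "bb_fitres")
}

#' @export
print.bb_fitres <- function(x, ...) {
  cat(sprintf("<bb_fitres %s: lnL = %.3f, BIC = %.2f, AIC = %.2f | %s>\n",
              x$label, x$logLik, x$BIC, x$AIC,
              paste(sprintf("%s = %.3g", names(x$par), x$par),
                    collapse = ", ")))
  invisible(x)
}

#' Bayesian and Akaike information criteria
#'
#' BIC = k ln(n) - 2 lnL and AIC = 2k - 2 lnL.
#'
#' @param logL Maximised log-likelihood.
#' @param k Number of free parameters (>= 0).
#' @param n Number of observations (>= 1).
#' @return Named numeric `c(BIC, AIC)`.
#' @export
information_criteria <- function(logL, k, n) {
  stopifnot(n >= 1, k >= 0)
  c(BIC = k * log(n) - 2 * logL, AIC = 2 * k - 2 * logL)
}

#' Within-subject standard errors of a participants-by-models table
#'
#' Removes each participant's mean across models and restores the grand mean
#' (the within-subject normalisation appropriate for repeated-measures error
#' bars), then returns each model column's s.d. divided by the square root of
#' the number of participants.
#'
#' @param values Numeric matrix or data frame, participants in rows, models
#'   in columns; no missing cells.
#' @return Named numeric vector of per-model standard errors.
#' @export
within_subject_se <- function(values) {
  m <- as.matrix(values)
  if (any(!is.finite(m))) stop("missing or non-finite cells")
  norm <- m - rowMeans(m) + mean(m)
  apply(norm, 2, stats::sd) / sqrt(nrow(m))
}

#' Fit and compare several strategy rows across participants
#'
#' Fits every requested row to every participant independently and assembles
#' the comparison table: per-model mean BIC/AIC with within-subject standard
#' errors, plus the full per-participant fit results. Individual fit failures
#' are reported per cell, not fatal.
#'
#' @param data Multi-participant choice data (`participant_id`, `block`,
#'   `trial`, `choice`, `reward`).
#' @param rows List of strategy rows (default: all eight
#'   [table1_strategies()]).
#' @param n_starts Optimiser starts per fit.
#' @param seed Master seed; per-(participant, model) seeds are derived from
#'   it so the whole comparison is reproducible.
#' @return List with `summary` (data frame: model, mean_bic, se_bic,
#'   mean_aic, se_aic, n_failed), `bic` and `aic` (participants x models
#'   matrices) and `fits` (nested list of `bb_fitres`).
#' @export
model_comparison <- function(data, rows = table1_strategies(), n_starts = 10,
                             seed = 1) {
  stopifnot(length(rows) >= 2)
  pids <- unique(data$participant_id)
  labels <- vapply(rows, function(r) r$label, character(1))
  bic <- matrix(NA_real_, length(pids), length(rows),
                dimnames = list(as.character(pids), labels))
  aic <- bic
  fits <- list()
  for (pi_ in seq_along(pids)) {
    pd <- data[data$participant_id == pids[pi_], ]
    fits[[as.character(pids[pi_])]] <- list()
    for (ri in seq_along(rows)) {
      f <- tryCatch(
        fit_participant(pd, rows[[ri]], n_starts = n_starts,
                        seed = seed + 7919L * pi_ + 104729L * ri),
        error = function(err) err)
      fits[[as.character(pids[pi_])]][[labels[ri]]] <- f
      if (inherits(f, "bb_fitres")) {
        bic[pi_, ri] <- f$BIC
        aic[pi_, ri] <- f$AIC
      }
    }
  }
  ok <- stats::complete.cases(bic)
  se_bic <- if (sum(ok) >= 2) within_subject_se(bic[ok, , drop = FALSE])
            else rep(NA_real_, length(rows))
  se_aic <- if (sum(ok) >= 2) within_subject_se(aic[ok, , drop = FALSE])
            else rep(NA_real_, length(rows))
  summary <- data.frame(
    model = labels,
    mean_bic = colMeans(bic, na.rm = TRUE), se_bic = se_bic,
    mean_aic = colMeans(aic, na.rm = TRUE), se_aic = se_aic,
    n_failed = colSums(is.na(bic)), row.names = NULL)
  list(summary = summary, bic = bic, aic = aic, fits = fits)
}
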