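rows <- table1_strategies()

small_dataset <- function(seed = 3, n_participants = 1) {
  gen_choice_dataset(n_participants, rows$bg_hybrid,
                     c(alpha_q = 0.4, alpha_s = 0.2, lambda = 0.5, e = 1),
                     seed = seed)$data
}

test_that("a strategy forced to chance gives n log 2", {
  d <- small_dataset()
  # alpha_q = alpha_s = 0 keeps Q = S = 0, so every trial is a symmetric
  # zero-noise state resolving to probability one half
  nll <- choice_negloglik(d, rows$bg_hybrid,
                          c(alpha_q = 0, alpha_s = 0, lambda = 1, e = 0))
  expect_equal(nll, nrow(d) * log(2), tolerance = 1e-10)
})

test_that("negative log-likelihood is nonnegative and finite", {
  d <- small_dataset()
  set.seed(17)
  for (lbl in names(rows)) {
    row <- rows[[lbl]]
    pars <- (row$lower + row$upper) / 2
    names(pars) <- row$free
    nll <- choice_negloglik(d, row, pars)
    expect_true(is.finite(nll))
    expect_gte(nll, 0)
  }
})

test_that("likelihood matches a step-by-step manual trace", {
  # 5-trial hand-worked block under the directed neural row
  d <- data.frame(block = 1, trial = 1:5, choice = c(1, 2, 1, 1, 2),
                  reward = c(3, -1, 2.5, 0.5, -2))
  pars <- c(alpha_q = 0.3, alpha_s = 0.1, lambda = 0.6, e = 1.2)
  row <- rows$bg_directed
  m <- 0.677; k <- 4.486; pw <- -0.791
  Q <- c(0, 0); S <- c(0, 0); n <- c(1, 1)
  ll <- 0
  for (t in 1:5) {
    shat <- S * n^pw
    num <- (Q[1] - Q[2]) + 0.6 * m * (S[1] - S[2]) + 0.6 * k * (shat[1] -
                                                                  shat[2])
    p1 <- stats::pnorm(num / (sqrt(2) * 1.2))   # a = b = 0: den = sqrt(2) e
    p <- if (d$choice[t] == 1) p1 else 1 - p1
    ll <- ll - log(p)
    c_t <- d$choice[t]
    delta <- d$reward[t] - Q[c_t]
    Q[c_t] <- Q[c_t] + 0.3 * delta
    S[c_t] <- S[c_t] + 0.1 * (abs(delta) - S[c_t])
    n[c_t] <- n[c_t] + 1
  }
  expect_equal(choice_negloglik(d, row, pars), ll, tolerance = 1e-12)
})

test_that("likelihood is invariant to relabelling the two arms", {
  d <- small_dataset(seed = 9)
  d2 <- d
  d2$choice <- 3L - d$choice
  for (lbl in c("bg_hybrid", "kalman_hybrid", "kalman_directed")) {
    row <- rows[[lbl]]
    pars <- (row$lower + row$upper) / 4
    names(pars) <- row$free
    expect_equal(choice_negloglik(d, row, pars),
                 choice_negloglik(d2, row, pars), tolerance = 1e-12)
  }
})

test_that("fitting is deterministic under a fixed master seed", {
  d <- small_dataset(seed = 12)
  f1 <- fit_participant(d, rows$bg_value, n_starts = 6, seed = 77)
  f2 <- fit_participant(d, rows$bg_value, n_starts = 6, seed = 77)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$logLik, f2$logLik)
  expect_identical(f1$best_start, f2$best_start)
})

test_that("emitted fit results satisfy the BIC/AIC identities exactly", {
  d <- small_dataset(seed = 4)
  for (lbl in c("bg_value", "kalman_random")) {
    f <- fit_participant(d, rows[[lbl]], n_starts = 4, seed = 5)
    expect_equal(f$BIC, f$n_free_params * log(f$n_obs) - 2 * f$logLik)
    expect_equal(f$AIC, 2 * f$n_free_params - 2 * f$logLik)
  }
})

test_that("information criteria arithmetic", {
  ic <- information_criteria(-50, 2, 100)
  expect_equal(ic[["BIC"]], 2 * log(100) + 100)
  expect_equal(ic[["AIC"]], 104)
  ic0 <- information_criteria(-12.5, 0, 30)
  expect_equal(ic0[["BIC"]], 25)
  expect_equal(ic0[["AIC"]], 25)
  # equal likelihoods: BIC difference is the penalty difference alone
  d_bic <- information_criteria(-80, 4, 200)[["BIC"]] -
    information_criteria(-80, 2, 200)[["BIC"]]
  expect_equal(d_bic, 2 * log(200))
  # AIC and BIC can rank differently when parameter counts differ
  aic <- c(information_criteria(-50, 4, 200)[["AIC"]],
           information_criteria(-52.5, 2, 200)[["AIC"]])
  bic <- c(information_criteria(-50, 4, 200)[["BIC"]],
           information_criteria(-52.5, 2, 200)[["BIC"]])
  expect_true(which.min(aic) != which.min(bic))
})

test_that("within-subject standard errors remove participant offsets", {
  tab <- matrix(rep(c(100, 105, 110), 6), nrow = 6, byrow = TRUE)
  expect_equal(unname(within_subject_se(tab)), c(0, 0, 0))
  set.seed(21)
  tab2 <- matrix(stats::rnorm(40, 100, 5), 10, 4)
  shifted <- tab2 + stats::rnorm(10, 0, 50)    # per-participant offsets
  expect_equal(within_subject_se(tab2), within_subject_se(shifted))
  # reference implementation oracle
  ref <- apply(tab2 - rowMeans(tab2) + mean(tab2), 2, stats::sd) /
    sqrt(nrow(tab2))
  expect_equal(within_subject_se(tab2), ref)
  expect_error(within_subject_se(cbind(tab2, NA)), "missing")
})

test_that("duplicated model rows tie in a comparison table", {
  d <- gen_choice_dataset(2, rows$bg_value, c(alpha_q = 0.4, e = 2),
                          seed = 31)$data
  two <- list(rows$bg_value,
              utils::modifyList(rows$bg_value, list(label = "bg_value_copy")))
  cmp <- model_comparison(d, two, n_starts = 8, seed = 10)
  expect_lt(abs(diff(cmp$summary$mean_bic)), 0.5)
  expect_equal(dim(cmp$bic), c(2, 2))
})

test_that("generating parameters are recoverable from value-learner data", {
  set.seed(41)
  np <- 12
  truth <- data.frame(alpha_q = stats::runif(np, 0.1, 0.8),
                      e = stats::runif(np, 1, 4))
  g <- gen_choice_dataset(np, rows$bg_value, truth, seed = 42)
  est <- t(vapply(seq_len(np), function(p) {
    pd <- g$data[g$data$participant_id == sprintf("p%03d", p), ]
    fit_participant(pd, rows$bg_value, n_starts = 6, seed = 50 + p)$par
  }, c(alpha_q = 0, e = 0)))
  expect_gt(stats::cor(truth$alpha_q, est[, "alpha_q"]), 0)
  expect_gt(stats::cor(truth$e, est[, "e"]), 0)
})
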