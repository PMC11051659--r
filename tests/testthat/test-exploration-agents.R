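test_that("Kalman utilities implement their value definitions", {
  st <- kalman_state(2)
  st$Q <- c(1, 0); st$var <- c(0, 1)
  # directed with all bonuses off is greedy
  sp <- strategy_params("kalman", "directed", theta = 0, e = 0)
  expect_equal(kalman_utilities(st, sp), c(1, 0))
  # directed tie: Q = (1,0), sigma = (0,1), theta = 1
  sp1 <- strategy_params("kalman", "directed", theta = 1, e = 0)
  expect_equal(kalman_utilities(st, sp1), c(1, 1))
  # random: V ~ N(Q, (gamma*sigma)^2), moment oracle
  st$var <- c(1, 1)
  spr <- strategy_params("kalman", "random", gamma = 1)
  set.seed(8)
  u <- replicate(2e4, kalman_utilities(st, spr))
  expect_within(mean(u[1, ]), 1, 3 / sqrt(2e4))
  expect_within(stats::sd(u[2, ]), 1, 3 / sqrt(2 * 2e4))
  sph <- strategy_params("kalman", "hybrid")
  expect_error(kalman_utilities(st, sph), "no explicit value utility")
})

test_that("neural utility code paths agree to machine precision", {
  set.seed(77)
  dm <- dopamine_model()
  sp <- strategy_params("basal_ganglia", "hybrid", e = 0.7, lambda = 0.5,
                        dopamine = dm)
  for (rep in 1:100) {
    st <- random_learner2()
    Z <- stats::rnorm(2); Zn <- stats::rnorm(2)
    u1 <- neural_utilities(st, sp, path = "dopamine", Z = Z, Znoise = Zn)
    u2 <- neural_utilities(st, sp, path = "decomposed", Z = Z, Znoise = Zn)
    expect_true(max(abs(u1 - u2)) < 1e-12)
  }
  # lambda = 0, e = 0 decouples dopamine entirely
  sp0 <- strategy_params("basal_ganglia", "hybrid", e = 0, lambda = 0,
                         dopamine = dm)
  st <- random_learner2()
  expect_equal(neural_utilities(st, sp0), st$Q)
  # noiseless dopamine: deterministic T = Q + lambda * Dbar(n) * S
  dmq <- dopamine_model("refined", m = 0.5, k = 2, pi = -0.6, a = 0, b = 0)
  spq <- strategy_params("basal_ganglia", "directed", e = 0, lambda = 0.3,
                         dopamine = dmq)
  expect_equal(neural_utilities(st, spq),
               st$Q + 0.3 * novelty_mean(st$n, dmq) * st$S)
})

test_that("symmetric two-arm states give probability one half everywhere", {
  stl <- learner_state(2, q0 = 0.4, s0 = 0.8)
  stk <- kalman_state(2)
  stk$Q <- c(0.4, 0.4); stk$var <- c(2, 2)
  strategies <- list(
    strategy_params("kalman", "directed", theta = 1, e = 1),
    strategy_params("kalman", "random", gamma = 2),
    strategy_params("kalman", "hybrid", gamma = 1, theta = 1),
    strategy_params("kalman", "value", e = 1),
    strategy_params("basal_ganglia", "hybrid", e = 1, lambda = 0.5),
    strategy_params("basal_ganglia", "directed", e = 1, lambda = 0.5,
                    dopamine = dopamine_model("refined", a = 0, b = 0)),
    strategy_params("basal_ganglia", "random", lambda = 0.5),
    strategy_params("basal_ganglia", "value", e = 1))
  for (sp in strategies) {
    st <- if (sp$learning_rule == "kalman") stk else stl
    expect_equal(choice_prob_two_arm(st, sp), 0.5)
  }
})

test_that("Kalman UCB probability is the standard normal CDF of its ratio", {
  # choose state so that Q1-Q2 + theta(sigma1-sigma2) = sqrt(2 e^2)
  e <- 0.8; theta <- 1.5
  st <- kalman_state(2)
  st$Q <- c(sqrt(2) * e, 0)
  st$var <- c(4, 4)
  sp <- strategy_params("kalman", "directed", theta = theta, e = e)
  expect_equal(choice_prob_two_arm(st, sp), stats::pnorm(1))
  st$var <- c(9, 4)   # now the uncertainty bonus contributes
  expect_equal(choice_prob_two_arm(st, sp),
               stats::pnorm((sqrt(2) * e + theta * 1) / (sqrt(2) * e)))
})

test_that("choice probability increases with the value difference", {
  dqs <- seq(-2, 2, length.out = 21)
  strategies <- list(
    kal = list(strategy_params("kalman", "directed", theta = 1, e = 1),
               strategy_params("kalman", "random", gamma = 1),
               strategy_params("kalman", "hybrid", gamma = 1, theta = 0.5),
               strategy_params("kalman", "value", e = 1)),
    bg = list(strategy_params("basal_ganglia", "hybrid", e = 0.5,
                              lambda = 0.4),
              strategy_params("basal_ganglia", "random", lambda = 0.4),
              strategy_params("basal_ganglia", "value", e = 1)))
  for (sp in strategies$kal) {
    p <- vapply(dqs, function(d) {
      st <- kalman_state(2); st$Q <- c(d, 0); st$var <- c(3, 1.5)
      choice_prob_two_arm(st, sp)
    }, numeric(1))
    expect_true(all(diff(p) > 0))
  }
  for (sp in strategies$bg) {
    p <- vapply(dqs, function(d) {
      st <- learner_state(2, q0 = 0, s0 = 0)
      st$Q <- c(d, 0); st$S <- c(1, 0.6); st$n <- c(2, 6)
      choice_prob_two_arm(st, sp)
    }, numeric(1))
    expect_true(all(diff(p) > 0))
  }
})

test_that("undefined zero-over-zero is signalled unless tie-break requested", {
  st <- learner_state(2, q0 = 0, s0 = 0)
  sp <- strategy_params("basal_ganglia", "hybrid", e = 0, lambda = 0.5)
  expect_error(choice_prob_two_arm(st, sp), "undefined")
  expect_equal(choice_prob_two_arm(st, sp, tie_break = TRUE), 0.5)
  # zero denominator with nonzero numerator gives a degenerate choice
  st$Q <- c(1, 0)
  expect_equal(choice_prob_two_arm(st, sp), 1)
})

test_that("classic UCB indices match hand-computed tables", {
  # UCB1 on a fixed small history
  h <- list(n = c(3, 5), mean = c(0.4, 0.6), sumsq = c(1.2, 2.5))
  ix <- classic_ucb_index(h, t = 9, variant = "ucb1")
  expect_equal(ix$index,
               c(0.4 + sqrt(2 * log(9) / 3), 0.6 + sqrt(2 * log(9) / 5)))
  expect_false(any(ix$must_play))
  # symmetry: equal means and counts give equal indices
  hs <- list(n = c(4, 4), mean = c(0.5, 0.5), sumsq = c(2, 2))
  ixs <- classic_ucb_index(hs, t = 9, variant = "ucb1")
  expect_equal(ixs$index[1], ixs$index[2])
  # bonus decreases with n_j
  hb <- list(n = c(1, 4), mean = c(0.5, 0.5), sumsq = c(0.25, 1))
  ixb <- classic_ucb_index(hb, t = 5, variant = "ucb1")
  expect_gt(ixb$index[1], ixb$index[2])

  # UCB1-tuned hand table
  ixt <- classic_ucb_index(h, t = 9, variant = "ucb1_tuned")
  v <- pmax(h$sumsq / h$n - h$mean^2, 0) + sqrt(2 * log(9) / h$n)
  expect_equal(ixt$index, h$mean + sqrt(log(9) / h$n * pmin(0.25, v)))

  # UCB1-normal: forced-play rule and index
  hn <- list(n = c(2, 60), mean = c(0.5, 0.55), sumsq = c(0.7, 20))
  ixn <- classic_ucb_index(hn, t = 62, variant = "ucb1_normal")
  expect_true(ixn$must_play[1])               # 2 < ceiling(8 log 62)
  expect_false(ixn$must_play[2])
  ss2 <- hn$sumsq[2] - hn$n[2] * hn$mean[2]^2
  expect_equal(ixn$index[2],
               0.55 + sqrt(16 * ss2 / 59 * log(61) / 60))

  # UCB2 with epochs
  hu <- list(n = c(4, 6), mean = c(0.3, 0.5), sumsq = c(1, 2),
             epoch = c(2L, 3L))
  a <- 0.1
  ixu <- classic_ucb_index(hu, t = 11, variant = "ucb2", alpha_ucb = a)
  tau_r <- ceiling((1 + a)^hu$epoch)
  expect_equal(ixu$index,
               hu$mean + sqrt((1 + a) * log(exp(1) * 11 / tau_r) /
                                (2 * tau_r)))
  # unplayed arms are must-play
  expect_true(classic_ucb_index(list(n = c(0, 2), mean = c(0, 0.5),
                                     sumsq = c(0, 1)), t = 3,
                                variant = "ucb1")$must_play[1])
})

test_that("action selection: argmax, forced plays, uniform tie-breaks", {
  expect_equal(select_action(c(0.2, 0.9, 0.1)), 2)
  expect_equal(select_action(c(0.2, 0.9), must_play = c(TRUE, FALSE)), 1)
  expect_error(select_action(numeric(0)), "empty")
  set.seed(55)
  picks <- replicate(1e4, select_action(c(1, 1)))
  expect_within(mean(picks == 1), 0.5, 3 * 0.5 / sqrt(1e4))
  # K > 2: frequencies of noisy-utility argmax match a Monte-Carlo oracle
  set.seed(56)
  Q <- c(0.2, 0, -0.1)
  freq_sel <- table(factor(replicate(2e4,
    select_action(Q + 0.5 * stats::rnorm(3))), levels = 1:3)) / 2e4
  freq_mc <- table(factor(apply(matrix(stats::rnorm(3 * 2e4, sd = 0.5),
    ncol = 3, byrow = TRUE) + rep(Q, each = 2e4), 1, which.max),
    levels = 1:3)) / 2e4
  expect_true(max(abs(freq_sel - freq_mc)) < 3 * sqrt(0.5 * 0.5 / 2e4) * 2)
})
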