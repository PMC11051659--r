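# shared fixtures built in code

# a random two-arm learner state with positive spreads and counts
random_learner2 <- function() {
  st <- learner_state(2, q0 = 0, s0 = 0)
  st$Q <- stats::rnorm(2)
  st$S <- stats::runif(2, 0.3, 2)
  st$G <- st$S + st$Q
  st$N <- st$S - st$Q
  st$n <- sample(1:10, 2, replace = TRUE)
  st
}

# a random two-arm Kalman state part-way through learning
random_kalman2 <- function() {
  st <- kalman_state(2, prior_mean = 0, prior_var = 100, reward_var = 10)
  st$Q <- stats::rnorm(2)
  st$var <- stats::runif(2, 0.5, 20)
  st
}

# Monte-Carlo frequency that utility 1 beats utility 2, given a function
# drawing M pairs of utilities; independent oracle for closed-form checks
mc_choice_freq <- function(draw_fn, M = 1e6) {
  u <- draw_fn(M)
  mean(u[[1]] > u[[2]])
}

expect_within <- function(x, target, tol) {
  expect_true(abs(x - target) <= tol,
              label = sprintf("|%.6g - %.6g| <= %.3g", x, target, tol))
}
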