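make_traces <- function(n_neurons, n_index, f, noise_sd = 0) {
  do.call(rbind, lapply(seq_len(n_neurons), function(i) {
    n <- seq_len(n_index)
    data.frame(neuron_id = sprintf("n%02d", i), n = n,
               rate = f(n) + stats::rnorm(n_index, 0, noise_sd))
  }))
}

test_that("noiseless data is recovered exactly by its own family", {
  tr <- make_traces(4, 12, function(n) 0.5 + 2 / sqrt(n))
  fi <- fit_average_curve(tr, "inverse_sqrt")
  expect_equal(unname(fi$par), c(0.5, 2), tolerance = 1e-8)
  expect_lt(fi$rss, 1e-12)
  tr2 <- make_traces(4, 12, function(n) 0.7 + 3 * n^(-0.8))
  fp <- fit_average_curve(tr2, "power", n_starts = 25)
  expect_equal(unname(fp$par), c(0.7, 3, -0.8), tolerance = 1e-3)
  tr3 <- make_traces(4, 12, function(n) 0.4 + 2 * exp(-0.35 * n))
  fe <- fit_average_curve(tr3, "exponential", n_starts = 25)
  expect_equal(unname(fe$par), c(0.4, 2, -0.35), tolerance = 1e-3)
})

test_that("power fit pinned at -1/2 reproduces the inverse-sqrt fit exactly", {
  set.seed(61)
  g <- gen_dopamine_traces(n_neurons = 30, n_index = 12, seed = 61)
  fi <- fit_average_curve(g$traces, "inverse_sqrt")
  fp <- fit_average_curve(g$traces, "power", pin_pi = -0.5)
  expect_equal(unname(fp$par[1:2]), unname(fi$par), tolerance = 1e-12)
  expect_equal(fp$logLik, fi$logLik, tolerance = 1e-12)
  expect_equal(fp$BIC, fi$BIC, tolerance = 1e-12)
})

test_that("the 3-parameter power family never fits worse than its nested form", {
  for (s in 1:5) {
    g <- gen_dopamine_traces(n_neurons = 20, n_index = 12, seed = 70 + s)
    fi <- fit_average_curve(g$traces, "inverse_sqrt")
    fp <- fit_average_curve(g$traces, "power", n_starts = 25)
    expect_gte(fp$logLik, fi$logLik - 1e-6)
  }
})

test_that("average-curve ML fit agrees with an independent NLS implementation", {
  g <- gen_dopamine_traces(n_neurons = 40, n_index = 15, seed = 91)
  fp <- fit_average_curve(g$traces, "power", n_starts = 30)
  y <- tapply(g$traces$rate, g$traces$n, mean)
  df <- data.frame(n = as.numeric(names(y)), y = as.numeric(y))
  ref <- minpack.lm::nlsLM(y ~ m + k * n^p, data = df,
                           start = list(m = 0.5, k = 4, p = -0.7))
  expect_equal(unname(fp$par), unname(stats::coef(ref)), tolerance = 1e-4)
})

test_that("estimation error of the shape parameter shrinks with data size", {
  sizes <- c(8, 32, 128)
  rmse <- vapply(sizes, function(nn) {
    est <- vapply(1:8, function(r) {
      g <- gen_dopamine_traces(n_neurons = nn, n_index = 15,
                               seed = 1000 * nn + r)
      fit_average_curve(g$traces, "power", n_starts = 20)$par["pi"]
    }, numeric(1))
    sqrt(mean((est + 0.791)^2))
  }, numeric(1))
  expect_lt(rmse[3], rmse[1])
})

test_that("hierarchical two-stage fit behaves like a mixed-effects model", {
  # degenerate population: identical parameters, no noise
  tr <- make_traces(5, 12, function(n) 0.7 + 3 * n^(-0.8))
  h <- fit_per_neuron_hierarchical(tr, "power", mode = "joint",
                                   n_starts = 10)
  expect_equal(unname(h$fixed), c(0.7, 3, -0.8), tolerance = 1e-3)
  expect_lt(max(abs(h$random)), 1e-4)

  # population recovery with independent random effects; response noise kept
  # moderate so single-neuron traces remain informative
  dml <- dopamine_model("refined", a = 0.3, b = 0.05)
  g <- gen_dopamine_traces(n_neurons = 30, n_index = 15, model = dml,
                           random_effects = list(sd_m = 0.2, sd_logk = 0.15,
                                                 sd_pi = 0.08),
                           seed = 63)
  h2 <- fit_per_neuron_hierarchical(g$traces, "power", mode = "independent",
                                    n_starts = 12)
  # fixed effects near population truth (loose simulation CI)
  expect_within(h2$fixed["m"], 0.677, 0.5)
  expect_within(h2$fixed["pi"], -0.791, 0.4)
  expect_equal(nrow(h2$per_neuron), 30)

  # independent mode not worse than joint on uncorrelated truth (majority);
  # at low measurement noise the per-neuron estimates reflect the truly
  # uncorrelated population rather than correlated estimation error
  dms <- dopamine_model("refined", a = 0.05, b = 0.01)
  wins <- 0
  for (s in 1:5) {
    gs <- gen_dopamine_traces(n_neurons = 15, n_index = 15, model = dms,
                              random_effects = list(sd_m = 0.2,
                                                    sd_logk = 0.15,
                                                    sd_pi = 0.08),
                              seed = 600 + s)
    hj <- fit_per_neuron_hierarchical(gs$traces, "power", "joint",
                                      n_starts = 8)
    hi <- fit_per_neuron_hierarchical(gs$traces, "power", "independent",
                                      n_starts = 8)
    wins <- wins + (hi$BIC <= hj$BIC)
  }
  expect_gte(wins, 3)

  # neurons with too few points are dropped with a warning
  short <- rbind(tr, data.frame(neuron_id = "tiny", n = 1:2,
                                rate = c(1, 0.5)))
  expect_warning(fit_per_neuron_hierarchical(short, "power", n_starts = 5),
                 "dropped")
})

test_that("mean-s.d. regression recovers exact affine relations", {
  # construct per-index rate pairs with mean mu and s.d. exactly 1 + 0.3 mu
  mu <- c(5, 4, 3, 2, 1)
  tr <- do.call(rbind, lapply(seq_along(mu), function(i) {
    s <- 1 + 0.3 * mu[i]
    d <- s / sqrt(2)                # sd of c(x-d, x+d) is d*sqrt(2)
    data.frame(neuron_id = c("a", "b"), n = i, rate = mu[i] + c(-d, d))
  }))
  r <- suppressWarnings(mean_sd_regression(tr))  # lm warns on a perfect fit
  expect_equal(r$a, 1, tolerance = 1e-10)
  expect_equal(r$b, 0.3, tolerance = 1e-10)
  expect_equal(r$r, 1, tolerance = 1e-10)
  # degenerate regressor: constant mean across indices
  tr_bad <- do.call(rbind, lapply(1:4, function(i)
    data.frame(neuron_id = c("a", "b"), n = i, rate = c(1 - 0.1 * i,
                                                        1 + 0.1 * i))))
  expect_error(mean_sd_regression(tr_bad), "degenerate")
})
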