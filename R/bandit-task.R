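#' Reward distribution for a bandit arm
#'
#' Constructs a validated per-arm reward distribution. Two families are
#' supported: Bernoulli rewards in \{0, 1\} with success probability `p`, and
#' Gaussian rewards with mean `mu` and standard deviation `sigma`.
#'
#' @param family `"bernoulli"` or `"gaussian"`.
#' @param p Success probability (Bernoulli only), in \[0, 1\].
#' @param mu Mean reward (Gaussian only).
#' @param sigma Reward standard deviation (Gaussian only), strictly positive.
#'
#' @return An object of class `"bb_dist"`: a list with the distribution family
#'   and its parameters.
#' @examples
#' d <- reward_dist("bernoulli", p = 0.55)
#' dist_mean(d)
#' dist_mad(d)   # mean absolute deviation, 2p(1-p)
#' @export
reward_dist <- function(family = c("bernoulli", "gaussian"), p = NULL,
                        mu = NULL, sigma = NULL) {
  family <- match.arg(family)
  if (family == "bernoulli") {
    if (is.null(p) || !is.finite(p) || p < 0 || p > 1)
      stop("bernoulli reward distribution requires p in [0, 1]")
    out <- list(family = "bernoulli", p = as.numeric(p))
  } else {
    if (is.null(mu) || !is.finite(mu))
      stop("gaussian reward distribution requires finite mu")
    if (is.null(sigma) || !is.finite(sigma) || sigma <= 0)
      stop("gaussian reward distribution requires sigma > 0")
    out <- list(family = "gaussian", mu = as.numeric(mu),
                sigma = as.numeric(sigma))
  }
  class(out) <- "bb_dist"
  out
}

#' Analytic mean of a reward distribution
#' @param d A [reward_dist()] object.
#' @return Expected reward: `p` for Bernoulli, `mu` for Gaussian.
#' @export
dist_mean <- function(d) {
  stopifnot(inherits(d, "bb_dist"))
  if (d$family == "bernoulli") d$p else d$mu
}

#' Analytic mean absolute deviation of a reward distribution
#'
#' The mean absolute deviation E|R - E R| is the quantity the reward-spread
#' estimate S converges to under the idealised GO/NO-GO learning rule, so it
#' is exposed analytically: `2p(1-p)` for Bernoulli, `sigma*sqrt(2/pi)` for
#' Gaussian.
#'
#' @param d A [reward_dist()] object.
#' @return The mean absolute deviation.
#' @export
dist_mad <- function(d) {
  stopifnot(inherits(d, "bb_dist"))
  if (d$family == "bernoulli") 2 * d$p * (1 - d$p)
  else d$sigma * sqrt(2 / pi)
}

# Catalogue of benchmark tasks. Exact reward margins for the ten-arm tasks are
# package defaults (overridable): one best arm and K-1 identical worse arms.
.bb_task_catalogue <- function() {
  list(
    ten_arm_bernoulli_A = list(K = 10, tau = 2000, family = "bernoulli",
                               mu_plus = 0.55, mu_minus = 0.45),
    ten_arm_bernoulli_B = list(K = 10, tau = 2000, family = "bernoulli",
                               mu_plus = 0.9, mu_minus = 0.8),
    ten_arm_gaussian_C  = list(K = 10, tau = 2000, family = "gaussian",
                               mu_plus = 0.55, mu_minus = 0.45, sigma = 0.3),
    two_arm_gaussian_D  = list(K = 2, tau = 10, family = "gaussian",
                               block_resampling = list(mean_prior_mu = 0,
                                                       mean_prior_var = 100,
                                                       fixed_reward_var = 10)),
    six_arm_bernoulli_E = list(K = 6, tau = 1000, family = "bernoulli",
                               mu_plus = 0.3, mu_minus = 0.2)
  )
}

#' Construct a multi-armed bandit task
#'
#' Builds a stationary K-armed bandit task either from the benchmark catalogue
#' or from a custom arm list. Catalogue entries:
#' \describe{
#'   \item{`ten_arm_bernoulli_A`}{K = 10 Bernoulli arms, one best arm
#'     (defaults mu+ = 0.55, mu- = 0.45).}
#'   \item{`ten_arm_bernoulli_B`}{K = 10 Bernoulli arms, mu+ = 0.9, mu- = 0.8.}
#'   \item{`ten_arm_gaussian_C`}{K = 10 Gaussian arms with the same means as
#'     task A and common sigma = 0.3.}
#'   \item{`two_arm_gaussian_D`}{K = 2 Gaussian arms, 10 trials per block,
#'     per-block mean resampling from N(0, 100) with reward variance fixed
#'     at 10 (the two-armed behavioural-experiment design).}
#'   \item{`six_arm_bernoulli_E`}{K = 6 Bernoulli arms, one best arm in a
#'     low-reward environment (defaults 0.3 vs 0.2).}
#' }
#' The reward margins of the ten-arm and six-arm tasks are package defaults,
#' overridable through `mu_plus` / `mu_minus`. The best arm's physical index
#' is fixed (arm 1) across repeated runs.
#'
#' @param spec Catalogue name, or a list with fields `arms` (list of
#'   [reward_dist()] or plain lists with `family`/`p`/`mu`/`sigma`), `tau`,
#'   and optionally `block_resampling` (list with `mean_prior_mu`,
#'   `mean_prior_var`, `fixed_reward_var`). A list with a `name` field is
#'   treated as a catalogue entry plus overrides.
#' @param mu_plus,mu_minus Optional overrides of the catalogue reward margins.
#' @param tau Optional override of trials per block.
#'
#' @return An object of class `"bb_task"`: list with `K`, `tau`, `arms`,
#'   `block_resampling` (or NULL), `optimal_mean`, `optimal_arm`, `name`.
#' @examples
#' task <- make_task("ten_arm_gaussian_C")
#' task$K
#' sapply(task$arms, dist_mean)
#' @export
make_task <- function(spec, mu_plus = NULL, mu_minus = NULL, tau = NULL) {
  if (is.character(spec)) spec <- list(name = spec)
  stopifnot(is.list(spec))

  if (!is.null(spec$name)) {
    cat <- .bb_task_catalogue()
    if (!spec$name %in% names(cat))
      stop("unknown catalogue task: ", spec$name)
    entry <- cat[[spec$name]]
    if (!is.null(mu_plus)) entry$mu_plus <- mu_plus
    if (!is.null(mu_minus)) entry$mu_minus <- mu_minus
    if (!is.null(tau)) entry$tau <- tau
    if (!is.null(spec$tau)) entry$tau <- spec$tau

    if (!is.null(entry$block_resampling)) {
      # task D: means are placeholders until resample_block_means() is called
      arms <- replicate(entry$K, reward_dist("gaussian", mu = 0,
                          sigma = sqrt(entry$block_resampling$fixed_reward_var)),
                        simplify = FALSE)
    } else {
      if (entry$mu_plus <= entry$mu_minus)
        stop("mu_plus must exceed mu_minus")
      means <- c(entry$mu_plus, rep(entry$mu_minus, entry$K - 1))
      arms <- lapply(means, function(m) {
        if (entry$family == "bernoulli") reward_dist("bernoulli", p = m)
        else reward_dist("gaussian", mu = m, sigma = entry$sigma)
      })
    }
    task <- list(K = entry$K, tau = entry$tau, arms = arms,
                 block_resampling = entry$block_resampling,
                 name = spec$name)
  } else {
    if (is.null(spec$arms)) stop("custom task spec requires an arm list")
    arms <- lapply(spec$arms, function(a) {
      if (inherits(a, "bb_dist")) a
      else do.call(reward_dist, a)
    })
    if (length(arms) < 2) stop("a bandit task requires K >= 2 arms")
    tau_use <- if (!is.null(tau)) tau else spec$tau
    if (is.null(tau_use) || tau_use < 1) stop("tau must be >= 1")
    task <- list(K = length(arms), tau = as.integer(tau_use), arms = arms,
                 block_resampling = spec$block_resampling,
                 name = if (is.null(spec$label)) "custom" else spec$label)
  }
  task$optimal_mean <- max(vapply(task$arms, dist_mean, numeric(1)))
  task$optimal_arm <- which.max(vapply(task$arms, dist_mean, numeric(1)))
  class(task) <- "bb_task"
  task
}

#' @export
print.bb_task <- function(x, ...) {
  cat(sprintf("<bb_task '%s': K = %d, tau = %d, optimal mean = %.4g>\n",
              x$name, x$K, x$tau, x$optimal_mean))
  invisible(x)
}

#' Redraw per-block arm means for a resampling task
#'
#' For tasks with an active `block_resampling` rule, every block start redraws
#' each arm's mean independently from the Gaussian mean prior while keeping the
#' reward variance fixed. Uses the current R random stream.
#'
#' @param task A [make_task()] object.
#' @return The task with resolved arm means (and `optimal_mean`/`optimal_arm`
#'   updated). Tasks without a resampling rule are returned unchanged.
#' @export
resample_block_means <- function(task) {
  stopifnot(inherits(task, "bb_task"))
  br <- task$block_resampling
  if (is.null(br)) return(task)
  mus <- stats::rnorm(task$K, br$mean_prior_mu, sqrt(br$mean_prior_var))
  sd_r <- sqrt(br$fixed_reward_var)
  task$arms <- lapply(mus, function(m) reward_dist("gaussian", mu = m,
                                                   sigma = sd_r))
  task$optimal_mean <- max(mus)
  task$optimal_arm <- which.max(mus)
  task
}

#' Sample a reward from one arm
#'
#' Draws a single reward from the arm's distribution using the current R
#' random stream (seed before calling for reproducibility). Bernoulli arms
#' return exactly 0 or 1.
#'
#' @param task A [make_task()] object (means resolved).
#' @param arm 1-based arm index.
#' @return Scalar reward.
#' @export
sample_reward <- function(task, arm) {
  stopifnot(inherits(task, "bb_task"))
  if (arm < 1 || arm > task$K) stop("arm index out of range")
  d <- task$arms[[arm]]
  if (d$family == "bernoulli") as.numeric(stats::runif(1) < d$p)
  else stats::rnorm(1, d$mu, d$sigma)
}

#' Per-trial regret of choosing an arm
#'
#' Regret is the difference between the expected reward of the optimal arm and
#' that of the chosen arm; it is deterministic given the (resolved) task and
#' always lies in \[0, mu+ - mu-\].
#'
#' @param task A [make_task()] object with resolved means.
#' @param arm 1-based chosen arm index.
#' @return Nonnegative scalar regret.
#' @export
per_trial_regret <- function(task, arm) {
  stopifnot(inherits(task, "bb_task"))
  if (arm < 1 || arm > task$K) stop("arm index out of range")
  task$optimal_mean - dist_mean(task$arms[[arm]])
}

#' Read a task specification from JSON or YAML
#'
#' The file holds either `{"name": "<catalogue entry>", ...overrides}` or a
#' full custom spec `{"arms": [...], "tau": ..., "block_resampling": ...}`.
#'
#' @param path File path; format chosen by extension (`.json` vs `.yml`/`.yaml`).
#' @return A [make_task()] object.
#' @export
read_task_spec <- function(path) {
  spec <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  make_task(spec)
}
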