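# registry for plug-in simulation agents (e.g. external actor-critic models)
.sim_registry <- new.env(parent = emptyenv())

#' Register a plug-in simulation agent
#'
#' Extends the simulation harness with a new agent kind without touching the
#' core. An agent is three functions:
#' `init(task)` returning an opaque state, `choose(state, task, t)` returning
#' `list(arm, state)`, and `learn(state, task, arm, reward)` returning the
#' updated state. Registered kinds are available to [sim_strategy()] and
#' [run_block()].
#'
#' @param kind Agent name (string).
#' @param init,choose,learn The three agent functions.
#' @return `kind`, invisibly.
#' @export
register_sim_agent <- function(kind, init, choose, learn) {
  stopifnot(is.character(kind), is.function(init), is.function(choose),
            is.function(learn))
  assign(kind, list(init = init, choose = choose, learn = learn),
         envir = .sim_registry)
  invisible(kind)
}

.BUILTIN_KINDS <- c("ucb1", "ucb2", "ucb1_tuned", "ucb1_normal",
                    "kalman_ucb", "neural", "egreedy", "random_uniform")

#' Define a simulation strategy
#'
#' Bundles an agent kind with its parameters for the simulation harness.
#' Built-in kinds:
#' \describe{
#'   \item{ucb1, ucb2, ucb1_tuned, ucb1_normal}{Classic deterministic UCB
#'     algorithms ([classic_ucb_index()]); `alpha_ucb` applies to ucb2.}
#'   \item{kalman_ucb}{Kalman-filter learning with deterministic
#'     upper-confidence selection Q + theta*sigma (e = 0); `theta`,
#'     `prior_mean`, `prior_var`, `reward_var`.}
#'   \item{neural}{Basal-ganglia directed strategy in its deterministic
#'     simulation configuration (a = b = m = 0, k = 1, e = 0): index
#'     Q + lambda * S * n^pi with idealised Q/S learning; `lambda`,
#'     `alpha_q`, `alpha_s`, `pi`, `rate_mode` ("fixed" or "dynamic", the
#'     latter decaying the rates as n^pi), `q0`/`s0` initial estimates.}
#'   \item{egreedy}{Sample-mean learning; probability `epsilon` of a uniform
#'     random arm, otherwise greedy.}
#'   \item{random_uniform}{Uniform random choice (floor reference).}
#' }
#' Any kind previously added with [register_sim_agent()] is also accepted;
#' its parameters are passed through.
#'
#' @param kind Agent kind.
#' @param ... Parameters for the kind (see Details).
#' @return An object of class `"bb_simstrategy"`.
#' @export
sim_strategy <- function(kind, ...) {
  pars <- list(...)
  if (!(kind %in% .BUILTIN_KINDS || exists(kind, envir = .sim_registry)))
    stop("unknown strategy kind: ", kind)
  defaults <- switch(kind,
    ucb2 = list(alpha_ucb = 0.1),
    kalman_ucb = list(theta = 1, prior_mean = 0.5, prior_var = 100,
                      reward_var = NULL),
    neural = list(lambda = 1, alpha_q = 0.1, alpha_s = 0.05, pi = -0.5,
                  rate_mode = "fixed", q0 = 0.5, s0 = 0.5),
    egreedy = list(epsilon = 0.1),
    list())
  pars <- utils::modifyList(defaults, pars)
  structure(c(list(kind = kind), pars), class = "bb_simstrategy")
}

#' @export
print.bb_simstrategy <- function(x, ...) {
  p <- x[setdiff(names(x), "kind")]
  cat(sprintf("<bb_simstrategy %s%s>\n", x$kind,
              if (length(p)) paste0(": ", paste(sprintf("%s = %s", names(p),
                vapply(p, function(v) paste(format(v), collapse = "/"),
                       character(1))), collapse = ", ")) else ""))
  invisible(x)
}

#' Simulate one block of a bandit task
#'
#' Runs `tau` trials of select-reward-learn for one strategy on one task
#' instance. For mean-resampling tasks the arm means are redrawn at the block
#' start. Identical seeds give identical trajectories.
#'
#' Initialisation follows the benchmark convention: mean-reward and spread
#' estimators start at 0.5 for the fixed catalogue tasks and at 0 for the
#' mean-resampling two-arm task (the `neural` and `kalman_ucb` defaults are
#' overridden automatically for tasks with a resampling rule); classic UCB
#' variants use their own forced initial plays.
#'
#' @param strategy A [sim_strategy()].
#' @param task A [make_task()] object.
#' @param seed Integer seed for the block.
#' @return Data frame with per-trial `trial`, `choice`, `reward`, `regret`,
#'   plus attribute `"task_means"` (resolved arm means).
#' @export
run_block <- function(strategy, task, seed = 1) {
  stopifnot(inherits(strategy, "bb_simstrategy"), inherits(task, "bb_task"))
  set.seed(seed)
  task <- resample_block_means(task)
  means <- vapply(task$arms, dist_mean, numeric(1))
  opt <- max(means)
  K <- task$K
  tau <- task$tau

  runner <- switch(strategy$kind,
    ucb1 = , ucb1_tuned = , ucb1_normal = .run_ucb1_family,
    ucb2 = .run_ucb2,
    kalman_ucb = .run_kalman_ucb,
    neural = .run_neural,
    egreedy = .run_egreedy,
    random_uniform = .run_random,
    .run_plugin)
  res <- runner(strategy, task, K, tau)
  if (any(!is.finite(res$reward)))
    stop("non-finite state encountered; diverged configuration")
  out <- data.frame(trial = seq_len(tau), choice = res$choice,
                    reward = res$reward, regret = opt - means[res$choice])
  attr(out, "task_means") <- means
  out
}

.draw_rewards <- function(task) {
  # pre-draw one reward per (trial, arm) so the trajectory consumes a fixed
  # randomness layout; rewards for unchosen arms are simply discarded
  K <- task$K
  tau <- task$tau
  fam <- vapply(task$arms, function(a) a$family, character(1))
  mat <- matrix(0, tau, K)
  for (j in seq_len(K)) {
    a <- task$arms[[j]]
    mat[, j] <- if (fam[j] == "bernoulli")
      as.numeric(stats::runif(tau) < a$p)
    else stats::rnorm(tau, a$mu, a$sigma)
  }
  mat
}

.run_ucb1_family <- function(strategy, task, K, tau) {
  R <- .draw_rewards(task)
  n <- numeric(K); xbar <- numeric(K); sumsq <- numeric(K)
  choice <- integer(tau); reward <- numeric(tau)
  for (t in seq_len(tau)) {
    ix <- classic_ucb_index(list(n = n, mean = xbar, sumsq = sumsq), t,
                            variant = strategy$kind)
    arm <- if (any(ix$must_play)) which(ix$must_play)[1]
           else select_action(ix$index)
    r <- R[t, arm]
    n[arm] <- n[arm] + 1
    xbar[arm] <- xbar[arm] + (r - xbar[arm]) / n[arm]
    sumsq[arm] <- sumsq[arm] + r^2
    choice[t] <- arm; reward[t] <- r
  }
  list(choice = choice, reward = reward)
}

.run_ucb2 <- function(strategy, task, K, tau) {
  R <- .draw_rewards(task)
  n <- numeric(K); xbar <- numeric(K); sumsq <- numeric(K)
  epoch <- integer(K)
  pending_arm <- 0L; pending_left <- 0L
  alpha_ucb <- strategy$alpha_ucb
  choice <- integer(tau); reward <- numeric(tau)
  for (t in seq_len(tau)) {
    if (pending_left > 0L) {
      arm <- pending_arm
      pending_left <- pending_left - 1L
    } else {
      ix <- classic_ucb_index(list(n = n, mean = xbar, sumsq = sumsq,
                                   epoch = epoch), t,
                              variant = "ucb2", alpha_ucb = alpha_ucb)
      if (any(ix$must_play)) {
        arm <- which(ix$must_play)[1]
      } else {
        arm <- select_action(ix$index)
        # play the selected arm tau(r+1) - tau(r) times, then advance r
        tr <- ceiling((1 + alpha_ucb)^epoch[arm])
        tr1 <- ceiling((1 + alpha_ucb)^(epoch[arm] + 1L))
        pending_arm <- arm
        pending_left <- max(tr1 - tr, 1L) - 1L
        epoch[arm] <- epoch[arm] + 1L
      }
    }
    r <- R[t, arm]
    n[arm] <- n[arm] + 1
    xbar[arm] <- xbar[arm] + (r - xbar[arm]) / n[arm]
    sumsq[arm] <- sumsq[arm] + r^2
    choice[t] <- arm; reward[t] <- r
  }
  list(choice = choice, reward = reward)
}

.init_level <- function(task, value) {
  # 0.5 initial estimates for fixed tasks, 0 for mean-resampling tasks
  if (!is.null(task$block_resampling)) 0 else value
}

.run_kalman_ucb <- function(strategy, task, K, tau) {
  R <- .draw_rewards(task)
  rv <- strategy$reward_var
  if (is.null(rv)) {
    # default observation variance: the arms' actual reward variance
    a1 <- task$arms[[1]]
    rv <- if (a1$family == "gaussian") a1$sigma^2 else 0.25
  }
  q0 <- .init_level(task, strategy$prior_mean)
  Q <- rep(q0, K); v <- rep(strategy$prior_var, K)
  th <- strategy$theta
  choice <- integer(tau); reward <- numeric(tau)
  for (t in seq_len(tau)) {
    idx <- Q + th * sqrt(v)
    arm <- select_action(idx)
    r <- R[t, arm]
    g <- v[arm] / (v[arm] + rv)
    Q[arm] <- Q[arm] + g * (r - Q[arm])
    v[arm] <- (1 - g) * v[arm]
    choice[t] <- arm; reward[t] <- r
  }
  list(choice = choice, reward = reward)
}

.run_neural <- function(strategy, task, K, tau) {
  R <- .draw_rewards(task)
  q0 <- .init_level(task, strategy$q0)
  s0 <- .init_level(task, strategy$s0)
  Q <- rep(q0, K); S <- rep(s0, K); n <- rep(1, K)
  lam <- strategy$lambda; pw <- strategy$pi
  dynamic <- identical(strategy$rate_mode, "dynamic")
  aq <- strategy$alpha_q; as_ <- strategy$alpha_s
  choice <- integer(tau); reward <- numeric(tau)
  for (t in seq_len(tau)) {
    idx <- Q + lam * S * n ^ pw
    arm <- select_action(idx)
    r <- R[t, arm]
    if (dynamic) {
      scale <- n[arm] ^ pw     # m = 0, k = 1: rates decay with novelty
      aq_t <- aq * scale; as_t <- as_ * scale
    } else {
      aq_t <- aq; as_t <- as_
    }
    delta <- r - Q[arm]
    Q[arm] <- Q[arm] + aq_t * delta
    S[arm] <- S[arm] + as_t * (abs(delta) - S[arm])
    n[arm] <- n[arm] + 1
    choice[t] <- arm; reward[t] <- r
  }
  list(choice = choice, reward = reward)
}

.run_egreedy <- function(strategy, task, K, tau) {
  R <- .draw_rewards(task)
  n <- numeric(K); xbar <- numeric(K)
  eps <- strategy$epsilon
  choice <- integer(tau); reward <- numeric(tau)
  for (t in seq_len(tau)) {
    if (t <= K) {
      arm <- t                      # forced initial play of each arm
    } else if (stats::runif(1) < eps) {
      arm <- sample.int(K, 1)
    } else {
      arm <- select_action(xbar)
    }
    r <- R[t, arm]
    n[arm] <- n[arm] + 1
    xbar[arm] <- xbar[arm] + (r - xbar[arm]) / n[arm]
    choice[t] <- arm; reward[t] <- r
  }
  list(choice = choice, reward = reward)
}

.run_random <- function(strategy, task, K, tau) {
  R <- .draw_rewards(task)
  choice <- sample.int(K, tau, replace = TRUE)
  list(choice = choice, reward = R[cbind(seq_len(tau), choice)])
}

.run_plugin <- function(strategy, task, K, tau) {
  agent <- get(strategy$kind, envir = .sim_registry)
  state <- agent$init(task)
  choice <- integer(tau); reward <- numeric(tau)
  for (t in seq_len(tau)) {
    ch <- agent$choose(state, task, t)
    arm <- ch$arm
    state <- ch$state
    r <- sample_reward(task, arm)
    state <- agent$learn(state, task, arm, r)
    choice[t] <- arm; reward[t] <- r
  }
  list(choice = choice, reward = reward)
}

#' Run a repeated-block simulation experiment
#'
#' Performs `n_runs` independent seeded blocks ([run_block()]) and aggregates
#' the per-trial regret: mean and standard error across runs, plus the mean
#' total regret. Run seeds are derived deterministically from `master_seed`
#' (seed + run index), so two strategies evaluated under the same master seed
#' share reward streams -- common random numbers that sharpen comparisons at
#' reduced run counts.
#'
#' @param strategy A [sim_strategy()].
#' @param task A [make_task()] object.
#' @param n_runs Number of repeated runs (>= 2).
#' @param master_seed Master seed.
#' @return An object of class `"bb_regret"`: list with `mean_regret` and
#'   `se_regret` (per-trial vectors), `total_regret` (mean over runs of the
#'   summed regret), `regret_bound` (max minus min arm mean; NA for
#'   mean-resampling tasks), `n_runs`, `task`, `strategy`, `master_seed`.
#' @export
run_experiment <- function(strategy, task, n_runs = 200, master_seed = 1) {
  stopifnot(n_runs >= 2)
  tau <- task$tau
  regret <- matrix(0, n_runs, tau)
  for (r in seq_len(n_runs)) {
    blk <- run_block(strategy, task, seed = master_seed + r)
    regret[r, ] <- blk$regret
  }
  bound <- if (is.null(task$block_resampling)) {
    mm <- vapply(task$arms, dist_mean, numeric(1))
    max(mm) - min(mm)
  } else NA_real_
  structure(list(mean_regret = colMeans(regret),
                 se_regret = apply(regret, 2, stats::sd) / sqrt(n_runs),
                 total_regret = mean(rowSums(regret)),
                 regret_bound = bound,
                 n_runs = n_runs, task = task$name,
                 strategy = strategy$kind, params = unclass(strategy),
                 master_seed = master_seed),
            class = "bb_regret")
}

#' @export
print.bb_regret <- function(x, ...) {
  cat(sprintf(
    "<bb_regret %s on %s: total regret %.3f over %d trials (%d runs)>\n",
    x$strategy, x$task, x$total_regret, length(x$mean_regret), x$n_runs))
  invisible(x)
}

#' Coarse grid optimisation of strategy parameters
#'
#' Evaluates every row of a parameter grid by [run_experiment()] under a
#' shared master seed (common random numbers across candidates) and returns
#' the parameters minimising the mean total regret, together with the full
#' evaluation table. This is the crude global search used to give every
#' strategy its best shot on each task before benchmark comparisons.
#'
#' @param kind Strategy kind passed to [sim_strategy()].
#' @param task A [make_task()] object.
#' @param grid Data frame (one candidate per row) or named list of value
#'   vectors (expanded by [expand.grid()]).
#' @param fixed Named list of parameters common to all candidates.
#' @param n_runs Runs per candidate.
#' @param master_seed Shared master seed.
#' @return List with `best` (named parameter list), `best_total_regret` and
#'   `table` (grid plus `total_regret` column).
#' @export
optimize_strategy_params <- function(kind, task, grid, fixed = list(),
                                     n_runs = 50, master_seed = 1) {
  if (!is.data.frame(grid)) grid <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 0) stop("empty parameter grid")
  total <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    pars <- c(as.list(grid[i, , drop = FALSE]), fixed)
    strat <- do.call(sim_strategy, c(list(kind = kind), pars))
    total[i] <- run_experiment(strat, task, n_runs = n_runs,
                               master_seed = master_seed)$total_regret
  }
  best_i <- which.min(total)
  out_tab <- cbind(grid, total_regret = total)
  list(best = as.list(grid[best_i, , drop = FALSE]),
       best_total_regret = total[best_i], table = out_tab)
}

#' Export a regret summary as a plot-ready data frame
#'
#' @param x A `"bb_regret"` object.
#' @return Data frame with `trial`, `mean_regret`, `se_regret`, `task`,
#'   `strategy`.
#' @export
regret_table <- function(x) {
  stopifnot(inherits(x, "bb_regret"))
  data.frame(trial = seq_along(x$mean_regret), mean_regret = x$mean_regret,
             se_regret = x$se_regret, task = x$task, strategy = x$strategy)
}
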