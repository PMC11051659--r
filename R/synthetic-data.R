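# FNV-1a 32-bit hash of a character scalar; used only for provenance headers
.fnv1a <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256                      # xor touches the low byte only
    h <- h - lo + bitwXor(lo, b)
    # h * 16777619 mod 2^32 in 16-bit halves (stays within double precision)
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.provenance_header <- function(kind, seed, spec) {
  ver <- tryCatch(as.character(utils::packageVersion("banditbg")),
                  error = function(e) "dev")
  spec_hash <- .fnv1a(paste(deparse(spec), collapse = ""))
  c(sprintf("# banditbg v%s %s", ver, kind),
    sprintf("# seed=%s spec_hash=%s", as.character(seed), spec_hash))
}

.write_csv_with_header <- function(df, path, header) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Generate synthetic dopaminergic novelty traces
#'
#' Emulates the shape of trial-indexed normalised firing-rate recordings:
#' for each neuron and presentation index n, the rate is drawn from
#' \eqn{N(m + k n^\pi,\ (a + b(m + k n^\pi))^2)} -- the refined dopamine
#' novelty model. Optionally, per-neuron curve parameters are drawn from a
#' random-effects distribution: independent normal deviations on m and pi and
#' log-normal on k (keeping the mean response positive), or a joint Gaussian
#' on (m, log k, pi) when a covariance matrix is supplied. The response-noise
#' parameters a and b stay at their population values.
#'
#' The defaults (58 neurons, 15 presentation indices, refined-model constants)
#' reproduce the dimensions of the Pavlovian-task recordings that the
#' curve-fitting module is designed for.
#'
#' @param n_neurons Number of neurons (default 58).
#' @param n_index Number of presentation indices per neuron (default 15).
#' @param model A [dopamine_model()] giving the population curve (default:
#'   refined model with the data-derived constants).
#' @param random_effects NULL (none), a list with any of `sd_m`, `sd_logk`,
#'   `sd_pi` (independent per-neuron deviations), or a list with `cov`
#'   (3x3 covariance of (m, log k, pi), positive semidefinite).
#' @param seed Master seed; fully determines the output.
#' @return List with `traces` (data frame `neuron_id`, `n`, `rate`),
#'   `ground_truth` (population parameters, per-neuron parameters, seed).
#' @examples
#' g <- gen_dopamine_traces(n_neurons = 10, n_index = 8, seed = 1)
#' head(g$traces)
#' @export
gen_dopamine_traces <- function(n_neurons = 58, n_index = 15,
                                model = dopamine_model(),
                                random_effects = NULL, seed = 1) {
  stopifnot(n_neurons >= 1, n_index >= 1)
  set.seed(seed)
  pars <- matrix(rep(c(model$m, model$k, model$pi), each = n_neurons),
                 ncol = 3, dimnames = list(NULL, c("m", "k", "pi")))
  if (!is.null(random_effects)) {
    re <- random_effects
    if (!is.null(re$cov)) {
      ev <- eigen(re$cov, symmetric = TRUE, only.values = TRUE)$values
      if (any(ev < -1e-8))
        stop("random-effects covariance is not positive semidefinite")
      dev <- MASS::mvrnorm(n_neurons, mu = c(0, 0, 0), Sigma = re$cov)
      pars[, "m"] <- pars[, "m"] + dev[, 1]
      pars[, "k"] <- pars[, "k"] * exp(dev[, 2])
      pars[, "pi"] <- pars[, "pi"] + dev[, 3]
    } else {
      if (!is.null(re$sd_m))
        pars[, "m"] <- pars[, "m"] + stats::rnorm(n_neurons, 0, re$sd_m)
      if (!is.null(re$sd_logk))
        pars[, "k"] <- pars[, "k"] * exp(stats::rnorm(n_neurons, 0, re$sd_logk))
      if (!is.null(re$sd_pi))
        pars[, "pi"] <- pars[, "pi"] + stats::rnorm(n_neurons, 0, re$sd_pi)
    }
  }
  n_seq <- seq_len(n_index)
  out <- vector("list", n_neurons)
  for (i in seq_len(n_neurons)) {
    mu <- pars[i, "m"] + pars[i, "k"] * n_seq ^ pars[i, "pi"]
    sd_ <- model$a + model$b * mu
    if (any(sd_ < 0)) stop("negative response s.d.; invalid parameters")
    out[[i]] <- data.frame(neuron_id = sprintf("n%03d", i), n = n_seq,
                           rate = stats::rnorm(n_index, mu, sd_))
  }
  list(traces = do.call(rbind, out),
       ground_truth = list(population = list(m = model$m, k = model$k,
                                             pi = model$pi, a = model$a,
                                             b = model$b),
                           per_neuron = as.data.frame(pars),
                           random_effects = random_effects,
                           n_neurons = n_neurons, n_index = n_index,
                           seed = seed))
}

#' Generate a synthetic two-armed choice dataset
#'
#' Simulates participants performing the two-armed mean-resampling bandit
#' task (20 blocks of 10 trials by default; block means drawn from N(0, 100),
#' reward variance 10). Choices are sampled from the strategy row's own
#' closed-form choice probabilities; learner states reset at block
#' boundaries. Per-participant true parameters may be supplied as a data
#' frame (one row per participant, columns = the row's free parameters) to
#' create population heterogeneity for recovery studies; a single named
#' vector applies to everyone.
#'
#' @param n_participants Number of participants.
#' @param row Strategy row from [table1_strategies()] used as the generator.
#' @param true_pars Named numeric vector, or data frame with
#'   `n_participants` rows.
#' @param task A [make_task()] object (default `two_arm_gaussian_D`).
#' @param n_blocks Blocks per participant (default from `task` design: 20).
#' @param seed Master seed; fully determines the output.
#' @return List with `data` (data frame `participant_id`, `block`, `trial`,
#'   `choice`, `reward`) and `ground_truth` (row label, per-participant
#'   parameters, task name, seed).
#' @examples
#' rows <- table1_strategies()
#' g <- gen_choice_dataset(2, rows$bg_value,
#'                         c(alpha_q = 0.4, e = 2), seed = 1)
#' head(g$data)
#' @export
gen_choice_dataset <- function(n_participants, row, true_pars,
                               task = make_task("two_arm_gaussian_D"),
                               n_blocks = 20, seed = 1) {
  stopifnot(inherits(task, "bb_task"))
  if (task$K != 2)
    stop("choice datasets are generated for two-armed tasks only")
  set.seed(seed)
  if (is.data.frame(true_pars)) {
    stopifnot(nrow(true_pars) == n_participants)
    par_tab <- true_pars
  } else {
    par_tab <- as.data.frame(as.list(true_pars))[rep(1, n_participants), ,
                                                 drop = FALSE]
  }
  rownames(par_tab) <- NULL

  recs <- vector("list", n_participants * n_blocks)
  ri <- 0L
  for (p in seq_len(n_participants)) {
    pars <- unlist(par_tab[p, , drop = TRUE])
    for (blk in seq_len(n_blocks)) {
      tb <- resample_block_means(task)
      sim <- .simulate_block_choices(tb, row, pars)
      ri <- ri + 1L
      recs[[ri]] <- data.frame(participant_id = sprintf("p%03d", p),
                               block = blk, trial = seq_len(tb$tau),
                               choice = sim$choice, reward = sim$reward)
    }
  }
  list(data = do.call(rbind, recs),
       ground_truth = list(model = row$label, parameters = par_tab,
                           task = task$name, n_blocks = n_blocks,
                           seed = seed))
}

# simulate one block of the two-arm task from the row's choice probabilities
.simulate_block_choices <- function(task, row, pars) {
  pars <- .merge_row_pars(row, pars[row$free])
  tau <- task$tau
  choice <- integer(tau)
  reward <- numeric(tau)
  if (row$learning_rule == "kalman") {
    kal <- row$fixed$kalman
    Q <- rep(kal$prior_mean, 2)
    v <- rep(kal$prior_var, 2)
    for (t in seq_len(tau)) {
      st <- structure(list(Q = Q, var = v, K = 2L,
                           prior_mean = kal$prior_mean,
                           prior_var = kal$prior_var,
                           reward_var = kal$reward_var),
                      class = "bb_kalman")
      p1 <- choice_prob_two_arm(st, .row_strategy(row, pars),
                                tie_break = TRUE)
      c_t <- if (stats::runif(1) < p1) 1L else 2L
      r_t <- sample_reward(task, c_t)
      g <- v[c_t] / (v[c_t] + kal$reward_var)
      Q[c_t] <- Q[c_t] + g * (r_t - Q[c_t])
      v[c_t] <- (1 - g) * v[c_t]
      choice[t] <- c_t
      reward[t] <- r_t
    }
  } else {
    st <- learner_state(2, q0 = 0, s0 = 0, n0 = 1)
    lp <- learning_params(alpha_q = max(pars[["alpha_q"]], 1e-12),
                          alpha_s = 0, beta = 0)
    # alpha_s handled through explicit rates to avoid the constraint warning
    for (t in seq_len(tau)) {
      p1 <- choice_prob_two_arm(st, .row_strategy(row, pars),
                                tie_break = TRUE)
      c_t <- if (stats::runif(1) < p1) 1L else 2L
      r_t <- sample_reward(task, c_t)
      st <- update_qs_idealised(st, c_t, r_t, lp,
                                rates = c(pars[["alpha_q"]],
                                          pars[["alpha_s"]]))
      choice[t] <- c_t
      reward[t] <- r_t
    }
  }
  list(choice = choice, reward = reward)
}

# build a bb_strategy for choice_prob_two_arm from a row + merged parameters
.row_strategy <- function(row, pars) {
  if (row$learning_rule == "kalman") {
    structure(list(learning_rule = "kalman", exploration = row$exploration,
                   theta = if (is.na(pars[["theta"]])) 0 else pars[["theta"]],
                   gamma = if (is.na(pars[["gamma"]])) 1 else pars[["gamma"]],
                   e = if (is.na(pars[["e"]])) 0 else pars[["e"]],
                   lambda = 0, dopamine = NULL, learning = NULL),
              class = "bb_strategy")
  } else {
    dop <- row$fixed$dop
    dm <- dopamine_model("refined", m = dop[["m"]], k = dop[["k"]],
                         pi = dop[["pi"]], a = dop[["a"]], b = dop[["b"]])
    structure(list(learning_rule = "basal_ganglia",
                   exploration = row$exploration,
                   theta = 0, gamma = 1,
                   e = if (is.na(pars[["e"]])) 0 else pars[["e"]],
                   lambda = pars[["lambda"]],
                   dopamine = dm, learning = NULL),
              class = "bb_strategy")
  }
}

#' Write / read neural traces CSV
#'
#' CSV schema `neuron_id,n,rate` with a two-line provenance header
#' (`# banditbg v<version> <kind>` and `# seed=<seed> spec_hash=<hash>`)
#' that the reader skips. Identical generator seeds yield byte-identical
#' files.
#'
#' @param traces Data frame from [gen_dopamine_traces()].
#' @param path Output path.
#' @param seed Seed recorded in the header.
#' @param spec Object hashed into the header (e.g. the ground-truth list).
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path, seed = NA, spec = list()) {
  df <- data.frame(neuron_id = traces$neuron_id, n = traces$n,
                   rate = sprintf("%.17g", traces$rate))
  .write_csv_with_header(df, path,
                         .provenance_header("dopamine_traces", seed, spec))
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  stopifnot(all(c("neuron_id", "n", "rate") %in% names(df)))
  df$n <- as.integer(df$n)
  df$rate <- as.numeric(df$rate)
  df
}

#' Write / read behavioural choice CSV
#'
#' CSV schema `participant_id,block,trial,choice,reward` with the same
#' provenance header convention as [write_traces_csv()].
#'
#' @param data Data frame from [gen_choice_dataset()].
#' @param path Output path.
#' @param seed Seed recorded in the header.
#' @param spec Object hashed into the header.
#' @return `path`, invisibly.
#' @export
write_choice_csv <- function(data, path, seed = NA, spec = list()) {
  df <- data.frame(participant_id = data$participant_id, block = data$block,
                   trial = data$trial, choice = data$choice,
                   reward = sprintf("%.17g", data$reward))
  .write_csv_with_header(df, path,
                         .provenance_header("choice_dataset", seed, spec))
}

#' @rdname write_choice_csv
#' @export
read_choice_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  stopifnot(all(c("participant_id", "block", "trial", "choice", "reward")
                %in% names(df)))
  df$block <- as.integer(df$block)
  df$trial <- as.integer(df$trial)
  df$choice <- as.integer(df$choice)
  df$reward <- as.numeric(df$reward)
  df
}
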