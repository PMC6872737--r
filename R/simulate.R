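#' Co-player agent parameters
#'
#' The decisions of the `N - 1` other group members are produced by a
#' logistic policy on the previous round's state. The defaults are chosen
#' so that agents (i) tend to stay with their previous decision, (ii)
#' contribute more in a cooperative group, and (iii) free-ride more after
#' a failure to produce the goods specifically in a less cooperative
#' group (the failure weight is scaled by the group's previous
#' free-riding proportion), with the failure effect further scaled by the
#' remaining horizon.
#'
#' @param intercept Baseline log-odds of contributing.
#' @param beta_stay Weight on the agent's own previous decision (0/1).
#' @param beta_coop Weight on the previous contribution proportion of the
#'   agent's `N - 1` co-members.
#' @param beta_fail Weight on a previous failure to produce the goods
#'   (negative: failure discourages contribution); applied in proportion
#'   to how uncooperative the group was.
#' @param beta_horizon Scaling of the failure effect by the remaining
#'   fraction of the block, `(T - t + 1) / T`.
#' @return A named numeric vector of class `coplayer_params`.
#' @export
coplayer_params <- function(intercept = -2.8, beta_stay = 4.5,
                            beta_coop = 2.2, beta_fail = -2,
                            beta_horizon = 1) {
  structure(c(intercept = intercept, beta_stay = beta_stay,
              beta_coop = beta_coop, beta_fail = beta_fail,
              beta_horizon = beta_horizon),
            class = "coplayer_params")
}

#' Co-player contribution probability
#'
#' On round 1 the agent contributes with the focal subject's control-block
#' contribution rate (agents start out deciding as the participant
#' would). From round 2 on, the probability is the logistic of
#' `intercept + beta_stay * prev_own + beta_coop * prev_others_prop +
#' beta_fail * prev_failure * (1 - prev_others_prop) * beta_horizon *
#' (T - t + 1) / T`: a failure discourages contribution in proportion to
#' how uncooperative the group already was.
#'
#' @param prev_own Agent's own decision in the previous round (0/1).
#' @param prev_others_prop Contribution proportion among the agent's
#'   `N - 1` co-members in the previous round.
#' @param prev_failure 1 if the previous round failed to produce the
#'   goods.
#' @param t Current round (>= 2; use `control_rate` directly for t = 1).
#' @param cfg A [pgg_config()].
#' @param params A [coplayer_params()].
#' @return Probability of contributing.
#' @export
coplayer_prob <- function(prev_own, prev_others_prop, prev_failure, t, cfg,
                          params = coplayer_params()) {
  if (t < 2) stop("coplayer_prob applies from round 2 on")
  x <- params[["intercept"]] +
    params[["beta_stay"]] * prev_own +
    params[["beta_coop"]] * prev_others_prop +
    params[["beta_fail"]] * prev_failure * (1 - prev_others_prop) *
      params[["beta_horizon"]] * (cfg$T - t + 1) / cfg$T
  plogis(x)
}

# incremental focal-player policy: returns p(contribute) for round t given
# the belief / accumulator state, and updates that state from outcomes
focal_step <- function(model, pars, state, t, cfg, control_rate, order) {
  if (model == "ia") {
    p <- if (t == 1) control_rate else control_rate * plogis(pars[["kappa"]] * state$acc)
    return(list(p = p, state = state))
  }
  belief <- higher_order_belief(state$gamma, order, cfg)
  Q <- switch(model,
              sl = decision_value(
                individual_utility(belief, pars[["lambda"]], pars[["pi"]], cfg),
                group_utility(belief, t, cfg), pars[["omega"]]),
              myopic = pars[["omega"]] *
                individual_utility(belief, pars[["lambda"]], pars[["pi"]], cfg),
              gu = pars[["zeta"]] + pars[["chi"]] * group_utility(belief, t, cfg))
  list(p = choice_prob(Q), state = state)
}

focal_learn <- function(model, pars, state, outcome, cfg) {
  if (model == "ia") {
    cbar <- (cfg$N - 1 - outcome$n_free_others) / (cfg$N - 1)
    state$acc <- state$acc + pars[["epsilon"]] * outcome$group_reward -
      pars[["delta"]] * (outcome$decision - cbar)
  } else {
    up <- update_belief(state$gamma, outcome$n_free_others,
                        outcome$group_reward, pars[["alpha"]],
                        pars[["theta"]], cfg)
    state$gamma <- up$gamma
  }
  state
}

#' Simulate one block of PGG play
#'
#' Plays `T` rounds: the focal player samples from the chosen model's
#' contribution probability, the `N - 1` co-players follow
#' [coplayer_prob()], and outcomes, payoffs and the focal player's
#' beliefs evolve consistently. Uses R's global RNG stream, so results
#' are reproducible under [set.seed()].
#'
#' @param model Focal-player model (`"sl"`, `"myopic"`, `"gu"`, `"ia"`).
#' @param params Named parameter vector for the focal model.
#' @param control_rate Focal subject's control-block contribution rate.
#' @param cfg A [pgg_config()] whose `k` is this block's threshold.
#' @param coplayers A [coplayer_params()].
#' @param block_id Identifier stored in the `block` column.
#' @param order Belief order of the focal model.
#' @return A trial data frame (one row per round) in the [pgg_session()]
#'   column layout.
#' @export
simulate_block <- function(model, params, control_rate, cfg,
                           coplayers = coplayer_params(), block_id = 1L,
                           order = 1) {
  model <- match.arg(model, PGG_MODELS)
  pars <- params_vector(params, model)
  n_others <- cfg$N - 1
  state <- list(gamma = 1 - control_rate, acc = 0)
  co_prev <- integer(n_others)
  own_prev <- 0L
  prev_fail <- 0L
  rows <- vector("list", cfg$T)
  for (t in seq_len(cfg$T)) {
    st <- focal_step(model, pars, state, t, cfg, control_rate, order)
    own <- rbinom(1, 1, st$p)
    co <- if (t == 1) {
      rbinom(n_others, 1, control_rate)
    } else {
      total_prev <- sum(co_prev) + own_prev
      probs <- vapply(seq_len(n_others), function(j) {
        others_prop <- (total_prev - co_prev[j]) / n_others
        coplayer_prob(co_prev[j], others_prop, prev_fail, t, cfg, coplayers)
      }, numeric(1))
      rbinom(n_others, 1, probs)
    }
    n_contrib <- own + sum(co)
    succ <- group_success(n_contrib, cfg)
    reward <- cfg$R * succ
    outcome <- list(decision = own, n_free_others = n_others - sum(co),
                    success = succ, group_reward = reward)
    rows[[t]] <- data.frame(block = block_id, k = cfg$k, round = t,
                            decision = own,
                            n_free_others = outcome$n_free_others,
                            success = succ, group_reward = reward)
    state <- focal_learn(model, pars, state, outcome, cfg)
    co_prev <- co
    own_prev <- own
    prev_fail <- 1L - succ
  }
  do.call(rbind, rows)
}

#' Cohort specification for synthetic data generation
#'
#' Describes a synthetic cohort emulating the study layout: 25 subjects,
#' 12 blocks of 15 rounds each, a balanced schedule of thresholds
#' `k = 2` and `k = 4`, focal players driven by one of the four choice
#' models with per-subject parameters drawn from truncated normal
#' distributions, and control rates drawn from a Beta distribution.
#'
#' By default the per-subject generating parameters are centered on the
#' cohort means reported for the fitted models (e.g. social learning
#' `omega = 0.65`, `pi = 0.16`, `lambda = -2.10`, `alpha = 0.51`,
#' `theta = 0.13`) with spreads equal to the reported SEMs scaled by
#' `sqrt(25)`, truncated to the fitting bounds.
#'
#' @param n_subjects Number of subjects.
#' @param n_blocks Blocks per subject (split evenly across `k_levels`).
#' @param model Generating model name.
#' @param cfg A [pgg_config()] (its `k` is overridden by the schedule).
#' @param k_levels Thresholds to balance across blocks.
#' @param param_means,param_sds Optional named vectors overriding the
#'   generating parameter distribution.
#' @param control_shape Two Beta shape parameters for the control-rate
#'   distribution.
#' @param coplayers A [coplayer_params()].
#' @param order Belief order of the generating model.
#' @param seed Master seed; each subject receives a derived sub-seed so
#'   cohorts are reproducible and subject-level draws are stable under
#'   cohort resizing.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 25, n_blocks = 12, model = "sl",
                        cfg = pgg_config(), k_levels = c(2L, 4L),
                        param_means = NULL, param_sds = NULL,
                        control_shape = c(3, 2),
                        coplayers = coplayer_params(), order = 1,
                        seed = 1) {
  model <- match.arg(model, PGG_MODELS)
  if (n_subjects < 0) stop("n_subjects must be >= 0")
  if (n_blocks %% length(k_levels) != 0) {
    stop("n_blocks must be a multiple of length(k_levels) for a balanced schedule")
  }
  defaults <- generator_defaults(model)
  if (is.null(param_means)) param_means <- defaults$means
  if (is.null(param_sds)) param_sds <- defaults$sds
  structure(list(n_subjects = n_subjects, n_blocks = n_blocks,
                 model = model, cfg = cfg, k_levels = as.integer(k_levels),
                 param_means = param_means, param_sds = param_sds,
                 control_shape = control_shape, coplayers = coplayers,
                 order = order, seed = seed),
            class = "cohort_spec")
}

# cohort means and SEM * sqrt(25) spreads of the reported group estimates
generator_defaults <- function(model) {
  switch(model,
         sl = list(means = c(omega = 0.65, pi = 0.16, lambda = -2.10,
                             alpha = 0.51, theta = 0.13),
                   sds = sqrt(25) * c(omega = 0.07, pi = 0.16, lambda = 0.45,
                                      alpha = 0.06, theta = 0.02)),
         myopic = list(means = c(omega = 11.04, pi = 0.34, lambda = -2.98,
                                 alpha = 0.59, theta = 0.14),
                       sds = sqrt(25) * c(omega = 2.76, pi = 0.19,
                                          lambda = 1.09, alpha = 0.06,
                                          theta = 0.04)),
         gu = list(means = c(chi = 9.30, zeta = -30.91, alpha = 0.56,
                             theta = 0.12),
                   sds = sqrt(25) * c(chi = 4.55, zeta = 4.92, alpha = 0.06,
                                      theta = 0.02)),
         ia = list(means = c(delta = 16.39, epsilon = 0.61, kappa = 1.37),
                   sds = sqrt(25) * c(delta = 7.11, epsilon = 0.42,
                                      kappa = 1.00)),
         stop("unknown model: ", model))
}

rtruncnorm1 <- function(mean, sd, lower, upper) {
  for (i in 1:10000) {
    x <- rnorm(1, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
  min(max(mean, lower), upper)
}

#' Simulate a synthetic cohort
#'
#' Draws per-subject generating parameters and control rates, plays every
#' block with [simulate_block()], and records the ground truth alongside
#' the data.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `pgg_cohort` with `sessions` (list of
#'   [pgg_session()]), `ground_truth` (data frame: subject, control rate
#'   and generating parameters) and `spec`.
#' @export
simulate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec")
  n <- spec$n_subjects
  if (n == 0) {
    return(structure(list(sessions = list(),
                          ground_truth = data.frame(), spec = spec),
                     class = "pgg_cohort"))
  }
  subject_seeds <- withr_seed(spec$seed, function() {
    sample.int(.Machine$integer.max - 1L, n)
  })
  bounds <- model_bounds(spec$model)
  nm <- model_par_names(spec$model)
  sessions <- vector("list", n)
  truth <- vector("list", n)
  for (j in seq_len(n)) {
    res <- withr_seed(subject_seeds[j], function() {
      pars <- vapply(nm, function(p) {
        rtruncnorm1(spec$param_means[[p]], spec$param_sds[[p]],
                    bounds$lower[[p]], bounds$upper[[p]])
      }, numeric(1))
      control_rate <- rbeta(1, spec$control_shape[1], spec$control_shape[2])
      ks <- sample(rep(spec$k_levels, spec$n_blocks / length(spec$k_levels)))
      trials <- do.call(rbind, lapply(seq_len(spec$n_blocks), function(b) {
        simulate_block(spec$model, pars, control_rate,
                       with_k(spec$cfg, ks[b]), spec$coplayers,
                       block_id = b, order = spec$order)
      }))
      list(pars = pars, control_rate = control_rate, trials = trials)
    })
    id <- sprintf("S%02d", j)
    sessions[[j]] <- pgg_session(id, res$trials, res$control_rate, spec$cfg)
    truth[[j]] <- data.frame(subject = id, model = spec$model,
                             control_rate = res$control_rate,
                             t(res$pars))
  }
  structure(list(sessions = sessions,
                 ground_truth = do.call(rbind, truth), spec = spec),
            class = "pgg_cohort")
}

#' @export
print.pgg_cohort <- function(x, ...) {
  cat(sprintf("Synthetic PGG cohort: %d subjects x %d blocks (%s model, seed %s)\n",
              length(x$sessions), x$spec$n_blocks, x$spec$model,
              format(x$spec$seed)))
  invisible(x)
}

#' Write a cohort and its ground-truth sidecar to disk
#'
#' @param cohort A `pgg_cohort` from [simulate_cohort()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  paths <- write_sessions(cohort$sessions, dir)
  gt <- file.path(dir, "ground_truth.tsv")
  write.table(cohort$ground_truth, gt, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(paths, ground_truth = gt))
}

#' Simulate a null session with history-independent decisions
#'
#' All five group members decide by independent fair coin flips, so the
#' focal decisions carry no dependence on trial history. Used to check
#' the calibration (type-I error) of the model-free group analysis.
#'
#' @param subject_id Subject identifier.
#' @param cfg A [pgg_config()].
#' @param n_blocks Number of blocks.
#' @param k_levels Thresholds, balanced across blocks.
#' @return A [pgg_session()].
#' @export
simulate_null_session <- function(subject_id, cfg = pgg_config(),
                                  n_blocks = 12, k_levels = c(2L, 4L)) {
  ks <- rep(k_levels, length.out = n_blocks)
  trials <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    dec <- rbinom(cfg$T, 1, 0.5)
    co <- rbinom(cfg$T, cfg$N - 1, 0.5)   # contributors among others
    succ <- as.integer(dec + co >= ks[b])
    data.frame(block = b, k = ks[b], round = seq_len(cfg$T), decision = dec,
               n_free_others = cfg$N - 1 - co, success = succ,
               group_reward = cfg$R * succ)
  }))
  pgg_session(subject_id, trials, control_rate = 0.5, cfg)
}
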