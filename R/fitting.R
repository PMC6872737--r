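# flatten a session into the arrays consumed by the compiled likelihood
session_arrays <- function(session) {
  tr <- session$trials
  list(decision = as.integer(tr$decision),
       n_free = as.integer(tr$n_free_others),
       reward = as.numeric(tr$group_reward),
       round = as.integer(tr$round),
       k = as.integer(tr$k))
}

model_code <- function(model) match(model, PGG_MODELS)

# fast per-trial probabilities (compiled path used by the fitter)
model_probs_fast <- function(model, par, session, order = 1,
                             rate_fn = "logistic") {
  a <- session_arrays(session)
  cfg <- session$cfg
  .model_probs_cpp(model_code(model), as.numeric(par), a$decision, a$n_free,
                   a$reward, a$round, a$k, cfg$N, cfg$T, cfg$R,
                   1 - session$control_rate, session$control_rate,
                   as.integer(order), as.integer(rate_fn == "linear"))
}

#' Bayesian information criterion
#'
#' `BIC = -2 lnL + mu * log(n)`; lower values indicate a better penalized
#' fit.
#'
#' @param lnL Maximized log-likelihood.
#' @param mu Number of free parameters.
#' @param n Number of observations entering the likelihood.
#' @export
bic <- function(lnL, mu, n) -2 * lnL + mu * log(n)

#' Maximum-likelihood fit of one choice model to one session
#'
#' Minimizes the negative Bernoulli log-likelihood over bounded parameter
#' space with multi-start `L-BFGS-B` (one deterministic start at typical
#' values plus `n_restarts - 1` uniform draws within the bounds). The fit
#' is deterministic given `seed`.
#'
#' @param model One of `"sl"`, `"myopic"`, `"gu"`, `"ia"`.
#' @param session A [pgg_session()].
#' @param n_restarts Number of optimization starts.
#' @param seed Integer seed for the random starts (optional).
#' @param order Belief order for the belief-based models.
#' @param fixed Named list of parameters to hold fixed (used by
#'   [ablate_sl()]); fixed parameters do not count toward `mu`.
#' @param maxit Iteration cap passed to [stats::optim()].
#' @return An object of class `pgg_fit`: a list with `model`, `estimate`
#'   (full named parameter vector, fixed values merged back in), `lnL`,
#'   `n` (trial count), `mu` (free-parameter count), `bic`, `order`,
#'   `converged`, `n_restarts` and `fixed`.
#' @export
fit_mle <- function(model, session, n_restarts = 20, seed = NULL, order = 1,
                    fixed = list(), maxit = 500) {
  model <- match.arg(model, PGG_MODELS)
  if (nrow(session$trials) == 0L) stop("session has no trials")
  bounds <- model_bounds(model)
  par_names <- model_par_names(model)
  if (length(fixed) && !all(names(fixed) %in% par_names)) {
    stop("fixed contains unknown parameter names")
  }
  free <- setdiff(par_names, names(fixed))
  if (!length(free)) stop("no free parameters left to fit")
  lower <- bounds$lower[free]
  upper <- bounds$upper[free]
  decisions <- session$trials$decision
  n <- length(decisions)

  full_par <- function(theta) {
    p <- setNames(numeric(length(par_names)), par_names)
    p[free] <- theta
    for (nm in names(fixed)) p[nm] <- fixed[[nm]]
    p
  }
  a <- session_arrays(session)
  scfg <- session$cfg
  mcode <- model_code(model)
  nll <- function(theta) {
    .model_nll_cpp(mcode, as.numeric(full_par(theta)), a$decision, a$n_free,
                   a$reward, a$round, a$k, scfg$N, scfg$T, scfg$R,
                   1 - session$control_rate, session$control_rate,
                   as.integer(order), 0L, 1e-9)
  }

  canonical <- model_start_set(model)[, free, drop = FALSE]
  starts <- canonical[seq_len(min(nrow(canonical), n_restarts)), ,
                      drop = FALSE]
  n_rand <- n_restarts - nrow(starts)
  if (n_rand > 0) {
    rng <- model_start_range(model)
    rlo <- pmax(rng$lower[free], lower)
    rhi <- pmin(rng$upper[free], upper)
    draw_starts <- function() {
      matrix(runif(n_rand * length(free), rep(rlo, each = n_rand),
                   rep(rhi, each = n_rand)),
             ncol = length(free), dimnames = list(NULL, free))
    }
    runs <- if (!is.null(seed)) withr_seed(seed, draw_starts) else draw_starts()
    starts <- rbind(starts, runs)
  }

  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[s, ], nll, method = "L-BFGS-B", lower = lower,
            upper = upper, control = list(maxit = maxit, factr = 1e9)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimization restarts failed for model ", model)

  # polish the incumbent at the optimizer's default (tighter) tolerance
  polish <- tryCatch(
    optim(best$par, nll, method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(maxit = maxit)),
    error = function(e) NULL)
  if (!is.null(polish) && is.finite(polish$value) &&
      polish$value < best$value) {
    best <- polish
  }

  est <- full_par(best$par)
  mu <- length(free)
  lnL <- -best$value
  structure(list(model = model, estimate = est, lnL = lnL, n = n, mu = mu,
                 bic = bic(lnL, mu, n), order = order,
                 converged = best$convergence == 0,
                 n_restarts = n_restarts, fixed = fixed),
            class = "pgg_fit")
}

# run fn with a temporary RNG state seeded by `seed`, restoring afterwards
withr_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' @export
print.pgg_fit <- function(x, ...) {
  cat(sprintf("%s model fit: lnL = %.2f, BIC = %.2f (mu = %d, n = %d)\n",
              x$model, x$lnL, x$bic, x$mu, x$n))
  print(round(x$estimate, 4))
  invisible(x)
}

#' Fit several models to every session of a cohort
#'
#' @param sessions List of [pgg_session()] objects.
#' @param models Character vector of model names to fit.
#' @param n_restarts,seed,order Passed to [fit_mle()]; each subject-model
#'   fit gets its own seed derived from `seed`.
#' @return A list with `fits` (nested list, subject then model) and
#'   `table` (data frame with one row per subject-model: `subject`,
#'   `model`, `lnL`, `mu`, `n`, `bic`, `converged`).
#' @export
fit_cohort <- function(sessions, models = PGG_MODELS, n_restarts = 10,
                       seed = 1, order = 1) {
  fits <- lapply(seq_along(sessions), function(j) {
    per <- lapply(seq_along(models), function(m) {
      fit_mle(models[m], sessions[[j]], n_restarts = n_restarts,
              seed = seed + 1000L * j + m, order = order)
    })
    names(per) <- models
    per
  })
  names(fits) <- vapply(sessions, function(s) s$subject_id, character(1))
  rows <- do.call(rbind, lapply(names(fits), function(id) {
    do.call(rbind, lapply(models, function(m) {
      f <- fits[[id]][[m]]
      data.frame(subject = id, model = m, lnL = f$lnL, mu = f$mu,
                 n = f$n, bic = f$bic, converged = f$converged)
    }))
  }))
  list(fits = fits, table = rows)
}

#' Group-level model comparison
#'
#' Sums per-subject BICs per model (lower is better), counts per-subject
#' winners, and runs random-effects Bayesian model selection on the
#' subject-wise model evidences approximated as `-BIC/2`: a variational
#' Dirichlet posterior over model frequencies is estimated by fixed-point
#' iteration, and exceedance probabilities (the probability that a model
#' is the most frequent in the population) are computed by Monte-Carlo
#' draws from that posterior.
#'
#' @param fit_table The `table` component of [fit_cohort()], or any data
#'   frame with columns `subject`, `model`, `bic`.
#' @param n_draws Number of Dirichlet posterior draws for the exceedance
#'   probabilities.
#' @param seed Optional seed for the draws.
#' @return A list with `summed_bic` (named, ascending is better),
#'   `best_model` (overall summed-BIC winner), `best_counts` (per-subject
#'   winner counts), `model_freq` (posterior expected frequencies, sums to
#'   1), `exceedance` (sums to 1) and `alpha` (Dirichlet posterior
#'   parameters).
#' @export
compare_models <- function(fit_table, n_draws = 1e6, seed = NULL) {
  models <- sort(unique(fit_table$model))
  subjects <- unique(fit_table$subject)
  bicm <- matrix(NA_real_, length(subjects), length(models),
                 dimnames = list(subjects, models))
  for (r in seq_len(nrow(fit_table))) {
    bicm[as.character(fit_table$subject[r]), fit_table$model[r]] <-
      fit_table$bic[r]
  }
  if (anyNA(bicm)) stop("every subject must have a fit for every model")

  summed <- colSums(bicm)
  winners <- models[apply(bicm, 1, which.min)]
  best_counts <- table(factor(winners, levels = models))

  lme <- -bicm / 2
  alpha <- bms_dirichlet(lme)
  freq <- alpha / sum(alpha)

  draw <- function() {
    g <- matrix(rgamma(n_draws * length(models), shape = rep(alpha, each = n_draws)),
                nrow = n_draws)
    tab <- tabulate(max.col(g), nbins = length(models))
    tab / n_draws
  }
  xp <- if (!is.null(seed)) withr_seed(seed, draw) else draw()
  names(xp) <- models

  list(summed_bic = summed, best_model = names(which.min(summed)),
       best_counts = best_counts, model_freq = freq, exceedance = xp,
       alpha = alpha)
}

# variational fixed-point update for the Dirichlet posterior over model
# frequencies given subject-wise log model evidences (rows = subjects)
bms_dirichlet <- function(lme, alpha0 = NULL, tol = 1e-8, maxit = 1000) {
  K <- ncol(lme)
  if (is.null(alpha0)) alpha0 <- rep(1, K)
  lme <- lme - apply(lme, 1, max)
  alpha <- alpha0
  for (it in seq_len(maxit)) {
    w <- exp(sweep(lme, 2, digamma(alpha) - digamma(sum(alpha)), "+"))
    w <- w / rowSums(w)
    alpha_new <- alpha0 + colSums(w)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  setNames(alpha, colnames(lme))
}

#' Leave-one-block-out cross-validation
#'
#' For each block of the session, fits the model on the remaining blocks
#' and scores the held-out block's predictive log-likelihood. Blocks are
#' independent given the block-boundary resets, so the held-out
#' prediction needs no information from the training blocks beyond the
#' fitted parameters.
#'
#' @inheritParams fit_mle
#' @return A data frame with one row per block: `block`, `n` (held-out
#'   trials) and `lnL_holdout`.
#' @export
loo_block_cv <- function(model, session, n_restarts = 5, seed = NULL,
                         order = 1) {
  blocks <- unique(session$trials$block)
  if (length(blocks) < 2) stop("need at least two blocks for cross-validation")
  out <- lapply(seq_along(blocks), function(j) {
    b <- blocks[j]
    train <- pgg_session(session$subject_id,
                         session$trials[session$trials$block != b, ],
                         session$control_rate, session$cfg)
    test <- pgg_session(session$subject_id,
                        session$trials[session$trials$block == b, ],
                        session$control_rate, session$cfg)
    fit <- fit_mle(model, train, n_restarts = n_restarts,
                   seed = if (is.null(seed)) NULL else seed + j,
                   order = order)
    pr <- model_probs_fast(model, fit$estimate, test, order)
    data.frame(block = b, n = nrow(test$trials),
               lnL_holdout = log_likelihood(pr, test$trials$decision))
  })
  do.call(rbind, out)
}

#' Parameter ablation of the social learning model
#'
#' Refits the social learning model with one parameter removed and
#' reports the change in fit quality. `theta`, `lambda` and `pi` are
#' ablated by fixing them at zero; `alpha` is ablated by fixing it at
#' zero so the learning rate reduces to the logistic of `theta * PE_R`
#' alone.
#'
#' @param session A [pgg_session()].
#' @param which One of `"alpha"`, `"theta"`, `"lambda"`, `"pi"`.
#' @inheritParams fit_mle
#' @return A list with `full` and `ablated` fits, `delta_bic`
#'   (`ablated$bic - full$bic`; positive means the ablation hurt) and
#'   `delta_lnL` (`ablated$lnL - full$lnL`, non-positive up to optimizer
#'   tolerance by nesting).
#' @export
ablate_sl <- function(session, which = c("alpha", "theta", "lambda", "pi"),
                      n_restarts = 10, seed = NULL, order = 1) {
  which <- match.arg(which)
  full <- fit_mle("sl", session, n_restarts = n_restarts, seed = seed,
                  order = order)
  fixed <- setNames(list(0), which)
  abl <- fit_mle("sl", session, n_restarts = n_restarts,
                 seed = if (is.null(seed)) NULL else seed + 1,
                 order = order, fixed = fixed)
  list(full = full, ablated = abl,
       delta_bic = abl$bic - full$bic,
       delta_lnL = abl$lnL - full$lnL)
}
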