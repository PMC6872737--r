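#' Trial-wise predictions of the four choice models
#'
#' Each `predict_*` function walks a subject's session block by block and
#' returns the per-trial contribution probability together with the full
#' computational trace. The belief about others' free-riding is
#' re-initialized to `1 - control_rate` at every block start (new
#' partners) and updated after each observed outcome with the social and
#' reward prediction errors; the inequity-aversion history likewise resets
#' at block boundaries.
#'
#' @param session A [pgg_session()].
#' @param params A parameter object from [sl_params()], [myopic_params()],
#'   [gu_params()] or [ia_params()] (a plain named numeric vector with the
#'   right names also works).
#' @param order Belief order (1, 2 or 3); orders above 1 replace the
#'   belief entering the utilities by its higher-order transform
#'   ([higher_order_belief()]); the learning update itself always operates
#'   on the first-order belief.
#' @param rate_fn Learning-rate link, see [update_belief()].
#' @return A data frame with one row per trial: `block`, `k`, `round`,
#'   `decision`, the belief columns `gamma` (first-order) and `belief`
#'   (order-adjusted, used in the utilities), prediction-error columns
#'   `pe_social`, `pe_reward`, `rate`, `wpe` (NA on round 1 of each
#'   block), the utilities `I` and `G`, the decision value `Q` and
#'   `p_contribute`. Models that do not use a component carry `NA` there
#'   (e.g. `G` for the myopic model).
#' @name predict_models
NULL

# shared walker over blocks: computes belief trajectory and hands each
# trial to `value_fn(trace_row, cfg_k)` which must fill I, G, Q
predict_belief_model <- function(session, pars, order, rate_fn, value_fn) {
  cfg <- session$cfg
  gamma1 <- 1 - session$control_rate
  out <- lapply(unique(session$trials$block), function(b) {
    tr <- session$trials[session$trials$block == b, ]
    cfg_k <- with_k(cfg, tr$k[1])
    n <- nrow(tr)
    res <- data.frame(block = tr$block, k = tr$k, round = tr$round,
                      decision = tr$decision, gamma = NA_real_,
                      belief = NA_real_, pe_social = NA_real_,
                      pe_reward = NA_real_, rate = NA_real_,
                      wpe = NA_real_, I = NA_real_, G = NA_real_,
                      Q = NA_real_, p_contribute = NA_real_)
    gamma <- gamma1
    for (t in seq_len(n)) {
      if (t > 1) {
        up <- update_belief(gamma, tr$n_free_others[t - 1],
                            tr$group_reward[t - 1],
                            pars[["alpha"]], pars[["theta"]],
                            cfg_k, rate_fn)
        gamma <- up$gamma
        res$pe_social[t] <- up$pe_social
        res$pe_reward[t] <- up$pe_reward
        res$rate[t] <- up$rate
        res$wpe[t] <- up$wpe
      }
      res$gamma[t] <- gamma
      res$belief[t] <- higher_order_belief(gamma, order, cfg_k)
      vals <- value_fn(res$belief[t], tr$round[t], cfg_k)
      res$I[t] <- vals$I
      res$G[t] <- vals$G
      res$Q[t] <- vals$Q
      res$p_contribute[t] <- choice_prob(vals$Q)
    }
    res
  })
  do.call(rbind, out)
}

#' @rdname predict_models
#' @export
predict_sl <- function(session, params, order = 1,
                       rate_fn = c("logistic", "linear")) {
  rate_fn <- match.arg(rate_fn)
  p <- params_vector(params, "sl")
  if (nrow(session$trials) == 0L) stop("session has no trials")
  predict_belief_model(session, p, order, rate_fn, function(belief, t, cfg_k) {
    I <- individual_utility(belief, p[["lambda"]], p[["pi"]], cfg_k)
    G <- group_utility(belief, t, cfg_k)
    list(I = I, G = G, Q = decision_value(I, G, p[["omega"]]))
  })
}

#' @rdname predict_models
#' @export
predict_myopic <- function(session, params, order = 1,
                           rate_fn = c("logistic", "linear")) {
  rate_fn <- match.arg(rate_fn)
  p <- params_vector(params, "myopic")
  predict_belief_model(session, p, order, rate_fn, function(belief, t, cfg_k) {
    I <- individual_utility(belief, p[["lambda"]], p[["pi"]], cfg_k)
    list(I = I, G = NA_real_, Q = p[["omega"]] * I)
  })
}

#' @rdname predict_models
#' @export
predict_gu <- function(session, params, order = 1,
                       rate_fn = c("logistic", "linear")) {
  rate_fn <- match.arg(rate_fn)
  p <- params_vector(params, "gu")
  predict_belief_model(session, p, order, rate_fn, function(belief, t, cfg_k) {
    G <- group_utility(belief, t, cfg_k)
    list(I = NA_real_, G = G, Q = p[["zeta"]] + p[["chi"]] * G)
  })
}

#' @rdname predict_models
#' @export
predict_ia <- function(session, params) {
  p <- params_vector(params, "ia")
  cfg <- session$cfg
  p_c1 <- session$control_rate
  out <- lapply(unique(session$trials$block), function(b) {
    tr <- session$trials[session$trials$block == b, ]
    n <- nrow(tr)
    res <- data.frame(block = tr$block, k = tr$k, round = tr$round,
                      decision = tr$decision, accumulator = NA_real_,
                      p_contribute = NA_real_)
    acc <- 0
    for (t in seq_len(n)) {
      if (t > 1) {
        cbar <- (cfg$N - 1 - tr$n_free_others[t - 1]) / (cfg$N - 1)
        acc <- acc + p[["epsilon"]] * tr$group_reward[t - 1] -
          p[["delta"]] * (tr$decision[t - 1] - cbar)
        res$accumulator[t] <- acc
        res$p_contribute[t] <- p_c1 * plogis(p[["kappa"]] * acc)
      } else {
        res$p_contribute[t] <- p_c1
      }
    }
    res
  })
  do.call(rbind, out)
}

#' Generic dispatcher over the four model predictors
#'
#' @param model One of `"sl"`, `"myopic"`, `"gu"`, `"ia"`.
#' @param session A [pgg_session()].
#' @param params Named parameter vector for the model.
#' @param order Belief order (ignored by the inequity-aversion model).
#' @return The model's prediction data frame, see [predict_models].
#' @export
predict_model <- function(model, session, params, order = 1) {
  switch(model,
         sl = predict_sl(session, params, order),
         myopic = predict_myopic(session, params, order),
         gu = predict_gu(session, params, order),
         ia = predict_ia(session, params),
         stop("unknown model: ", model))
}

#' Bernoulli log-likelihood of observed decisions
#'
#' `sum(C_t * log(p_t) + (1 - C_t) * log(1 - p_t))`, with probabilities
#' clamped to `[clamp, 1 - clamp]` for numerical safety.
#'
#' @param p Per-trial contribution probabilities, or a prediction data
#'   frame from [predict_model()] (its `p_contribute` and `decision`
#'   columns are used).
#' @param decisions Observed binary decisions, aligned with `p`. Ignored
#'   when `p` is a prediction data frame.
#' @param clamp Clamping bound for the probabilities.
#' @return The log-likelihood (always `<= 0` after clamping).
#' @export
log_likelihood <- function(p, decisions = NULL, clamp = 1e-9) {
  if (is.data.frame(p)) {
    decisions <- p$decision
    p <- p$p_contribute
  }
  if (length(p) != length(decisions)) stop("p and decisions lengths differ")
  p <- pmin(pmax(p, clamp), 1 - clamp)
  sum(decisions * log(p) + (1 - decisions) * log(1 - p))
}
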