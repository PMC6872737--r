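#' Binomial belief over the number of free-riders among others
#'
#' Given the belief `gamma` that any one other member free-rides, the
#' probability that exactly `i` of the `N - 1` others free-ride is the
#' binomial mass `choose(N-1, i) * gamma^i * (1-gamma)^(N-1-i)`. At
#' `i = N - k` this is the probability of the pivotal profile in which
#' one's own contribution decides whether the goods are produced.
#'
#' @param gamma Belief that one other member free-rides, in `[0, 1]`.
#' @param i Number of free-riders among others (vectorized, `0..N-1`).
#' @param cfg A [pgg_config()].
#' @return Probability mass at `i`.
#' @export
belief_pmf <- function(gamma, i, cfg) {
  if (any(gamma < 0 | gamma > 1)) stop("gamma must lie in [0, 1]")
  if (any(i < 0 | i > cfg$N - 1)) stop("i must lie in [0, N - 1]")
  dbinom(i, size = cfg$N - 1, prob = gamma)
}

#' Probability the goods are produced given one's own contribution
#'
#' Sums the binomial belief over `i = 0 .. N - k` free-riders among the
#' others: with one's own contribution, the group succeeds whenever at
#' most `N - k` others free-ride.
#'
#' @inheritParams belief_pmf
#' @return A probability, non-increasing in `gamma`.
#' @export
success_prob_contribute <- function(gamma, cfg) {
  if (any(gamma < 0 | gamma > 1)) stop("gamma must lie in [0, 1]")
  pbinom(cfg$N - cfg$k, size = cfg$N - 1, prob = gamma)
}

#' Update the belief about others' free-riding from one round's outcome
#'
#' Reinforcement-learning update of `gamma`: the social prediction error
#' `PE_S` is the observed free-riding proportion among others minus the
#' prior belief; the learning rate is a logistic function of
#' `alpha + theta * PE_R`, where the reward prediction error `PE_R` is the
#' absolute gap between the expected group reward (`R` times the success
#' probability given contribution) and the realized group reward. The
#' update `gamma + rate * PE_S` is a convex combination, so the belief
#' stays in `[0, 1]`.
#'
#' @param gamma Prior belief, in `[0, 1]`.
#' @param n_free_others Observed number of free-riders among the others in
#'   the previous round.
#' @param group_reward Realized group reward of the previous round (0 or
#'   `R` MU).
#' @param alpha Learning-rate argument.
#' @param theta Weight of `PE_R` on the learning rate.
#' @param cfg A [pgg_config()].
#' @param rate_fn `"logistic"` (default) passes `alpha + theta * PE_R`
#'   through the logistic sigmoid; `"linear"` uses the raw value clipped
#'   to `[0, 1]`.
#' @return A list with `gamma` (updated belief), `pe_social`, `pe_reward`,
#'   `rate` and `wpe` (the weighted prediction error `rate * pe_social`,
#'   i.e. the update increment).
#' @export
update_belief <- function(gamma, n_free_others, group_reward, alpha, theta,
                          cfg, rate_fn = c("logistic", "linear")) {
  rate_fn <- match.arg(rate_fn)
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  if (n_free_others < 0 || n_free_others > cfg$N - 1) {
    stop("n_free_others must lie in [0, N - 1]")
  }
  pe_social <- n_free_others / (cfg$N - 1) - gamma
  pe_reward <- abs(cfg$R * success_prob_contribute(gamma, cfg) - group_reward)
  rate <- if (rate_fn == "logistic") {
    plogis(alpha + theta * pe_reward)
  } else {
    min(max(alpha + theta * pe_reward, 0), 1)
  }
  wpe <- rate * pe_social
  list(gamma = gamma + wpe, pe_social = pe_social, pe_reward = pe_reward,
       rate = rate, wpe = wpe)
}

#' Higher-order belief transforms
#'
#' Iterative-reasoning variants of the belief. Order 1 returns `gamma`
#' itself. Order 2 supposes the others are first-order reasoners, so the
#' probability any one of them free-rides is the pivotal-profile mass
#' `Gamma^{N-k}(gamma)`. Order 3 applies the same transform once more.
#'
#' @param gamma First-order belief, in `[0, 1]`.
#' @param order Belief order, 1, 2 or 3.
#' @param cfg A [pgg_config()].
#' @return The transformed belief.
#' @export
higher_order_belief <- function(gamma, order, cfg) {
  if (!order %in% 1:3) stop("order must be 1, 2 or 3")
  g <- gamma
  if (order >= 2) g <- belief_pmf(g, cfg$N - cfg$k, cfg)
  if (order >= 3) g <- belief_pmf(g, cfg$N - cfg$k, cfg)
  g
}
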