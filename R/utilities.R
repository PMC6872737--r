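#' Individual utility of contributing versus free-riding
#'
#' Immediate expected gain of a contribution relative to a free-ride,
#' including the altruistically weighted payout to the other members. The
#' closed form follows from the fact that the group reward differs between
#' the two choices only in the pivotal profile with `N - k` free-riders
#' among the others:
#' `I = lambda + Gamma^{N-k} R + pi * Gamma^{N-k} R (N - 1)`.
#'
#' @param gamma Belief that one other member free-rides, in `[0, 1]`.
#' @param lambda Subjective value of the contribution cost (typically
#'   negative; more negative means contribution feels costlier).
#' @param pi Altruism weight on the payout given to the other members
#'   (`pi > 0` values others' rewards, `pi < 0` is competitive).
#' @param cfg A [pgg_config()].
#' @return The signed utility difference (MU-scaled). Vectorized over
#'   `gamma`.
#' @seealso [individual_utility_enum()] for the brute-force profile sum
#'   this closed form simplifies.
#' @export
individual_utility <- function(gamma, lambda, pi, cfg) {
  g_piv <- belief_pmf(gamma, cfg$N - cfg$k, cfg)
  lambda + g_piv * cfg$R + pi * g_piv * cfg$R * (cfg$N - 1)
}

#' Individual utility by explicit enumeration (reference oracle)
#'
#' Computes the same quantity as [individual_utility()] by summing over
#' every possible count `i = 0..N-1` of free-riders among the others,
#' using the conditional group rewards `R_C` and `R_F` for each profile:
#' the focal player's own expected-reward difference plus `pi` times the
#' expected difference in the payout to the others. Serves as an
#' independent check of the closed form.
#'
#' @inheritParams individual_utility
#' @return The signed utility difference.
#' @export
individual_utility_enum <- function(gamma, lambda, pi, cfg) {
  i <- 0:(cfg$N - 1)
  rw <- conditional_group_rewards(i, cfg)
  gam <- belief_pmf(gamma, i, cfg)
  dr <- rw$R_C - rw$R_F
  own <- sum(gam * dr)
  # every one of the N-1 others receives the same group-reward difference,
  # whether they contributed ((N-1-i) of them) or free-rode (i of them)
  others <- sum(gam * ((cfg$N - 1 - i) * dr + i * dr))
  lambda + own + pi * others
}

#' Group utility: cumulative expected group reward over remaining rounds
#'
#' Expected public-goods reward accumulated over the remaining rounds
#' `t..T`, with the contribution of round `j` discounted by `K^(T-j)`
#' (`K = k/N`). The geometric sum gives
#' `G = (1 - K^(T-t+1)) / (1 - K) * R * P(success | contribute)`, so `G`
#' is largest at the start of a block and shrinks as it progresses. For
#' `k = N` (`K = 1`) the limit `(T - t + 1) * R * P` is used.
#'
#' @param gamma Belief that one other member free-rides, in `[0, 1]`.
#' @param t Current round, `1..T`.
#' @param cfg A [pgg_config()].
#' @return Non-negative utility. Vectorized over `gamma`.
#' @export
group_utility <- function(gamma, t, cfg) {
  if (any(t < 1 | t > cfg$T)) stop("t must lie in [1, T]")
  p_succ <- success_prob_contribute(gamma, cfg)
  mult <- if (cfg$K == 1) {
    cfg$T - t + 1
  } else {
    (1 - cfg$K^(cfg$T - t + 1)) / (1 - cfg$K)
  }
  mult * cfg$R * p_succ
}

#' Group utility by explicit double sum (reference oracle)
#'
#' Evaluates the remaining-horizon sum term by term:
#' `sum_{j=t}^{T} R K^{T-j} sum_{i=0}^{N-k} Gamma^i`.
#'
#' @inheritParams group_utility
#' @export
group_utility_sum <- function(gamma, t, cfg) {
  p_succ <- sum(belief_pmf(gamma, 0:(cfg$N - cfg$k), cfg))
  total <- 0
  for (j in t:cfg$T) total <- total + cfg$R * cfg$K^(cfg$T - j) * p_succ
  total
}

#' Decision value: weighted sum of individual and group utility
#'
#' @param I Individual utility.
#' @param G Group utility.
#' @param omega Weight on the individual utility, in `[0, 1]`; `1 - omega`
#'   weighs the group utility.
#' @return `omega * I + (1 - omega) * G`.
#' @export
decision_value <- function(I, G, omega) {
  if (any(omega < 0 | omega > 1)) stop("omega must lie in [0, 1]")
  omega * I + (1 - omega) * G
}

#' Contribution probability from a decision value
#'
#' Logistic sigmoid link: `p = 1 / (1 + exp(-Q))`.
#'
#' @param Q Decision value (finite).
#' @return Probability in `(0, 1)`, strictly increasing in `Q`.
#' @export
choice_prob <- function(Q) plogis(Q)
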