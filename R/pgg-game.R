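#' Threshold public goods game configuration
#'
#' Fixed parameters of a threshold public goods game (PGG). A group of `N`
#' members plays `T` rounds with the same partners. Each round every member
#' is endowed `E` monetary units (MU) and privately decides to contribute
#' (at cost `c`) or to free-ride. The group reward `R` is paid to every
#' member if and only if at least `k` members contributed.
#'
#' @param N Group size (number of members).
#' @param T Number of rounds per block (finite repetition horizon).
#' @param k Decision threshold: minimum number of contributors required to
#'   produce the public goods. Blocks of a session may override `k`; the
#'   value stored here is the default for single-block computations.
#' @param E Endowment per round, in MU.
#' @param c Cost of contribution, in MU.
#' @param R Group reward magnitude, in MU.
#'
#' @return An object of class `pgg_config`: a list with fields `N`, `T`,
#'   `k`, `E`, `c`, `R` and the threshold ratio `K = k/N`.
#'
#' @examples
#' cfg <- pgg_config()          # the study's task constants
#' cfg_weak <- pgg_config(k = 4) # weaker volunteer's dilemma
#' @export
pgg_config <- function(N = 5, T = 15, k = 2, E = 1, c = 1, R = 2) {
  stopifnot(length(N) == 1, length(T) == 1, length(k) == 1)
  N <- as.integer(N); T <- as.integer(T); k <- as.integer(k)
  if (is.na(N) || N < 2) stop("N must be an integer >= 2")
  if (is.na(T) || T < 1) stop("T must be an integer >= 1")
  if (is.na(k) || k < 1 || k > N) stop("k must satisfy 1 <= k <= N")
  if (E < 0 || c < 0 || R < 0) stop("E, c and R must be non-negative")
  structure(list(N = N, T = T, k = k, E = E, c = c, R = R, K = k / N),
            class = "pgg_config")
}

#' @export
print.pgg_config <- function(x, ...) {
  cat(sprintf(
    "Threshold PGG: N = %d, T = %d rounds, k = %d (K = %.2f), E = %g, c = %g, R = %g MU\n",
    x$N, x$T, x$k, x$K, x$E, x$c, x$R))
  invisible(x)
}

with_k <- function(cfg, k) {
  if (k == cfg$k) return(cfg)
  pgg_config(N = cfg$N, T = cfg$T, k = k, E = cfg$E, c = cfg$c, R = cfg$R)
}

#' Did the group produce the public goods?
#'
#' @param n_contributors Total number of contributors in the group
#'   (including the focal player), between 0 and `N`. Vectorized.
#' @param cfg A [pgg_config()].
#' @return Integer 0/1: 1 iff `n_contributors >= k`.
#' @examples
#' group_success(2, pgg_config(k = 2))  # 1
#' group_success(3, pgg_config(k = 4))  # 0
#' @export
group_success <- function(n_contributors, cfg) {
  if (any(n_contributors < 0 | n_contributors > cfg$N)) {
    stop("n_contributors must lie in [0, N]")
  }
  as.integer(n_contributors >= cfg$k)
}

#' Realized per-round payoff
#'
#' Computes the focal player's payoff for one round: `E - c*decision +
#' R*success`. With the study constants (E = 1, c = 1, R = 2) this is the
#' printed payoff matrix: 2 MU for a contributor and 3 MU for a free-rider
#' when the goods are produced; 0 MU and 1 MU when they are not.
#'
#' @param decision 1 = contribute, 0 = free-ride. Vectorized.
#' @param success 1 = public goods produced, 0 = not. Vectorized.
#' @param cfg A [pgg_config()].
#' @return Payoff in MU.
#' @export
pgg_payoff <- function(decision, success, cfg) {
  if (any(!decision %in% c(0, 1)) || any(!success %in% c(0, 1))) {
    stop("decision and success must be binary (0/1)")
  }
  cfg$E - cfg$c * decision + cfg$R * success
}

#' Group rewards conditional on one's own decision
#'
#' Given that `i` of the `N - 1` other members free-ride, the group reward
#' depends on whether the focal player contributes (`R_C`) or free-rides
#' (`R_F`). The two differ (by exactly `R`) only in the pivotal case
#' `i = N - k`, where one's own contribution decides the outcome.
#'
#' @param i Number of free-riders among the `N - 1` others (vectorized).
#' @param cfg A [pgg_config()].
#' @return A data frame with columns `i`, `R_C`, `R_F`.
#' @examples
#' conditional_group_rewards(3, pgg_config(k = 2))  # pivotal: R_C = 2, R_F = 0
#' @export
conditional_group_rewards <- function(i, cfg) {
  if (any(i < 0 | i > cfg$N - 1)) stop("i must lie in [0, N - 1]")
  others_contrib <- (cfg$N - 1) - i
  data.frame(
    i = i,
    R_C = ifelse(others_contrib >= cfg$k - 1, cfg$R, 0),
    R_F = ifelse(others_contrib >= cfg$k, cfg$R, 0)
  )
}
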