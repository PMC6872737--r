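#' Trial-wise model-based regressors for neuroimaging GLMs
#'
#' Evaluates the social learning model along a subject's observed data
#' and emits, for every outcome event (rounds 1..T-1, modeling the
#' decisions at rounds 2..T), the regressors used in model-based fMRI
#' analysis: the utilities `I` and `G`, the belief `gamma`, the weighted
#' prediction error `wpe` (the belief-update increment), the realized
#' group reward `reward`, the decision-trial index `t`, the change in
#' decision value `delta_q = Q_t - Q_{t-1}` (with `Q_1` computed under
#' the initial belief), and the behavioral `switch` flag.
#'
#' @param session A [pgg_session()].
#' @param params Social-learning parameters ([sl_params()] or named
#'   vector), typically a fitted estimate.
#' @param order Belief order.
#' @return A data frame with one row per outcome event: `subject`,
#'   `block`, `k`, `outcome_round` (`t - 1`), `t` (decision round), `I`,
#'   `G`, `gamma`, `wpe`, `reward`, `delta_q`, `switch` (0/1).
#' @export
build_regressors <- function(session, params, order = 1) {
  pred <- predict_sl(session, params, order)
  out <- lapply(unique(pred$block), function(b) {
    pr <- pred[pred$block == b, ]
    tr <- session$trials[session$trials$block == b, ]
    t_idx <- 2:nrow(pr)
    data.frame(subject = session$subject_id, block = b, k = pr$k[1],
               outcome_round = pr$round[t_idx - 1], t = pr$round[t_idx],
               I = pr$I[t_idx], G = pr$G[t_idx], gamma = pr$gamma[t_idx],
               wpe = pr$wpe[t_idx], reward = tr$group_reward[t_idx - 1],
               delta_q = pr$Q[t_idx] - pr$Q[t_idx - 1],
               switch = as.integer(tr$decision[t_idx] != tr$decision[t_idx - 1]))
  })
  do.call(rbind, out)
}

#' Orthogonalize confound regressors against regressors of interest
#'
#' Replaces each confound column by its residual after least-squares
#' projection onto the regressors of interest (plus an intercept), so the
#' adjusted confounds share no variance with the interest set while
#' remaining highly correlated with their originals when the shared
#' variance is modest. This is the partial-correlation scheme used to
#' let multiple regressors of interest keep their full variance in a GLM
#' instead of serially orthogonalizing them.
#'
#' @param confounds Numeric matrix (or data frame) of confound
#'   regressors, one column each.
#' @param interest Numeric matrix (or data frame) of regressors of
#'   interest; must have full column rank together with the intercept.
#' @param intercept Include an intercept column in the projection
#'   (default `TRUE`).
#' @return A matrix of adjusted confounds, same shape and column names as
#'   `confounds`. The operation is idempotent and the residuals have zero
#'   sample correlation with every interest regressor.
#' @export
partial_out <- function(confounds, interest, intercept = TRUE) {
  confounds <- as.matrix(confounds)
  interest <- as.matrix(interest)
  if (nrow(confounds) != nrow(interest)) stop("row counts differ")
  X <- if (intercept) cbind(`(Intercept)` = 1, interest) else interest
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("interest set is rank deficient")
  res <- qr.resid(qx, confounds)
  dimnames(res) <- dimnames(confounds)
  res
}

#' Behavioral switch/stay labels for outcome events
#'
#' Labels the outcome of round `t - 1` as a "switch" event when the
#' decision at round `t` differs from the decision at `t - 1`, purely
#' from behavior. Block boundaries are excluded.
#'
#' @param session A [pgg_session()].
#' @return A data frame with `subject`, `block`, `outcome_round`, `t` and
#'   `switch` (0/1).
#' @export
label_switch_stay <- function(session) {
  out <- lapply(unique(session$trials$block), function(b) {
    tr <- session$trials[session$trials$block == b, ]
    t_idx <- 2:nrow(tr)
    data.frame(subject = session$subject_id, block = b,
               outcome_round = tr$round[t_idx - 1], t = tr$round[t_idx],
               switch = as.integer(tr$decision[t_idx] != tr$decision[t_idx - 1]))
  })
  do.call(rbind, out)
}
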