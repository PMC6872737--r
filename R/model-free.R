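#' Lagged design matrix for the model-free analysis
#'
#' Builds the trial-history regressors used to test whether decisions are
#' explained by simple repetition of recent outcomes: for every trial
#' `t = 4..T` of each block, the number of free-riders among others
#' (`nF`), the subject's own decision (`D`), the success indicator (`S`)
#' and the win-stay/lose-switch interaction (`WsLs = D * S`) at lags 1-3.
#' Lags never cross block boundaries, so the first three trials of each
#' block are excluded.
#'
#' @param session A [pgg_session()].
#' @return A data frame with the outcome `y` (decision at `t`), the 12
#'   lagged regressors (`nF_l1..3`, `D_l1..3`, `S_l1..3`, `WsLs_l1..3`)
#'   and bookkeeping columns `subject`, `block`, `round`.
#' @export
build_lagged_design <- function(session) {
  out <- lapply(unique(session$trials$block), function(b) {
    tr <- session$trials[session$trials$block == b, ]
    if (nrow(tr) < 4) stop("blocks must have at least 4 rounds")
    t_idx <- 4:nrow(tr)
    row <- data.frame(subject = session$subject_id, block = b,
                      round = tr$round[t_idx], y = tr$decision[t_idx])
    for (l in 1:3) {
      row[[paste0("nF_l", l)]] <- tr$n_free_others[t_idx - l]
      row[[paste0("D_l", l)]] <- tr$decision[t_idx - l]
      row[[paste0("S_l", l)]] <- tr$success[t_idx - l]
      row[[paste0("WsLs_l", l)]] <- tr$decision[t_idx - l] * tr$success[t_idx - l]
    }
    row
  })
  do.call(rbind, out)
}

lagged_terms <- function() {
  as.vector(outer(c("nF", "D", "S", "WsLs"), 1:3,
                  function(v, l) paste0(v, "_l", l)))
}

# single-subject logistic regression with a ridge-stabilized fallback when
# the ML fit separates (non-convergence or runaway coefficients)
fit_lagged_logistic <- function(design, ridge_lambda = 0.05) {
  terms <- lagged_terms()
  x <- as.matrix(design[, terms])
  y <- design$y
  fit <- suppressWarnings(glm(y ~ x, family = binomial()))
  cf <- coef(fit)
  names(cf) <- c("(Intercept)", terms)
  ridge <- !fit$converged || any(!is.finite(cf)) || max(abs(cf[-1])) > 15
  if (ridge) {
    rf <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                         lambda = ridge_lambda, standardize = FALSE)
    cf <- setNames(as.numeric(coef(rf)), c("(Intercept)", terms))
  }
  list(coef = cf, ridge = ridge)
}

#' Two-stage model-free group analysis
#'
#' Stage one fits a per-subject logistic regression of the decision on
#' the 12 lagged history regressors; stage two treats subjects as random
#' effects by running a one-sample t-test on each coefficient across
#' subjects.
#'
#' @param sessions List of [pgg_session()] objects.
#' @param ridge_lambda L2 penalty used only when a subject's ML fit
#'   separates; such fits are flagged in the output.
#' @return A list with `coefficients` (subjects x terms matrix), `ridged`
#'   (logical per subject) and `group` (data frame per term: mean
#'   coefficient, `t`, `df`, two-sided `p`; `t` and `p` are `NA` when the
#'   across-subject variance is zero).
#' @export
fit_subject_then_group <- function(sessions, ridge_lambda = 0.05) {
  fits <- lapply(sessions, function(s) {
    fit_lagged_logistic(build_lagged_design(s), ridge_lambda)
  })
  cm <- do.call(rbind, lapply(fits, `[[`, "coef"))
  rownames(cm) <- vapply(sessions, function(s) s$subject_id, character(1))
  group <- do.call(rbind, lapply(colnames(cm), function(term) {
    v <- cm[, term]
    if (sd(v) == 0) {
      data.frame(term = term, estimate = mean(v), t = NA_real_,
                 df = length(v) - 1L, p = NA_real_)
    } else {
      tt <- t.test(v)
      data.frame(term = term, estimate = mean(v),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
    }
  }))
  list(coefficients = cm,
       ridged = vapply(fits, `[[`, logical(1), "ridge"),
       group = group)
}
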