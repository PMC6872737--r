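#' Choice-model parameter constructors
#'
#' Typed parameter sets for the four competing choice models.
#'
#' * **Social learning** (`sl_params`): `omega` in `[0, 1]` weighs
#'   individual against group utility; `pi` is the altruism weight;
#'   `lambda` the subjective contribution cost; `alpha` and `theta` govern
#'   the belief learning rate.
#' * **Myopic** (`myopic_params`): only the individual utility enters the
#'   decision value, scaled by `omega >= 0` (unbounded above).
#' * **Group utility** (`gu_params`): decision value `zeta + chi * G` with
#'   initial bias `zeta`; beliefs learned as in the social learning model.
#' * **Inequity aversion** (`ia_params`): contribution probability
#'   `p(C_1) * logistic(kappa * sum(epsilon * R_i - delta * (C_i - Cbar_i)))`
#'   accumulated within a block; `p(C_1)` is the subject's control-block
#'   contribution rate and is taken from the data, not fitted.
#'
#' @param omega,pi,lambda,alpha,theta,chi,zeta,delta,epsilon,kappa Model
#'   parameters, see Details.
#' @return A named numeric vector with class `c("<model>_params",
#'   "pgg_params")`.
#' @name model_params
NULL

#' @rdname model_params
#' @export
sl_params <- function(omega, pi, lambda, alpha, theta) {
  if (omega < 0 || omega > 1) stop("omega must lie in [0, 1] for the social learning model")
  new_params("sl", c(omega = omega, pi = pi, lambda = lambda,
                     alpha = alpha, theta = theta))
}

#' @rdname model_params
#' @export
myopic_params <- function(omega, pi, lambda, alpha, theta) {
  if (omega < 0) stop("omega must be >= 0 for the myopic model")
  new_params("myopic", c(omega = omega, pi = pi, lambda = lambda,
                         alpha = alpha, theta = theta))
}

#' @rdname model_params
#' @export
gu_params <- function(chi, zeta, alpha, theta) {
  new_params("gu", c(chi = chi, zeta = zeta, alpha = alpha, theta = theta))
}

#' @rdname model_params
#' @export
ia_params <- function(delta, epsilon, kappa) {
  if (delta < 0) stop("delta must be >= 0")
  if (kappa <= 0) stop("kappa must be > 0")
  new_params("ia", c(delta = delta, epsilon = epsilon, kappa = kappa))
}

new_params <- function(model, x) {
  if (any(!is.finite(x))) stop("parameters must be finite")
  structure(x, class = c(paste0(model, "_params"), "pgg_params"),
            model = model)
}

PGG_MODELS <- c("sl", "myopic", "gu", "ia")

model_par_names <- function(model) {
  switch(model,
         sl = ,
         myopic = c("omega", "pi", "lambda", "alpha", "theta"),
         gu = c("chi", "zeta", "alpha", "theta"),
         ia = c("delta", "epsilon", "kappa"),
         stop("unknown model: ", model))
}

# bound constraints used by the fitter; wide margins around plausible
# estimates for each model
model_bounds <- function(model) {
  switch(model,
         sl = list(lower = c(omega = 0, pi = -5, lambda = -10, alpha = -10, theta = -5),
                   upper = c(omega = 1, pi = 5, lambda = 10, alpha = 10, theta = 5)),
         myopic = list(lower = c(omega = 0, pi = -5, lambda = -10, alpha = -10, theta = -5),
                       upper = c(omega = 50, pi = 5, lambda = 10, alpha = 10, theta = 5)),
         gu = list(lower = c(chi = -50, zeta = -50, alpha = -10, theta = -5),
                   upper = c(chi = 50, zeta = 50, alpha = 10, theta = 5)),
         ia = list(lower = c(delta = 0, epsilon = -5, kappa = 1e-6),
                   upper = c(delta = 50, epsilon = 5, kappa = 50)),
         stop("unknown model: ", model))
}

# canonical deterministic starting points, one per row; the first rows of
# every multi-start fit before random restarts are added
model_start_set <- function(model) {
  m <- switch(model,
    sl = rbind(c(0.5, 0, -1, 0.5, 0.1),
               c(0.9, 0.2, -2, 0.5, 0.1),
               c(0.2, 0, -0.5, 0, 0)),
    myopic = rbind(c(1, 0, -1, 0.5, 0.1),
                   c(10, 0.3, -3, 0.5, 0.1),
                   c(0.2, 0, -0.5, 0, 0)),
    gu = rbind(c(1, 0, 0.5, 0.1),
               c(10, -30, 0.5, 0.1),
               c(-5, 5, 0.5, 0.1)),
    ia = rbind(c(1, 0.5, 1),
               c(16, 0.6, 1.4),
               c(0.5, 0, 0.2)),
    stop("unknown model: ", model))
  colnames(m) <- model_par_names(model)
  m
}

# ranges from which random restarts are drawn: narrower than the bound
# constraints, centred on the plausible region — starts on the flat
# saturated shoulders of the likelihood strand L-BFGS-B at the boundary
model_start_range <- function(model) {
  switch(model,
         sl = list(lower = c(omega = 0, pi = -2, lambda = -6, alpha = -3, theta = -2),
                   upper = c(omega = 1, pi = 2, lambda = 2, alpha = 3, theta = 2)),
         myopic = list(lower = c(omega = 0, pi = -2, lambda = -6, alpha = -3, theta = -2),
                       upper = c(omega = 20, pi = 2, lambda = 2, alpha = 3, theta = 2)),
         gu = list(lower = c(chi = -20, zeta = -35, alpha = -3, theta = -2),
                   upper = c(chi = 20, zeta = 35, alpha = 3, theta = 2)),
         ia = list(lower = c(delta = 0, epsilon = -2, kappa = 0.05),
                   upper = c(delta = 30, epsilon = 2, kappa = 5)),
         stop("unknown model: ", model))
}

params_vector <- function(params, model) {
  nm <- model_par_names(model)
  x <- unclass(params)
  if (!all(nm %in% names(x))) {
    stop("params must contain: ", paste(nm, collapse = ", "))
  }
  x[nm]
}
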