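test_that("regressor table aligns outcome events with modeled decisions", {
  s <- random_session(91, n_blocks = 3)
  prm <- sl_test_params()
  reg <- build_regressors(s, prm)
  expect_equal(nrow(reg), 3 * 14)          # outcomes 1..14 per block
  expect_equal(reg$t, reg$outcome_round + 1)

  pred <- predict_sl(s, prm)
  b2 <- pred[pred$block == 2, ]
  r2 <- reg[reg$block == 2, ]
  expect_equal(r2$I, b2$I[2:15])
  expect_equal(r2$G, b2$G[2:15])
  expect_equal(r2$gamma, b2$gamma[2:15])
  expect_equal(r2$wpe, b2$wpe[2:15])
  expect_equal(r2$delta_q, b2$Q[2:15] - b2$Q[1:14])
  tr2 <- s$trials[s$trials$block == 2, ]
  expect_equal(r2$reward, tr2$group_reward[1:14])
  expect_equal(r2$switch,
               as.integer(tr2$decision[2:15] != tr2$decision[1:14]))
  expect_false(anyNA(reg$wpe))
  expect_false(anyNA(reg$delta_q))
})

test_that("weighted prediction error vanishes when the belief is confirmed", {
  cfg <- pgg_config(T = 3, k = 2)
  # gamma_1 = 0.5 and two observed free-riders among four: PE_S = 0
  trials <- data.frame(block = 1L, k = 2L, round = 1:3,
                       decision = c(1L, 1L, 1L),
                       n_free_others = c(2L, 2L, 2L))
  trials$success <- 1L
  trials$group_reward <- 2
  s <- pgg_session("W", trials, control_rate = 0.5, cfg)
  reg <- build_regressors(s, sl_test_params())
  expect_equal(reg$wpe, c(0, 0))
  expect_equal(reg$gamma, c(0.5, 0.5))
  # with the belief frozen, the only decision-value drift left is the
  # shrinking horizon of the group utility
  expect_equal(reg$delta_q,
               0.6 * 0 + 0.4 * diff(group_utility(0.5, 1:3, cfg)))
})

test_that("the sign of delta-Q tracks the change in contribution probability", {
  s <- random_session(92)
  reg <- build_regressors(s, sl_test_params())
  pred <- predict_sl(s, sl_test_params())
  dp <- unlist(lapply(split(pred, pred$block), function(b) {
    diff(b$p_contribute)
  }), use.names = FALSE)
  expect_equal(sign(reg$delta_q), sign(dp))
})

test_that("partial_out orthogonalizes confounds against the interest set", {
  set.seed(93)
  n <- 150
  interest <- cbind(I = rnorm(n), G = rnorm(n))
  confounds <- cbind(wpe = 0.6 * interest[, 1] + rnorm(n, 0, 0.8),
                     t = rnorm(n))
  adj <- partial_out(confounds, interest)
  expect_equal(dim(adj), dim(confounds))
  expect_lt(max(abs(cor(adj, interest))), 1e-10)
  # idempotent
  expect_equal(partial_out(adj, interest), adj, tolerance = 1e-12)
  # modest shared variance: adjusted confound stays close to its original
  expect_gt(cor(adj[, "wpe"], confounds[, "wpe"]), 0.7)
  # a confound orthogonal to the interests is unchanged up to its mean
  ortho <- residuals(lm(confounds[, "t"] ~ interest))
  expect_equal(unname(partial_out(cbind(x = ortho), interest)[, 1]),
               unname(ortho), tolerance = 1e-10)
  # a confound equal to an interest regressor residualizes to zero
  expect_lt(max(abs(partial_out(cbind(interest[, 1]), interest))), 1e-10)
  # rank-deficient interest set is refused
  expect_error(partial_out(confounds, cbind(interest[, 1], interest[, 1])),
               "rank deficient")
})

test_that("switch/stay labels follow the behavioral sequence", {
  cfg <- pgg_config(T = 4, k = 2)
  trials <- data.frame(block = 1L, k = 2L, round = 1:4,
                       decision = c(1L, 1L, 0L, 1L),
                       n_free_others = rep(1L, 4))
  trials$success <- as.integer(trials$decision + 3 >= 2)
  trials$group_reward <- 2 * trials$success
  s <- pgg_session("SW", trials, 0.5, cfg)
  lab <- label_switch_stay(s)
  expect_equal(lab$switch, c(0L, 1L, 1L))   # stay, switch, switch
  expect_equal(lab$outcome_round, 1:3)

  const <- trials; const$decision <- 1L
  const$success <- 1L; const$group_reward <- 2
  expect_equal(label_switch_stay(pgg_session("C", const, 0.5, cfg))$switch,
               rep(0L, 3))
  alt <- trials; alt$decision <- c(1L, 0L, 1L, 0L)
  alt$success <- as.integer(alt$decision + 3 >= 2)
  alt$group_reward <- 2 * alt$success
  expect_equal(label_switch_stay(pgg_session("A", alt, 0.5, cfg))$switch,
               rep(1L, 3))
})
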