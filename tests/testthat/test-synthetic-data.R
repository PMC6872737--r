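test_that("co-player round-1 behavior mirrors the subject's control rate", {
  cfg <- pgg_config()
  set.seed(61)
  draws <- replicate(4000, {
    b <- simulate_block("sl", sl_test_params(), control_rate = 0.7, cfg)
    (cfg$N - 1) - b$n_free_others[1]
  })
  expect_equal(mean(draws) / (cfg$N - 1), 0.7, tolerance = 0.03)
})

test_that("co-player policy has the three documented tendencies", {
  cfg <- pgg_config()
  cp <- coplayer_params()
  # stay tendency
  expect_gt(coplayer_prob(1, 0.5, 0, 5, cfg, cp),
            coplayer_prob(0, 0.5, 0, 5, cfg, cp))
  # more contribution in a cooperative group
  expect_gt(coplayer_prob(1, 1, 0, 5, cfg, cp),
            coplayer_prob(1, 0.25, 0, 5, cfg, cp))
  # failure in an uncooperative group promotes free-riding ...
  expect_lt(coplayer_prob(0, 0.25, 1, 5, cfg, cp),
            coplayer_prob(0, 0.25, 0, 5, cfg, cp))
  # ... and matters less in a cooperative group
  drop_unco <- coplayer_prob(0, 0.25, 0, 5, cfg, cp) -
    coplayer_prob(0, 0.25, 1, 5, cfg, cp)
  drop_coop <- coplayer_prob(1, 1, 0, 5, cfg, cp) -
    coplayer_prob(1, 1, 1, 5, cfg, cp)
  expect_gt(drop_unco, drop_coop)
  # saturation: an extreme stay weight locks in the previous decision
  sticky <- coplayer_params(beta_stay = 60, intercept = -30)
  expect_gt(coplayer_prob(1, 0.5, 0, 5, cfg, sticky), 0.999)
  expect_lt(coplayer_prob(0, 0.5, 0, 5, cfg, sticky), 0.001)
  expect_error(coplayer_prob(1, 0.5, 0, 1, cfg, cp), "round 2")
})

test_that("Monte-Carlo contrast: cooperative history raises contribution", {
  cfg <- pgg_config()
  set.seed(62)
  p_coop <- coplayer_prob(1, 1, 0, 8, cfg)
  p_unco <- coplayer_prob(0, 0, 1, 8, cfg)
  coop <- mean(rbinom(10000, 1, p_coop))
  unco <- mean(rbinom(10000, 1, p_unco))
  expect_gt(coop, unco)
})

test_that("a block plays deterministically in the all-contribute limit", {
  cfg <- pgg_config(k = 2)
  # focal driven to certain contribution, co-players locked to contribute
  prm <- sl_params(1, 0, 10, 0, 0)  # I = 10 + ... > 0 -> p ~ 1
  cp <- coplayer_params(intercept = 50, beta_stay = 0, beta_coop = 0,
                        beta_fail = 0)
  set.seed(63)
  b <- simulate_block("sl", prm, control_rate = 1, cfg, coplayers = cp)
  expect_equal(b$decision, rep(1L, cfg$T))
  expect_equal(b$success, rep(1L, cfg$T))
  expect_equal(pgg_payoff(b$decision, b$success, cfg), rep(2, cfg$T))
})

test_that("block simulation is reproducible under a fixed seed", {
  cfg <- pgg_config(k = 4)
  set.seed(64)
  b1 <- simulate_block("gu", gu_params(5, -8, 0.5, 0.1), 0.6, cfg)
  set.seed(64)
  b2 <- simulate_block("gu", gu_params(5, -8, 0.5, 0.1), 0.6, cfg)
  expect_identical(b1, b2)
})

test_that("cohorts have the study layout and a recorded ground truth", {
  spec <- cohort_spec(n_subjects = 4, seed = 9)
  co <- simulate_cohort(spec)
  expect_length(co$sessions, 4)
  for (s in co$sessions) {
    expect_equal(nrow(s$trials), 12 * 15)
    expect_equal(sort(unique(s$trials$k)), c(2L, 4L))
    expect_equal(sum(tapply(s$trials$k, s$trials$block, unique) == 2), 6)
  }
  expect_equal(nrow(co$ground_truth), 4)
  expect_true(all(c("omega", "pi", "lambda", "alpha", "theta",
                    "control_rate") %in% names(co$ground_truth)))
  # empty cohort
  expect_length(simulate_cohort(cohort_spec(n_subjects = 0))$sessions, 0)
})

test_that("seeded cohorts rerun to byte-identical files", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(cohort_spec(n_subjects = 2, seed = 77)), dir1)
  write_cohort(simulate_cohort(cohort_spec(n_subjects = 2, seed = 77)), dir2)
  for (f in c("trials.tsv", "subjects.tsv", "ground_truth.tsv")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  # different seed, different data
  write_cohort(simulate_cohort(cohort_spec(n_subjects = 2, seed = 78)), dir2)
  expect_false(identical(readLines(file.path(dir1, "trials.tsv")),
                         readLines(file.path(dir2, "trials.tsv"))))
})

test_that("generating parameters respect their admissible ranges", {
  co <- simulate_cohort(cohort_spec(n_subjects = 12, seed = 10))
  gt <- co$ground_truth
  expect_true(all(gt$omega >= 0 & gt$omega <= 1))
  expect_true(all(gt$control_rate > 0 & gt$control_rate < 1))
  co_ia <- simulate_cohort(cohort_spec(n_subjects = 6, model = "ia", seed = 11))
  expect_true(all(co_ia$ground_truth$delta >= 0))
  expect_true(all(co_ia$ground_truth$kappa > 0))
})
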