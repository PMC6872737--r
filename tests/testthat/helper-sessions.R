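# fixtures built in code: random-but-consistent sessions and a tiny
# hand-sized session used by several oracle tests

# session whose decisions and co-player contributions are random coin
# flips; outcome columns are derived so the threshold rule holds
random_session <- function(seed, n_blocks = 4, cfg = pgg_config(),
                           k_levels = c(2L, 4L), control_rate = 0.4,
                           subject_id = "R1") {
  set.seed(seed)
  ks <- rep(k_levels, length.out = n_blocks)
  trials <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    dec <- rbinom(cfg$T, 1, 0.5)
    co <- rbinom(cfg$T, cfg$N - 1, 0.5)
    succ <- as.integer(dec + co >= ks[b])
    data.frame(block = b, k = ks[b], round = seq_len(cfg$T), decision = dec,
               n_free_others = cfg$N - 1 - co, success = succ,
               group_reward = cfg$R * succ)
  }))
  pgg_session(subject_id, trials, control_rate, cfg)
}

# three-round single-block session with fixed outcomes, small enough to
# trace by hand
tiny_session <- function(cfg = pgg_config(T = 3, k = 2)) {
  trials <- data.frame(block = 1L, k = 2L, round = 1:3,
                       decision = c(1L, 0L, 1L),
                       n_free_others = c(2L, 3L, 1L))
  trials$success <- as.integer(trials$decision +
                                 (cfg$N - 1 - trials$n_free_others) >= trials$k)
  trials$group_reward <- cfg$R * trials$success
  pgg_session("T1", trials, control_rate = 0.4, cfg)
}

sl_test_params <- function() {
  sl_params(omega = 0.6, pi = 0.2, lambda = -2, alpha = 0.3, theta = 0.1)
}
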