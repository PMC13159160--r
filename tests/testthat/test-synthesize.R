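test_that("indicator kernel is causal, peak-normalized and decaying", {
  expect_equal(gcamp_kernel(0), 0)
  expect_equal(gcamp_kernel(-1), 0)
  # closed-form peak location/value verified against a dense grid search
  tpk <- gcamp_peak_time(0.18, 1.8)
  expect_equal(gcamp_kernel(tpk), 1)
  grid <- seq(0, 10, by = 1e-4)
  kg <- gcamp_kernel(grid)
  expect_equal(max(kg), 1, tolerance = 1e-6)
  expect_equal(grid[which.max(kg)], tpk, tolerance = 1e-3)
  expect_lt(gcamp_kernel(100 * 1.8), 1e-10)
  # other kinetics obey the same closed form
  for (tr in c(0.05, 0.3)) for (td in c(0.9, 3)) {
    tp <- gcamp_peak_time(tr, td)
    expect_equal(gcamp_kernel(tp, tr, td), 1, info = paste(tr, td))
  }
  expect_error(gcamp_kernel(1, tau_rise = -1), "positive")
  expect_error(gcamp_kernel(1, tau_rise = 2, tau_decay = 1), "exceed")
})

test_that("generator is deterministic and substreams are stable", {
  a <- quick_session(seed = 3)
  b <- quick_session(seed = 3)
  expect_identical(a$traces$roi, b$traces$roi)
  expect_identical(a$ground_truth$evoked_events, b$ground_truth$evoked_events)
  d <- quick_session(seed = 4)
  expect_false(identical(a$traces$roi, d$traces$roi))
  # adding neurons does not perturb the traces of existing ones (role
  # planting is held fixed at zero responders: placement is count-exact and
  # therefore depends on the population size by design)
  cfg40 <- population_config(n_neurons = 40, us_responder_fraction = 0,
                             visual_responder_fraction = 0)
  cfg55 <- population_config(n_neurons = 55, us_responder_fraction = 0,
                             visual_responder_fraction = 0)
  s40 <- synthesize_traces(small_protocol(), cfg40, seed = 3)
  s55 <- synthesize_traces(small_protocol(), cfg55, seed = 3)
  expect_identical(s40$traces$roi, s55$traces$roi[, 1:40])
})

test_that("everything off yields constant traces at F0", {
  cfg <- population_config(n_neurons = 5, noise_sd = 0, spontaneous_rate = 0,
                           us_responder_fraction = 0, bg_amp = 0,
                           bg_amp_jitter = 0, visual_responder_fraction = 0)
  sim <- synthesize_traces(small_protocol(), cfg, seed = 1)
  corrected <- subtract_background(sim$traces)
  expect_equal(apply(corrected, 2, stats::sd), rep(0, 5))
  expect_equal(unname(corrected[1, ]),
               sim$ground_truth$f0 + (cfg$neuropil_coef - 1) * cfg$bg_offset)
})

test_that("a certain responder shows a transient at every onset", {
  cfg <- population_config(n_neurons = 10, noise_sd = 0, spontaneous_rate = 0,
                           us_responder_fraction = 0.1, us_response_prob = 1,
                           bg_amp = 0, bg_amp_jitter = 0, amp_sdlog = 0)
  sim <- synthesize_traces(small_protocol(), cfg, seed = 2)
  gt <- sim$ground_truth
  i <- which(gt$us_responder)
  expect_length(i, 1)
  expect_true(all(gt$evoked_events[i, ]))
  fs <- sim$traces$sampling_rate
  tr <- subtract_background(sim$traces)[, i]
  for (on in sim$traces$onsets) {
    j <- round(on * fs) + 1
    # flat up to the onset frame, rising within 1 frame after it
    expect_equal(tr[j], tr[j - 5])
    expect_gt(tr[j + 5], tr[j])
  }
})

test_that("event bookkeeping matches the planted Bernoulli draws", {
  sim <- quick_session(seed = 9)
  gt <- sim$ground_truth
  expect_equal(gt$n_evoked, sum(gt$evoked_events))
  # non-responders never get evoked events
  expect_true(all(!gt$evoked_events[!gt$us_responder & !gt$visual_responder, ]))
  # every onset admits a full epoch
  ts <- sim$traces
  expect_true(all(ts$onsets >= 5))
  expect_true(all(ts$onsets <= ts$session_length - 25))
})

test_that("spontaneous event counts follow the configured Poisson rate", {
  rate <- 0.05
  counts <- unlist(lapply(1:6, function(s) {
    sim <- synthesize_traces(
      small_protocol(n_trials = 3),
      population_config(n_neurons = 60, spontaneous_rate = rate,
                        us_responder_fraction = 0), seed = 100 + s)
    sim$ground_truth$n_spontaneous
  }))
  dur <- synthesize_traces(small_protocol(n_trials = 3),
                           population_config(n_neurons = 1),
                           seed = 1)$traces$session_length
  expected <- rate * dur
  # 360 neuron-sessions: the mean lands within 4 SE of rate * duration
  se <- sqrt(expected / length(counts))
  expect_lt(abs(mean(counts) - expected), 4 * se)
})

test_that("planted transient component scales linearly with amplitude", {
  base <- population_config(n_neurons = 10, noise_sd = 0, spontaneous_rate = 0,
                            us_responder_fraction = 0.2, us_response_prob = 1,
                            bg_amp = 0, bg_amp_jitter = 0, amp_sdlog = 0,
                            amp_meanlog = log(1))
  doubled <- base; doubled$amp_meanlog <- log(2)
  s1 <- synthesize_traces(small_protocol(), base, seed = 5)
  s2 <- synthesize_traces(small_protocol(), doubled, seed = 5)
  c1 <- subtract_background(s1$traces)
  c2 <- subtract_background(s2$traces)
  f0 <- s1$ground_truth$f0
  # transient component = corrected - flat part; doubling amp doubles it
  flat1 <- matrix(c1[1, ], nrow(c1), ncol(c1), byrow = TRUE)
  flat2 <- matrix(c2[1, ], nrow(c2), ncol(c2), byrow = TRUE)
  expect_equal(c2 - flat2, 2 * (c1 - flat1), tolerance = 1e-12)
})

test_that("trace sets round-trip through CSV + JSON", {
  sim <- synthesize_traces(small_protocol(n_trials = 2),
                           population_config(n_neurons = 6), seed = 8)
  dir <- withr::local_tempdir()
  write_traceset(sim$traces, dir)
  back <- read_traceset(dir)
  expect_equal(back$roi, sim$traces$roi, tolerance = 1e-12)
  expect_equal(back$onsets, sim$traces$onsets)
  expect_equal(back$condition, sim$traces$condition)
  expect_equal(back$analyzed, sim$traces$analyzed)
  expect_equal(back$sampling_rate, sim$traces$sampling_rate)
})
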