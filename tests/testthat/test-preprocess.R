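test_that("background subtraction is the elementwise difference", {
  x <- matrix(rnorm(60), 12, 5)
  expect_equal(subtract_background(x, x), matrix(0, 12, 5))
  expect_equal(subtract_background(x + 7, x), matrix(7, 12, 5))
  y <- matrix(rnorm(60), 12, 5)
  # naive loop oracle
  ref <- x
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x)))
    ref[i, j] <- x[i, j] - y[i, j]
  expect_equal(subtract_background(x, y), ref)
  expect_error(subtract_background(x, y[1:5, ]), "shapes differ")
})

test_that("frame averaging takes exact block means and drops the tail", {
  expect_equal(average_frames(rep(4.2, 30), 10), rep(4.2, 3))
  expect_equal(average_frames(1:30, 10), c(5.5, 15.5, 25.5))
  expect_length(average_frames(rnorm(30), 10), 3)  # 30 Hz -> 3 Hz
  # remainder frames are dropped
  expect_equal(average_frames(c(1:30, 100, 200), 10), c(5.5, 15.5, 25.5))
  # matrix input averages each column independently
  m <- cbind(1:30, 31:60)
  expect_equal(average_frames(m, 10), cbind(c(5.5, 15.5, 25.5), c(35.5, 45.5, 55.5)))
  expect_error(average_frames(1:30, 0), "positive")
  expect_error(average_frames(1:3, 10), "fewer frames")
})

test_that("epoching yields 90 aligned frames per analyzed onset", {
  fs <- 3
  tr <- matrix(seq_len(300 * fs), ncol = 1)  # strictly increasing ramp
  et <- epoch_traces(tr, onsets = c(20, 50), sampling_rate = fs)
  expect_equal(dim(et$values), c(1, 2, 90))   # (5+25) s * 3 Hz
  # onset exactly on a frame: epoch frame 16 (index of t=0) is that frame
  i0 <- round(20 * fs) + 1
  expect_equal(et$values[1, 1, 16], tr[i0, 1])
  expect_equal(et$values[1, 1, 1], tr[i0 - 15, 1])
  # identical onsets on a periodic trace give identical epochs
  per <- matrix(sin(2 * pi * (0:899) / 30), ncol = 1)
  ep <- epoch_traces(per, onsets = c(60, 70), sampling_rate = fs)
  expect_equal(ep$values[1, 1, ], ep$values[1, 2, ])
  expect_error(epoch_traces(tr, onsets = 3, sampling_rate = fs),
               "truncated.*3 s")
  expect_error(epoch_traces(tr, onsets = 299, sampling_rate = fs), "truncated")
})

test_that("dF/F normalizes each epoch by its own baseline mean", {
  cfg <- analysis_config()
  const <- one_epoch(rep(50, 90), units = "raw_F")
  expect_equal(as.numeric(compute_dff(const, cfg)$values), rep(0, 90))
  # baseline 100, plateau 200 after onset -> dF/F 1 post-onset
  step <- one_epoch(c(rep(100, 15), rep(200, 75)), units = "raw_F")
  d <- compute_dff(step, cfg)
  expect_equal(as.numeric(d$values[1, 1, 16:90]), rep(1, 75))
  expect_equal(d$units, "dff")
  # per-frame loop oracle on an arbitrary epoch
  set.seed(42)
  x <- abs(rnorm(90, 100, 10))
  et <- one_epoch(x, units = "raw_F")
  f0 <- mean(x[1:15])
  expect_equal(as.numeric(compute_dff(et, cfg)$values), (x - f0) / f0)
  # units gating: dff in, dff again out is rejected
  expect_error(compute_dff(d, cfg), "expects raw_F")
  # degenerate baseline
  neg <- one_epoch(c(rep(-1, 15), rep(10, 75)), units = "raw_F")
  expect_error(compute_dff(neg, cfg), "degenerate baseline")
})

test_that("z-scoring uses baseline mean/SD and flags zero-SD trials", {
  cfg <- analysis_config()
  # hand-built baseline with mean exactly 0 and SD exactly 0.1
  bl <- c(rep(-0.1, 7), rep(0.1, 7), 0)
  x <- c(bl, rep(0, 75)); x[20] <- 0.35
  z <- zscore_epochs(one_epoch(x), cfg)
  expect_equal(z$values[1, 1, 20], 3.5)
  expect_equal(mean(z$values[1, 1, 1:15]), 0)
  # zero baseline SD: flagged invalid, not an error
  flat <- one_epoch(c(rep(0, 15), rnorm(75)))
  zf <- zscore_epochs(flat, cfg)
  expect_false(zf$valid[1, 1])
  expect_true(all(is.na(zf$values)))
  # units gating
  expect_error(zscore_epochs(z, cfg), "expects")
})

test_that("dF/F and z are invariant to rescaling the raw fluorescence", {
  sim <- quick_session(seed = 13)
  cfg <- analysis_config()
  base <- preprocess_condition(sim$traces, "ultrasound", cfg)
  set.seed(1)
  for (a in stats::runif(3, 0.1, 10)) {
    scaled <- sim$traces
    scaled$roi <- a * scaled$roi
    scaled$background <- a * scaled$background
    got <- preprocess_condition(scaled, "ultrasound", cfg)
    expect_equal(got$dff$values, base$dff$values, tolerance = 1e-9)
    expect_equal(got$z$values, base$z$values, tolerance = 1e-9)
  }
})

test_that("session-scope z-scoring is available and differs from per-epoch", {
  sim <- quick_session(seed = 21)
  z_ep <- preprocess_condition(sim$traces, "ultrasound", analysis_config())$z
  z_se <- preprocess_condition(sim$traces, "ultrasound",
                               analysis_config(zscore_scope = "session"))$z
  expect_equal(dim(z_ep$values), dim(z_se$values))
  expect_false(isTRUE(all.equal(z_ep$values, z_se$values)))
})

test_that("epoch tensors round-trip through the CSV directory container", {
  sim <- quick_session(seed = 30, config = small_config())
  et <- preprocess_condition(sim$traces, "ultrasound")$dff
  dir <- withr::local_tempdir()
  write_epochs(et, dir)
  back <- read_epochs(dir)
  expect_equal(back$values, et$values, tolerance = 1e-12)
  expect_equal(back$units, "dff")
  expect_equal(back$window, et$window)
})
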