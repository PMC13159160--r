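#' Double-exponential calcium indicator impulse response
#'
#' Peak-normalized GCaMP-style transient
#' `k(t) = (exp(-t/tau_decay) - exp(-t/tau_rise)) / k(t*)`, zero for `t <= 0`,
#' where `t* = tau_rise*tau_decay/(tau_decay - tau_rise) * log(tau_decay/tau_rise)`
#' is the closed-form peak time. Defaults approximate GCaMP6s kinetics.
#'
#' @param t Time since event onset, s (vectorized; negative times give 0).
#' @param tau_rise Rise time constant, s.
#' @param tau_decay Decay time constant, s; must exceed `tau_rise`.
#' @return Kernel values in `[0, 1]`, peaking at exactly 1.
#' @examples
#' gcamp_kernel(gcamp_peak_time(0.18, 1.8))  # 1
#' @export
gcamp_kernel <- function(t, tau_rise = 0.18, tau_decay = 1.8) {
  if (tau_rise <= 0 || tau_decay <= 0) stop("time constants must be positive")
  if (tau_decay <= tau_rise) stop("tau_decay must exceed tau_rise")
  tpk <- gcamp_peak_time(tau_rise, tau_decay)
  peak <- exp(-tpk / tau_decay) - exp(-tpk / tau_rise)
  k <- ifelse(t > 0, (exp(-t / tau_decay) - exp(-t / tau_rise)) / peak, 0)
  k
}

#' @rdname gcamp_kernel
#' @export
gcamp_peak_time <- function(tau_rise = 0.18, tau_decay = 1.8) {
  if (tau_rise <= 0 || tau_decay <= 0) stop("time constants must be positive")
  if (tau_decay <= tau_rise) stop("tau_decay must exceed tau_rise")
  tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
}

#' Population configuration for the synthetic-trace generator
#'
#' Describes the simulated field of view: baseline fluorescence, noise,
#' neuropil contamination, spontaneous activity, and the planted responder
#' populations with their response probabilities and amplitudes. Defaults
#' emulate a 30 Hz recording of a few hundred V1 neurons with a sparse
#' (~1.2%) ultrasound-responsive population and enough spontaneous activity
#' that roughly a tenth of neurons respond weakly by chance.
#'
#' @param n_neurons Number of neurons in the field.
#' @param sampling_rate Raw acquisition rate, Hz.
#' @param f0_mean,f0_cv Mean and coefficient of variation of the lognormal
#'   per-neuron baseline fluorescence F0 (a.u.).
#' @param noise_sd SD of additive i.i.d. Gaussian noise on F (a.u., at the
#'   raw rate).
#' @param neuropil_coef Fraction of the background (neuropil) trace that
#'   contaminates the ROI trace. Full subtraction of the recorded background
#'   therefore leaves a bounded residual `(neuropil_coef - 1) * background`
#'   in the corrected trace, as in real recordings.
#' @param bg_offset Constant background level (a.u.).
#' @param bg_amp Amplitude of the slow background oscillation (a.u.);
#'   jittered per neuron by `bg_amp_jitter` (relative).
#' @param bg_amp_jitter Relative uniform jitter on `bg_amp`.
#' @param bg_freq_range Range of the per-neuron background oscillation
#'   frequency, Hz.
#' @param spontaneous_rate Poisson rate of spontaneous transients per neuron,
#'   events/s. Calibrated so that sham recordings yield ~8-10% weakly
#'   responding neurons under the default classification thresholds.
#' @param amp_meanlog,amp_sdlog Lognormal parameters of transient amplitudes
#'   in dF/F units (evoked and spontaneous share the distribution).
#' @param us_responder_fraction Fraction of neurons planted as ultrasound
#'   responders (exact count `round(fraction * n_neurons)`).
#' @param us_response_prob Per-trial response probability of ultrasound
#'   responders. `NULL` (default) uses the logistic pressure curve
#'   `response_prob_max * plogis((P - pressure_p50)/pressure_slope)` (0 at
#'   0 kPa); a number fixes the probability regardless of pressure.
#' @param response_prob_max,pressure_p50,pressure_slope Logistic
#'   pressure-response parameters (max probability; half-max pressure and
#'   slope, kPa).
#' @param visual_responder_fraction Fraction of planted visual responders.
#' @param visual_response_prob Per-trial response probability of visual
#'   responders to visual (and combined) stimulation.
#' @param suppressed_frac,enhanced_frac Fractions of visual responders whose
#'   combined-condition response amplitude is scaled by `gain_suppressed` /
#'   `gain_enhanced`; the remainder are unmodulated.
#' @param gain_suppressed,gain_enhanced Multiplicative amplitude gains under
#'   simultaneous ultrasound.
#' @param tau_rise,tau_decay Indicator kinetics, s.
#' @param first_onset First (invalid) train onset within each condition
#'   block, s.
#' @param tail_s Recording tail after the last epoch of each block, s.
#' @return A list of class `population_config`.
#' @export
population_config <- function(n_neurons = 430,
                              sampling_rate = 30,
                              f0_mean = 100, f0_cv = 0.2,
                              noise_sd = 2,
                              neuropil_coef = 0.7,
                              bg_offset = 25,
                              bg_amp = 21,
                              bg_amp_jitter = 0.2,
                              bg_freq_range = c(0.2, 0.45),
                              spontaneous_rate = 0.003,
                              amp_meanlog = 0, amp_sdlog = 0.25,
                              us_responder_fraction = 0.012,
                              us_response_prob = NULL,
                              response_prob_max = 0.9,
                              pressure_p50 = 250,
                              pressure_slope = 100,
                              visual_responder_fraction = 0.014,
                              visual_response_prob = 0.95,
                              suppressed_frac = 1 / 3,
                              enhanced_frac = 1 / 3,
                              gain_suppressed = 0.4,
                              gain_enhanced = 1.8,
                              tau_rise = 0.18, tau_decay = 1.8,
                              first_onset = 10,
                              tail_s = 10) {
  cfg <- as.list(environment())
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$f0_mean <= 0) stop("f0_mean must be > 0")
  if (cfg$spontaneous_rate < 0) stop("spontaneous_rate must be >= 0")
  if (cfg$us_responder_fraction < 0 || cfg$us_responder_fraction > 1 ||
      cfg$visual_responder_fraction < 0 || cfg$visual_responder_fraction > 1)
    stop("responder fractions must lie in [0, 1]")
  class(cfg) <- "population_config"
  cfg
}

#' Per-trial ultrasound response probability at a given pressure
#'
#' Logistic dose curve, forced to zero at non-positive pressure (no
#' transmit). Used by the generator to plant pressure-dependent responders.
#'
#' @param pressure_kpa Peak negative pressure, kPa (vectorized).
#' @param config A [population_config()].
#' @return Probability in `[0, 1]`.
#' @export
us_response_probability <- function(pressure_kpa, config) {
  if (!is.null(config$us_response_prob)) {
    p <- rep(config$us_response_prob, length(pressure_kpa))
  } else {
    p <- config$response_prob_max *
      stats::plogis((pressure_kpa - config$pressure_p50) / config$pressure_slope)
  }
  p[pressure_kpa <= 0] <- 0
  p
}

# deterministic per-neuron substream seed from the master seed; fixed offset
# so that adding neurons never perturbs existing ones
neuron_seed <- function(master, i) {
  as.integer((as.numeric(master) + 7919 * as.numeric(i)) %% 2147483629)
}

# exact-count planting: k indices evenly spread over 1..n, avoiding `exclude`
plant_indices <- function(n, k, exclude = integer(0)) {
  if (k <= 0) return(integer(0))
  pool <- setdiff(seq_len(n), exclude)
  if (k > length(pool)) stop("not enough neurons left to plant responders")
  pool[unique(round(seq(1, length(pool), length.out = k)))]
}

#' Synthesize a multi-condition calcium-imaging session with ground truth
#'
#' Generates per-neuron ROI and background fluorescence traces at the raw
#' sampling rate for a session containing one block of stimulation trains per
#' protocol. Each trace is
#' `F0 * (1 + sum of transients) + neuropil_coef * background + noise`,
#' where transients are amplitude-scaled indicator kernels planted at
#' stimulus onsets (Bernoulli per trial, per the neuron's role) and at
#' spontaneous Poisson event times; the background is a slow bounded
#' oscillation plus offset. The same master seed always reproduces the same
#' session bit-for-bit, and per-neuron substreams are derived by fixed
#' offsets so traces of existing neurons do not change when `n_neurons`
#' grows.
#'
#' @param protocols A [stimulus_protocol()] or list of them, one per
#'   condition block (in session order).
#' @param config A [population_config()].
#' @param seed Integer master seed.
#' @return A list with `traces` (class `trace_set`: matrices `roi` and
#'   `background` of frames x neurons, `sampling_rate`, `time`, `onsets`,
#'   `condition`, `analyzed`, `seed`, `protocols`) and `ground_truth`
#'   (per-neuron roles, probabilities, amplitudes, the planted
#'   evoked-event draws, and spontaneous event bookkeeping).
#' @export
synthesize_traces <- function(protocols, config = population_config(), seed = 1) {
  if (inherits(protocols, "stimulus_protocol")) protocols <- list(protocols)
  stopifnot(length(protocols) >= 1)
  for (p in protocols) validate_protocol(p)
  fs <- config$sampling_rate
  n <- config$n_neurons

  # --- session layout: one block per protocol, concatenated ---------------
  onsets <- numeric(0); condition <- character(0); analyzed <- logical(0)
  cond_of_train <- integer(0)
  t0 <- 0
  for (ci in seq_along(protocols)) {
    p <- protocols[[ci]]
    block_len <- config$first_onset + p$n_trials * (p$sd_s + p$si_s) + 25 + config$tail_s
    sch <- build_stimulus_schedule(p, session_length = block_len,
                                   first_onset = config$first_onset)
    onsets <- c(onsets, t0 + sch$onsets)
    condition <- c(condition, rep(p$modality, length(sch$onsets)))
    analyzed <- c(analyzed, sch$analyzed)
    cond_of_train <- c(cond_of_train, rep(ci, length(sch$onsets)))
    t0 <- t0 + block_len
  }
  session_length <- t0
  n_frames <- floor(session_length * fs)
  tt <- (seq_len(n_frames) - 1) / fs
  n_trains <- length(onsets)

  # --- roles (exact counts, deterministic placement) ----------------------
  k_us <- round(config$us_responder_fraction * n)
  k_vn <- round(config$visual_responder_fraction * n)
  us_idx <- plant_indices(n, k_us)
  vn_idx <- plant_indices(n, k_vn, exclude = us_idx)
  modulation <- rep("none", n)
  if (k_vn > 0) {
    n_sup <- round(config$suppressed_frac * k_vn)
    n_enh <- round(config$enhanced_frac * k_vn)
    modulation[vn_idx[seq_len(n_sup)]] <- "suppressed"
    if (n_enh > 0) modulation[vn_idx[n_sup + seq_len(n_enh)]] <- "enhanced"
  }
  us_responder <- seq_len(n) %in% us_idx
  vis_responder <- seq_len(n) %in% vn_idx

  # per-condition, per-neuron response probability
  prob <- matrix(0, n, length(protocols))
  for (ci in seq_along(protocols)) {
    p <- protocols[[ci]]
    if (p$modality %in% c("ultrasound", "combined"))
      prob[us_responder, ci] <- us_response_probability(p$peak_negative_pressure, config)
    if (p$modality %in% c("visual", "combined"))
      prob[vis_responder, ci] <- config$visual_response_prob
  }

  # combined-condition amplitude gain for modulated visual responders
  gain_of <- function(i, ci) {
    if (protocols[[ci]]$modality != "combined" || !vis_responder[i]) return(1)
    switch(modulation[i], suppressed = config$gain_suppressed,
           enhanced = config$gain_enhanced, 1)
  }

  # --- indicator kernel sampled at the raw rate ---------------------------
  k_len <- ceiling(12 * config$tau_decay * fs / 10) * 10  # ~12 decay constants
  kern <- gcamp_kernel((seq_len(k_len)) / fs, config$tau_rise, config$tau_decay)

  meanlog_f0 <- log(config$f0_mean) - 0.5 * log(1 + config$f0_cv^2)
  sdlog_f0 <- sqrt(log(1 + config$f0_cv^2))

  roi <- matrix(0, n_frames, n)
  bg <- matrix(0, n_frames, n)
  f0 <- numeric(n)
  amp <- numeric(n)
  evoked <- matrix(FALSE, n, n_trains)
  n_spont <- integer(n)
  omega <- 2 * pi * tt

  add_transient <- function(sig, t_event, a) {
    # frame nearest the event time reads k(0) = 0; the rise starts after it
    i0 <- round(t_event * fs) + 1L
    if (i0 >= n_frames) return(sig)
    idx <- (i0 + 1L):min(i0 + k_len, n_frames)
    sig[idx] <- sig[idx] + a * kern[seq_along(idx)]
    sig
  }

  for (i in seq_len(n)) {
    set.seed(neuron_seed(seed, i))
    # fixed draw order per neuron (stable substream)
    f0[i] <- stats::rlnorm(1, meanlog_f0, sdlog_f0)
    bamp <- config$bg_amp * stats::runif(1, 1 - config$bg_amp_jitter, 1 + config$bg_amp_jitter)
    bfreq <- stats::runif(1, config$bg_freq_range[1], config$bg_freq_range[2])
    bphase <- stats::runif(1, 0, 2 * pi)
    amp[i] <- stats::rlnorm(1, config$amp_meanlog, config$amp_sdlog)
    u_evoked <- stats::runif(n_trains)
    m_spont <- stats::rpois(1, config$spontaneous_rate * session_length)
    t_spont <- sort(stats::runif(m_spont, 0, session_length))
    a_spont <- stats::rlnorm(max(m_spont, 0), config$amp_meanlog, config$amp_sdlog)
    noise <- if (config$noise_sd > 0) stats::rnorm(n_frames, 0, config$noise_sd) else 0

    sig <- numeric(n_frames)
    hit <- u_evoked < prob[i, cond_of_train]
    evoked[i, ] <- hit
    for (k in which(hit))
      sig <- add_transient(sig, onsets[k], amp[i] * gain_of(i, cond_of_train[k]))
    n_spont[i] <- m_spont
    if (m_spont > 0)
      for (k in seq_len(m_spont)) sig <- add_transient(sig, t_spont[k], a_spont[k])

    b <- config$bg_offset + bamp * sin(bfreq * omega + bphase)
    bg[, i] <- b
    roi[, i] <- f0[i] + f0[i] * sig + config$neuropil_coef * b + noise
  }

  traces <- structure(
    list(roi = roi, background = bg, sampling_rate = fs, time = tt,
         onsets = onsets, condition = condition, analyzed = analyzed,
         session_length = session_length, seed = seed, protocols = protocols),
    class = "trace_set")
  ground_truth <- list(
    us_responder = us_responder,
    visual_responder = vis_responder,
    modulation_class = modulation,
    response_probability = prob,
    response_amplitude = amp,
    f0 = f0,
    spontaneous_rate = config$spontaneous_rate,
    evoked_events = evoked,
    n_evoked = sum(evoked),
    n_spontaneous = n_spont,
    condition_of_train = cond_of_train,
    conditions = vapply(protocols, `[[`, "", "modality"))
  list(traces = traces, ground_truth = ground_truth)
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf(
    "<trace_set> %d neurons x %d frames @ %g Hz (%.1f s), %d trains (%d analyzed), conditions: %s\n",
    ncol(x$roi), nrow(x$roi), x$sampling_rate, x$session_length,
    length(x$onsets), sum(x$analyzed), paste(unique(x$condition), collapse = ", ")))
  invisible(x)
}

#' Write / read a trace set as CSV matrices plus a JSON sidecar
#'
#' `write_traceset()` stores `roi.csv` and `background.csv` (frames x
#' neurons) together with `meta.json` holding the sampling rate, onsets,
#' condition tags, analyzed flags, seed and a protocol echo;
#' `read_traceset()` restores the `trace_set`.
#'
#' @param traces A `trace_set`.
#' @param dir Output directory (created if missing).
#' @return `write_traceset()` returns `dir` invisibly; `read_traceset()`
#'   returns a `trace_set`.
#' @export
write_traceset <- function(traces, dir) {
  stopifnot(inherits(traces, "trace_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(traces$roi), file.path(dir, "roi.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(traces$background), file.path(dir, "background.csv"), row.names = FALSE)
  meta <- list(sampling_rate = traces$sampling_rate,
               onsets = traces$onsets,
               condition = traces$condition,
               analyzed = traces$analyzed,
               session_length = traces$session_length,
               seed = traces$seed,
               protocols = lapply(traces$protocols, unclass))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_traceset
#' @export
read_traceset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  roi <- as.matrix(utils::read.csv(file.path(dir, "roi.csv")))
  bg <- as.matrix(utils::read.csv(file.path(dir, "background.csv")))
  dimnames(roi) <- dimnames(bg) <- NULL
  protocols <- lapply(seq_len(nrow(meta$protocols)), function(i) {
    p <- as.list(meta$protocols[i, ])
    structure(p, class = "stimulus_protocol")
  })
  n_frames <- nrow(roi)
  structure(
    list(roi = roi, background = bg, sampling_rate = meta$sampling_rate,
         time = (seq_len(n_frames) - 1) / meta$sampling_rate,
         onsets = meta$onsets, condition = meta$condition,
         analyzed = meta$analyzed, session_length = meta$session_length,
         seed = meta$seed, protocols = protocols),
    class = "trace_set")
}

#' Write generator ground truth to JSON
#'
#' @param ground_truth The `ground_truth` element returned by
#'   [synthesize_traces()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
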