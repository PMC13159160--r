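#' Define an ultrasound (or visual/sham) stimulation protocol
#'
#' A stimulus protocol bundles all acoustic and timing parameters of one
#' stimulation condition: a train of `pulses` of duration `pd` repeated at
#' `prf` within a stimulation window of length `sd`, the whole train repeated
#' every `sd + si` seconds for `n_trials + 1` deliveries (the first delivery
#' carries no recorded pre-stimulus baseline and is discarded from analysis).
#'
#' Defaults are the standard low-intensity neuromodulation condition used
#' throughout this package: 1 MHz carrier, 10 Hz PRF, 50 ms pulses with 25 ms
#' sine ramps, 0.5 s trains repeated every 30 s, 9 analyzed trials.
#'
#' @param center_frequency Carrier frequency in MHz.
#' @param peak_negative_pressure Peak negative pressure at focus, kPa.
#' @param prf Pulse repetition frequency within a train, Hz.
#' @param pd Pulse duration, ms.
#' @param rd Ramp duration of the rise/fall of each pulse, ms. Must satisfy
#'   `2 * rd <= pd`.
#' @param sd_s Stimulation duration (train length), s.
#' @param si_s Stimulation interval between trains (off time), s.
#' @param n_trials Number of analyzed trials. One extra leading train is
#'   always scheduled and flagged invalid.
#' @param modality One of `"ultrasound"`, `"visual"`, `"combined"`, `"sham"`.
#'
#' @return An object of class `stimulus_protocol` (a validated list). The
#'   pulse repetition interval `pri` (ms) is derived as `1000 / prf`.
#' @examples
#' p <- stimulus_protocol(peak_negative_pressure = 450)
#' p$pri  # 100 ms
#' @export
stimulus_protocol <- function(center_frequency = 1,
                              peak_negative_pressure = 450,
                              prf = 10,
                              pd = 50,
                              rd = 25,
                              sd_s = 0.5,
                              si_s = 30,
                              n_trials = 9,
                              modality = c("ultrasound", "visual", "combined", "sham")) {
  modality <- match.arg(modality)
  proto <- structure(
    list(center_frequency = center_frequency,
         peak_negative_pressure = peak_negative_pressure,
         prf = prf, pd = pd, pri = 1000 / prf, rd = rd,
         sd_s = sd_s, si_s = si_s, n_trials = as.integer(n_trials),
         modality = modality),
    class = "stimulus_protocol")
  validate_protocol(proto)
  proto
}

validate_protocol <- function(p) {
  stopifnot(inherits(p, "stimulus_protocol"))
  if (p$center_frequency <= 0) stop("center_frequency must be > 0")
  if (p$peak_negative_pressure < 0) stop("pressure must be >= 0")
  if (p$prf <= 0) stop("prf must be > 0")
  if (abs(p$prf * p$pri - 1000) > 1e-9) stop("prf and pri are inconsistent")
  if (p$pd > p$pri) stop("pulse duration exceeds pulse repetition interval")
  if (2 * p$rd > p$pd) stop("ramps do not fit inside the pulse (2*rd > pd)")
  if (p$sd_s > p$si_s) stop("stimulation duration exceeds stimulation interval")
  if (p$n_trials < 1) stop("need at least one analyzed trial")
  invisible(p)
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf(
    "<stimulus_protocol> %s | %g MHz, %g kPa | PRF %g Hz, PD %g ms, RD %g ms | SD %g s, SI %g s | %d analyzed trials\n",
    x$modality, x$center_frequency, x$peak_negative_pressure,
    x$prf, x$pd, x$rd, x$sd_s, x$si_s, x$n_trials))
  invisible(x)
}

#' Number of complete pulses inside one stimulation train
#'
#' Pulses start at multiples of the pulse repetition interval; a pulse counts
#' only if it finishes inside the train, so the count is
#' `floor((sd - pd) / pri) + 1` when `sd >= pd` and zero otherwise.
#' With PRF 10 Hz, PD 50 ms and SD 0.5 s this gives 5 pulses.
#'
#' @param protocol A [stimulus_protocol()].
#' @return Integer pulse count per train.
#' @export
pulses_per_train <- function(protocol) {
  validate_protocol(protocol)
  sd_ms <- protocol$sd_s * 1000
  if (sd_ms < protocol$pd) return(0L)
  as.integer(floor((sd_ms - protocol$pd) / protocol$pri) + 1L)
}

#' Build the train-onset schedule of a session
#'
#' Lays out `n_trials + 1` train onsets spaced by `sd + si` seconds starting
#' at `first_onset`. The first train is flagged invalid (no recorded baseline
#' precedes it) and is excluded from analysis downstream; the remaining
#' `n_trials` onsets are the analyzed trials.
#'
#' @param protocol A [stimulus_protocol()].
#' @param session_length Total session duration, s.
#' @param first_onset Time of the first (invalid) train onset, s. Must be at
#'   least 5 s so that even the first analyzed epoch has a full baseline.
#' @return A list with `onsets` (s), logical `analyzed` flags, `period` (s),
#'   `n_pulses` per train, and `pulse_starts` (s, within-train pulse onset
#'   offsets).
#' @examples
#' build_stimulus_schedule(stimulus_protocol(), session_length = 330)
#' @export
build_stimulus_schedule <- function(protocol, session_length,
                                    first_onset = 10) {
  validate_protocol(protocol)
  if (first_onset < 5) stop("first_onset must be >= 5 s")
  period <- protocol$sd_s + protocol$si_s
  n_trains <- protocol$n_trials + 1L
  onsets <- first_onset + (seq_len(n_trains) - 1L) * period
  last_end <- onsets[n_trains] + 25  # full post-stimulus window must fit
  if (last_end > session_length) {
    stop(sprintf(
      "schedule overflow: session of %g s too short for %d trains every %g s (needs %g s)",
      session_length, n_trains, period, last_end))
  }
  npul <- pulses_per_train(protocol)
  list(onsets = onsets,
       analyzed = c(FALSE, rep(TRUE, protocol$n_trials)),
       period = period,
       n_pulses = npul,
       pulse_starts = if (npul > 0) (seq_len(npul) - 1L) * protocol$pri / 1000 else numeric(0))
}

#' Quarter-sine ramp envelope of a single pulse
#'
#' Amplitude fraction of the smoothed pulse at time `t_ms` after pulse onset:
#' `sin(pi * t / (2 * rd))` on the rising ramp, 1 on the plateau
#' `[rd, pd - rd]`, and the mirrored quarter-sine on the fall. With the
#' default 50 ms pulse and 25 ms ramps the plateau has zero length, i.e. the
#' pulse is a full half-sine window.
#'
#' @param t_ms Time within the pulse, ms (vectorized). Values outside
#'   `[0, pd]` are an error.
#' @param protocol A [stimulus_protocol()].
#' @return Amplitude fraction in `[0, 1]`.
#' @examples
#' ramp_envelope(c(0, 12.5, 25, 50), stimulus_protocol())
#' @export
ramp_envelope <- function(t_ms, protocol) {
  validate_protocol(protocol)
  pd <- protocol$pd; rd <- protocol$rd
  if (any(t_ms < 0 | t_ms > pd)) stop("t_ms outside the pulse [0, pd]")
  env <- rep(1, length(t_ms))
  if (rd > 0) {
    rise <- t_ms < rd
    fall <- t_ms > pd - rd
    env[rise] <- sin(pi * t_ms[rise] / (2 * rd))
    env[fall] <- sin(pi * (pd - t_ms[fall]) / (2 * rd))
  }
  env
}
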