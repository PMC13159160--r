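#' Analysis configuration for epoching and classification
#'
#' Houses the windows and thresholds of the trace pipeline. Time windows are
#' in seconds relative to stimulus onset. Baseline-type windows are half-open
#' on the right (`[lo, hi)`), response-type windows half-open on the left
#' (`(lo, hi]`), so the onset frame itself belongs to neither.
#'
#' @param pre_s,post_s Epoch extent: seconds before / after onset.
#' @param baseline_window Window for the dF/F baseline F0 and the z-score
#'   mean/SD, default the full 5 s pre-stimulus.
#' @param response_window Window searched for evoked responses, default 0-3 s.
#' @param pre_window Window screened for pre-stimulus excitation, default
#'   -3-0 s.
#' @param excited_threshold z-score threshold; a trial is excited when the
#'   maximum z in the response window strictly exceeds it.
#' @param un_rate_threshold Response-rate threshold: strictly above it a
#'   neuron is a robust responder (UN/VN), in (0, threshold] a weak responder.
#' @param frame_average_factor Raw frames averaged per analysis frame
#'   (30 Hz -> 3 Hz with the default 10).
#' @param zscore_basis `"dff"` (z of dF/F; default) or `"raw"` (z of raw F,
#'   for heatmap parity).
#' @param zscore_scope `"epoch"` (baseline statistics per epoch; default) or
#'   `"session"` (per-neuron statistics pooled over all analyzed baselines).
#' @param exclusion_mode `"trial"` (a pre-excited trial is dropped from both
#'   numerator and denominator; default) or `"neuron"` (any pre-excited trial
#'   marks the whole neuron unclassifiable).
#' @param modulation_rule `"welch"` (per-neuron two-sided Welch test on
#'   per-trial response maxima, default) or `"log2gain"` (pure effect-size
#'   rule).
#' @param modulation_alpha Significance level of the Welch rule.
#' @param log2gain_threshold |log2 gain| needed by the effect-size rule.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(pre_s = 5, post_s = 25,
                            baseline_window = c(-5, 0),
                            response_window = c(0, 3),
                            pre_window = c(-3, 0),
                            excited_threshold = 2,
                            un_rate_threshold = 0.30,
                            frame_average_factor = 10,
                            zscore_basis = c("dff", "raw"),
                            zscore_scope = c("epoch", "session"),
                            exclusion_mode = c("trial", "neuron"),
                            modulation_rule = c("welch", "log2gain"),
                            modulation_alpha = 0.05,
                            log2gain_threshold = 0.585) {
  cfg <- list(pre_s = pre_s, post_s = post_s,
              baseline_window = baseline_window,
              response_window = response_window,
              pre_window = pre_window,
              excited_threshold = excited_threshold,
              un_rate_threshold = un_rate_threshold,
              frame_average_factor = as.integer(frame_average_factor),
              zscore_basis = match.arg(zscore_basis),
              zscore_scope = match.arg(zscore_scope),
              exclusion_mode = match.arg(exclusion_mode),
              modulation_rule = match.arg(modulation_rule),
              modulation_alpha = modulation_alpha,
              log2gain_threshold = log2gain_threshold)
  if (cfg$excited_threshold <= 0 || cfg$un_rate_threshold <= 0)
    stop("thresholds must be positive")
  if (cfg$frame_average_factor < 1) stop("frame_average_factor must be >= 1")
  win_ok <- function(w) w[1] >= -cfg$pre_s && w[2] <= cfg$post_s && w[1] < w[2]
  if (!win_ok(cfg$baseline_window) || !win_ok(cfg$response_window) ||
      !win_ok(cfg$pre_window))
    stop("analysis windows must lie inside the epoch")
  class(cfg) <- "analysis_config"
  cfg
}

#' Subtract the background trace from the ROI trace
#'
#' Elementwise difference `roi - background`. Accepts a `trace_set` (uses its
#' two matrices) or any pair of equal-shaped vectors/matrices.
#'
#' @param roi A `trace_set`, or ROI fluorescence (frames x neurons or vector).
#' @param background Background fluorescence, same shape as `roi` (ignored
#'   when `roi` is a `trace_set`).
#' @return Corrected fluorescence, same shape.
#' @export
subtract_background <- function(roi, background = NULL) {
  if (inherits(roi, "trace_set")) return(roi$roi - roi$background)
  if (is.null(background)) stop("background required")
  if (!identical(dim(roi), dim(background)) || length(roi) != length(background))
    stop("roi and background shapes differ")
  roi - background
}

#' Block-average frames to a lower rate
#'
#' Each output sample is the arithmetic mean of `factor` consecutive input
#' frames (acquisition-block averaging, e.g. 30 Hz -> 3 Hz with factor 10).
#' A trailing remainder of fewer than `factor` frames is dropped.
#'
#' @param x Trace vector or frames x neurons matrix.
#' @param factor Positive integer block size.
#' @return Averaged trace(s) at `rate / factor`.
#' @examples
#' average_frames(1:30, 10)  # 5.5 15.5 25.5
#' @export
average_frames <- function(x, factor) {
  if (factor <= 0) stop("factor must be positive")
  factor <- as.integer(factor)
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n_out <- nrow(x) %/% factor
  if (n_out == 0) stop("fewer frames than one averaging block")
  x <- x[seq_len(n_out * factor), , drop = FALSE]
  # fold each column into blocks of `factor` consecutive frames and average
  cm <- .colMeans(x, factor, n_out * ncol(x))
  out <- matrix(cm, n_out, ncol(x))
  if (vec) as.numeric(out) else out
}

# frame indices of a window within an epoch; `type` fixes the open end
window_frames <- function(n_frames, sampling_rate, pre_s, window,
                          type = c("baseline", "response")) {
  type <- match.arg(type)
  t_rel <- (seq_len(n_frames) - 1) / sampling_rate - pre_s
  eps <- 1e-9
  if (type == "baseline") {
    which(t_rel >= window[1] - eps & t_rel < window[2] - eps)
  } else {
    which(t_rel > window[1] + eps & t_rel <= window[2] + eps)
  }
}

new_epoch_tensor <- function(values, units, config, sampling_rate, condition,
                             valid = NULL, misalign = NULL) {
  stopifnot(length(dim(values)) == 3)
  if (is.null(valid)) valid <- matrix(TRUE, dim(values)[1], dim(values)[2])
  structure(list(values = values, units = units,
                 window = c(pre_s = config$pre_s, post_s = config$post_s),
                 sampling_rate = sampling_rate, condition = condition,
                 valid = valid, misalign = misalign),
            class = "epoch_tensor")
}

#' @export
print.epoch_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<epoch_tensor> %s | %d neurons x %d trials x %d frames @ %g Hz | window -%g/+%g s | condition %s\n",
    x$units, d[1], d[2], d[3], x$sampling_rate, x$window[1], x$window[2],
    x$condition %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cut peri-stimulus epochs out of corrected traces
#'
#' Aligns each analyzed onset to its nearest frame and extracts the
#' `[-pre_s, +post_s)` window: `round((pre_s + post_s) * rate)` frames with
#' the onset landing at frame index `pre_s * rate + 1`. Onsets whose window
#' would be truncated raise an error naming the offending onset.
#'
#' @param traces Corrected trace matrix (frames x neurons) at the analysis
#'   rate (after [average_frames()]).
#' @param onsets Stimulus onset times, s.
#' @param sampling_rate Frame rate of `traces`, Hz.
#' @param config An [analysis_config()].
#' @param condition Optional condition label carried in the tensor.
#' @return An `epoch_tensor` in `raw_F` units (neurons x trials x frames),
#'   with the worst onset/frame misalignment (s) recorded.
#' @export
epoch_traces <- function(traces, onsets, sampling_rate,
                         config = analysis_config(), condition = NULL) {
  if (is.null(dim(traces))) traces <- matrix(traces, ncol = 1)
  n_frames_total <- nrow(traces)
  n_pre <- round(config$pre_s * sampling_rate)
  n_post <- round(config$post_s * sampling_rate)
  n_ep <- n_pre + n_post
  n <- ncol(traces)
  vals <- array(NA_real_, c(n, length(onsets), n_ep))
  mis <- 0
  for (j in seq_along(onsets)) {
    i0 <- round(onsets[j] * sampling_rate) + 1L
    mis <- max(mis, abs((i0 - 1) / sampling_rate - onsets[j]))
    lo <- i0 - n_pre; hi <- i0 + n_post - 1L
    if (lo < 1 || hi > n_frames_total)
      stop(sprintf("epoch truncated for onset at %g s", onsets[j]))
    vals[, j, ] <- t(traces[lo:hi, , drop = FALSE])
  }
  new_epoch_tensor(vals, "raw_F", config, sampling_rate, condition,
                   misalign = mis)
}

# flatten (neurons x trials x frames) to (neuron-trial rows x frames)
et_matrix <- function(et) {
  d <- dim(et$values)
  matrix(et$values, d[1] * d[2], d[3])
}

#' Compute dF/F per epoch
#'
#' `dF/F(t) = (F(t) - F0) / F0` with `F0` the mean of the baseline-window
#' frames of that same epoch. Requires `raw_F` input (the units field rejects
#' re-application) and a strictly positive baseline.
#'
#' @param et An `epoch_tensor` in `raw_F` units.
#' @param config An [analysis_config()].
#' @return An `epoch_tensor` in `dff` units.
#' @export
compute_dff <- function(et, config = analysis_config()) {
  stopifnot(inherits(et, "epoch_tensor"))
  if (et$units != "raw_F")
    stop(sprintf("compute_dff expects raw_F input, got '%s'", et$units))
  d <- dim(et$values)
  bl <- window_frames(d[3], et$sampling_rate, et$window[1],
                      config$baseline_window, "baseline")
  m <- et_matrix(et)
  f0 <- rowMeans(m[, bl, drop = FALSE])
  if (any(f0 <= 0, na.rm = TRUE))
    stop("degenerate baseline: F0 <= 0 in at least one epoch")
  dff <- (m - f0) / f0
  out <- et
  out$values <- array(dff, d)
  out$units <- "dff"
  out
}

#' z-score epochs against their baseline
#'
#' `z(t) = (x(t) - mu) / sigma` with `mu`, `sigma` the mean and SD of the
#' baseline-window frames. With `zscore_scope = "epoch"` (default) the
#' statistics come from each epoch's own baseline; with `"session"` they are
#' pooled per neuron over all its epochs' baselines. Epochs with zero
#' baseline SD are not an error: they are flagged invalid (all-NA z) and
#' excluded downstream.
#'
#' @param et An `epoch_tensor` in `dff` units (or `raw_F` when
#'   `zscore_basis = "raw"`).
#' @param config An [analysis_config()].
#' @return An `epoch_tensor` in `zscored` units with a `valid`
#'   neurons x trials mask.
#' @export
zscore_epochs <- function(et, config = analysis_config()) {
  stopifnot(inherits(et, "epoch_tensor"))
  want <- if (config$zscore_basis == "dff") "dff" else "raw_F"
  if (et$units != want)
    stop(sprintf("zscore_epochs expects '%s' input, got '%s'", want, et$units))
  d <- dim(et$values)
  bl <- window_frames(d[3], et$sampling_rate, et$window[1],
                      config$baseline_window, "baseline")
  m <- et_matrix(et)
  b <- m[, bl, drop = FALSE]
  if (config$zscore_scope == "epoch") {
    mu <- rowMeans(b)
    s <- sqrt(rowSums((b - mu)^2) / (length(bl) - 1))
  } else {
    # pooled per neuron across trials: reshape baselines to neurons x (trials*frames)
    bb <- matrix(aperm(array(b, c(d[1], d[2], length(bl))), c(1, 3, 2)),
                 d[1], d[2] * length(bl))
    mu_n <- rowMeans(bb)
    s_n <- apply(bb, 1, stats::sd)
    mu <- rep(mu_n, times = d[2])
    s <- rep(s_n, times = d[2])
  }
  bad <- !is.finite(s) | s == 0
  s[bad] <- NA_real_
  z <- (m - mu) / s
  out <- et
  out$values <- array(z, d)
  out$units <- "zscored"
  out$valid <- et$valid & matrix(!bad, d[1], d[2])
  out
}

#' Round-trip an epoch tensor to a directory of CSVs plus a JSON manifest
#'
#' One CSV per trial (neurons x frames) and a manifest recording units,
#' window, sampling rate, condition, validity mask and a hash of the values.
#'
#' @param et An `epoch_tensor`.
#' @param dir Output directory.
#' @return `write_epochs()` returns `dir` invisibly; `read_epochs()` the
#'   restored `epoch_tensor`.
#' @export
write_epochs <- function(et, dir) {
  stopifnot(inherits(et, "epoch_tensor"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(et$values)
  for (j in seq_len(d[2])) {
    utils::write.csv(as.data.frame(et$values[, j, ]),
                     file.path(dir, sprintf("trial_%03d.csv", j)),
                     row.names = FALSE)
  }
  manifest <- list(units = et$units, window = as.list(et$window),
                   sampling_rate = et$sampling_rate,
                   condition = et$condition, n_trials = d[2],
                   n_neurons = d[1], n_frames = d[3],
                   valid = et$valid,
                   misalign = et$misalign)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  vals <- array(NA_real_, c(man$n_neurons, man$n_trials, man$n_frames))
  for (j in seq_len(man$n_trials)) {
    vals[, j, ] <- as.matrix(utils::read.csv(
      file.path(dir, sprintf("trial_%03d.csv", j))))
  }
  structure(list(values = vals, units = man$units,
                 window = c(pre_s = man$window$pre_s, post_s = man$window$post_s),
                 sampling_rate = man$sampling_rate,
                 condition = man$condition,
                 valid = matrix(man$valid, man$n_neurons, man$n_trials),
                 misalign = man$misalign),
            class = "epoch_tensor")
}
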