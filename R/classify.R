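#' Detect excited trials
#'
#' A neuron-trial is excited when the maximum z-scored signal over the
#' response window (default 0-3 s post-onset, half-open on the left)
#' strictly exceeds the threshold (default 2). Invalid trials (flagged by
#' [zscore_epochs()]) return `NA` and are excluded downstream.
#'
#' @param et_z An `epoch_tensor` in `zscored` units.
#' @param config An [analysis_config()].
#' @return Logical neurons x trials matrix (`NA` for invalid trials).
#' @export
detect_excited_trials <- function(et_z, config = analysis_config()) {
  stopifnot(inherits(et_z, "epoch_tensor"))
  if (et_z$units != "zscored") stop("detect_excited_trials expects zscored input")
  window_max(et_z, config$response_window, "response") > config$excited_threshold
}

#' Flag trials already excited before stimulus onset
#'
#' A neuron-trial is pre-excited when the maximum z over the pre-window
#' (default -3-0 s, half-open on the right) exceeds the excited threshold.
#' Such trials are excluded so the remaining responses are more likely
#' directly stimulus-driven.
#'
#' @inheritParams detect_excited_trials
#' @return Logical neurons x trials matrix (`NA` for invalid trials).
#' @export
flag_pre_excited <- function(et_z, config = analysis_config()) {
  stopifnot(inherits(et_z, "epoch_tensor"))
  if (et_z$units != "zscored") stop("flag_pre_excited expects zscored input")
  window_max(et_z, config$pre_window, "baseline") > config$excited_threshold
}

# per neuron-trial maximum over a window; NA where the trial is invalid
window_max <- function(et, window, type) {
  d <- dim(et$values)
  idx <- window_frames(d[3], et$sampling_rate, et$window[1], window, type)
  if (length(idx) == 0) stop("empty window")
  m <- et_matrix(et)[, idx, drop = FALSE]
  mx <- matrix(do.call(pmax, c(as.data.frame(m), na.rm = FALSE)), d[1], d[2])
  mx[!et$valid] <- NA_real_
  mx
}

#' Response rate over non-excluded trials
#'
#' `rate = excited count / non-excluded trial count`, computed per neuron.
#' Neurons with no usable trial left are unclassifiable (`NA` rate).
#'
#' @param excited Logical neurons x trials matrix from
#'   [detect_excited_trials()].
#' @param excluded Logical neurons x trials matrix of trials to drop
#'   (pre-excited and/or invalid).
#' @return A data.frame with `n_excited`, `n_valid` and `rate` per neuron.
#' @export
response_rate <- function(excited, excluded = NULL) {
  if (is.null(dim(excited))) excited <- matrix(excited, nrow = 1)
  if (is.null(excluded)) excluded <- matrix(FALSE, nrow(excited), ncol(excited))
  excluded <- excluded | is.na(excited)
  use <- !excluded
  n_valid <- rowSums(use)
  n_exc <- rowSums(excited & use, na.rm = TRUE)
  rate <- ifelse(n_valid > 0, n_exc / n_valid, NA_real_)
  data.frame(n_excited = n_exc, n_valid = n_valid, rate = rate)
}

# rate -> class, strict ">" at the rate threshold
rate_class <- function(rate, threshold) {
  cls <- rep("non_responsive", length(rate))
  cls[!is.na(rate) & rate > 0 & rate <= threshold] <- "weak"
  cls[!is.na(rate) & rate > threshold] <- "responder"
  cls[is.na(rate)] <- "unclassifiable"
  cls
}

#' Preprocess one condition of a session into aligned z-scored epochs
#'
#' Runs the standard chain on a `trace_set` for the analyzed onsets of one
#' condition: background subtraction, frame averaging, epoching, dF/F and
#' baseline z-scoring.
#'
#' @param traces A `trace_set` from [synthesize_traces()] or
#'   [read_traceset()].
#' @param condition Condition label to analyze (must be present in
#'   `traces$condition`).
#' @param config An [analysis_config()].
#' @return A list with `raw` (epoch tensor, raw_F), `dff`, and `z`.
#' @export
preprocess_condition <- function(traces, condition,
                                 config = analysis_config()) {
  stopifnot(inherits(traces, "trace_set"))
  keep <- traces$condition == condition & traces$analyzed
  if (!any(keep)) stop(sprintf("no analyzed onsets for condition '%s'", condition))
  corrected <- subtract_background(traces)
  avg <- average_frames(corrected, config$frame_average_factor)
  fs <- traces$sampling_rate / config$frame_average_factor
  raw_et <- epoch_traces(avg, traces$onsets[keep], fs, config, condition)
  dff <- compute_dff(raw_et, config)
  z <- zscore_epochs(if (config$zscore_basis == "dff") dff else raw_et, config)
  list(raw = raw_et, dff = dff, z = z)
}

#' Classify a population into robust / weak / non-responsive neurons
#'
#' For each condition: detect excited trials, drop pre-excited (and invalid)
#' trials, compute response rates, and label neurons as robust responders
#' (rate strictly above the threshold; UNs under ultrasound, VNs under visual
#' stimulation), weak responders (rate in (0, threshold]; NUNs/NVNs), or
#' non-responsive. With `exclusion_mode = "neuron"` any pre-excited trial
#' makes the neuron unclassifiable for that condition instead.
#'
#' @param z_by_condition Named list of `zscored` epoch tensors, one per
#'   condition (e.g. from [preprocess_condition()]).
#' @param config An [analysis_config()].
#' @return An object of class `neuron_labels`: a long data.frame
#'   (`neuron`, `condition`, `n_excited`, `n_valid`, `rate`, `class`) with
#'   the per-neuron-trial exclusion masks in `attr(, "excluded")`.
#' @export
classify_population <- function(z_by_condition, config = analysis_config()) {
  stopifnot(is.list(z_by_condition), length(z_by_condition) >= 1,
            !is.null(names(z_by_condition)))
  out <- list(); excl_masks <- list()
  for (cond in names(z_by_condition)) {
    et <- z_by_condition[[cond]]
    exc <- detect_excited_trials(et, config)
    pre <- flag_pre_excited(et, config)
    drop <- (pre & !is.na(pre)) | is.na(exc)
    if (config$exclusion_mode == "neuron") {
      bad_neuron <- rowSums(drop) > 0
      drop[bad_neuron, ] <- TRUE
    }
    rr <- response_rate(exc, drop)
    rr$neuron <- seq_len(nrow(rr))
    rr$condition <- cond
    rr$class <- rate_class(rr$rate, config$un_rate_threshold)
    out[[cond]] <- rr[, c("neuron", "condition", "n_excited", "n_valid",
                          "rate", "class")]
    excl_masks[[cond]] <- drop
  }
  labels <- do.call(rbind, out)
  rownames(labels) <- NULL
  structure(labels, excluded = excl_masks, class = c("neuron_labels", "data.frame"))
}

#' Logical responder flags for one condition
#'
#' @param labels A `neuron_labels` object.
#' @param condition Condition label.
#' @param which `"responder"` (UN/VN), `"weak"` (NUN/NVN) or any class name.
#' @return Logical vector over neurons.
#' @export
responder_flags <- function(labels, condition, which = "responder") {
  sub <- labels[labels$condition == condition, ]
  sub <- sub[order(sub$neuron), ]
  sub$class == which
}

#' Venn counts of two neuron sets
#'
#' @param set_a,set_b Logical vectors over the same neuron index space.
#' @return Named integer vector `c(a_only, b_only, both)`.
#' @export
overlap_sets <- function(set_a, set_b) {
  if (length(set_a) != length(set_b))
    stop("neuron index spaces differ")
  c(a_only = sum(set_a & !set_b),
    b_only = sum(!set_a & set_b),
    both = sum(set_a & set_b))
}

#' Subgroup visual responders by ultrasound modulation
#'
#' Compares each visual responder's per-trial response maxima (dF/F over the
#' response window) between the visual-only and the combined
#' visual+ultrasound condition. With the default Welch rule, a two-sided
#' two-sample t-test at `modulation_alpha` assigns: significant decrease
#' under ultrasound -> inhibited (VNs2), significant increase -> excited
#' (VNs3), otherwise unchanged (VNs1). The `log2gain` rule instead thresholds
#' `|log2(mean_combined / mean_visual)|`. Neurons with fewer than 2 valid
#' trials in either condition are reported `not_vn` with a warning.
#'
#' @param dff_visual,dff_combined `dff` epoch tensors of the two conditions
#'   (same neuron space).
#' @param vn_flag Logical vector: which neurons are visual responders.
#' @param config An [analysis_config()].
#' @return Character vector per neuron: `"VNs1"`, `"VNs2"`, `"VNs3"` or
#'   `"not_vn"`.
#' @export
classify_modulation <- function(dff_visual, dff_combined, vn_flag,
                                config = analysis_config()) {
  stopifnot(inherits(dff_visual, "epoch_tensor"),
            inherits(dff_combined, "epoch_tensor"))
  if (dff_visual$units != "dff" || dff_combined$units != "dff")
    stop("classify_modulation expects dff tensors")
  mx_v <- window_max(dff_visual, config$response_window, "response")
  mx_c <- window_max(dff_combined, config$response_window, "response")
  n <- nrow(mx_v)
  out <- rep("not_vn", n)
  short <- 0L
  for (i in which(vn_flag)) {
    a <- mx_v[i, ]; a <- a[is.finite(a)]
    b <- mx_c[i, ]; b <- b[is.finite(b)]
    if (length(a) < 2 || length(b) < 2) { short <- short + 1L; next }
    if (config$modulation_rule == "welch") {
      if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        out[i] <- if (isTRUE(all.equal(mean(a), mean(b)))) "VNs1"
                  else if (mean(b) < mean(a)) "VNs2" else "VNs3"
        next
      }
      tt <- stats::t.test(b, a, alternative = "two.sided")
      out[i] <- if (tt$p.value >= config$modulation_alpha) "VNs1"
                else if (mean(b) < mean(a)) "VNs2" else "VNs3"
    } else {
      lg <- log2(mean(b) / mean(a))
      out[i] <- if (!is.finite(lg) || abs(lg) <= config$log2gain_threshold) "VNs1"
                else if (lg < 0) "VNs2" else "VNs3"
    }
  }
  if (short > 0)
    warning(sprintf("%d visual responder(s) had <2 valid trials in a condition; reported not_vn", short))
  out
}
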