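#' Per-trial window maxima with group mean and SEM
#'
#' Takes each neuron-trial's maximum over a time window (response-type
#' half-open `(lo, hi]`) and summarizes across trials: the standard
#' "maximum response in 0-3 s" statistic of evoked-response figures.
#'
#' @param et An `epoch_tensor` (any units).
#' @param window Window in s relative to onset, default the response window.
#' @param config An [analysis_config()].
#' @return A list with `maxima` (neurons x trials), `mean`, `sem` (grand
#'   mean and SEM over all finite neuron-trial maxima), and per-trial means.
#' @export
window_max_summary <- function(et, window = NULL,
                               config = analysis_config()) {
  stopifnot(inherits(et, "epoch_tensor"))
  if (is.null(window)) window <- config$response_window
  mx <- window_max(et, window, "response")
  v <- mx[is.finite(mx)]
  list(maxima = mx,
       mean = mean(v),
       sem = stats::sd(v) / sqrt(length(v)),
       trial_mean = colMeans(mx, na.rm = TRUE))
}

#' Significance stars
#'
#' @param p P-value(s).
#' @return `"****"`, `"***"`, `"**"`, `"*"` or `"ns"` per the usual
#'   p < 0.0001/0.001/0.01/0.05 convention.
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

#' Compare groups: two-tailed t-test or one-way ANOVA with Tukey post hoc
#'
#' Two groups are compared by a two-tailed two-sample t-test (Welch by
#' default); three or more by one-way ANOVA followed by Tukey's honest
#' significant differences for all pairs. Each group needs at least two
#' values.
#'
#' @param values_by_group Named list of numeric vectors.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return A list with `design` (`"two_group"` or `"multi_group"`), group
#'   `means` and `sems`, and a `comparisons` data.frame (`group1`, `group2`,
#'   `statistic` (t or ANOVA F), `p`, `stars`).
#' @export
compare_groups <- function(values_by_group, var_equal = FALSE) {
  stopifnot(is.list(values_by_group), length(values_by_group) >= 2,
            !is.null(names(values_by_group)))
  ns <- vapply(values_by_group, length, 1L)
  if (any(ns < 2)) stop("every group needs at least 2 values")
  means <- vapply(values_by_group, mean, 1)
  sems <- vapply(values_by_group, function(v) stats::sd(v) / sqrt(length(v)), 1)
  gn <- names(values_by_group)
  if (length(values_by_group) == 2) {
    tt <- stats::t.test(values_by_group[[1]], values_by_group[[2]],
                        var.equal = var_equal)
    comparisons <- data.frame(group1 = gn[1], group2 = gn[2],
                              statistic = unname(tt$statistic),
                              p = tt$p.value,
                              stars = significance_stars(tt$p.value))
    design <- "two_group"
  } else {
    df <- data.frame(
      value = unlist(values_by_group, use.names = FALSE),
      group = factor(rep(gn, times = ns), levels = gn))
    fit <- stats::aov(value ~ group, data = df)
    fstat <- summary(fit)[[1]]$`F value`[1]
    tk <- stats::TukeyHSD(fit)$group
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    comparisons <- data.frame(
      group1 = vapply(pairs, `[`, "", 2),
      group2 = vapply(pairs, `[`, "", 1),
      statistic = fstat,
      p = tk[, "p adj"],
      stars = significance_stars(tk[, "p adj"]))
    rownames(comparisons) <- NULL
    design <- "multi_group"
  }
  list(design = design, means = means, sems = sems, comparisons = comparisons)
}

#' Class proportions of a labeled population, in percent
#'
#' @param labels A `neuron_labels` object from [classify_population()].
#' @param condition Condition label to tabulate.
#' @return Named numeric vector of percentages over
#'   responder/weak/non_responsive/unclassifiable (sums to 100).
#' @export
class_proportions <- function(labels, condition) {
  sub <- labels[labels$condition == condition, ]
  lv <- c("responder", "weak", "non_responsive", "unclassifiable")
  out <- 100 * table(factor(sub$class, levels = lv)) / nrow(sub)
  stats::setNames(as.numeric(out), lv)
}

#' Render standard figures and tables for a classified session
#'
#' Writes deterministic artifacts for one analyzed condition: a z-score
#' heatmap of the robust responders (trial-averaged, neurons x time), the
#' population mean trace, a labels CSV, class-proportion CSV and Venn counts
#' against a second neuron set if given. Empty classes render annotated
#' empty panels rather than failing.
#'
#' @param labels A `neuron_labels` object.
#' @param z_et The matching `zscored` epoch tensor.
#' @param condition Condition to render.
#' @param dir Output directory.
#' @param other_set Optional logical vector (e.g. visual responders) for a
#'   Venn-count table.
#' @return Invisibly, the vector of files written.
#' @export
render_outputs <- function(labels, z_et, condition, dir,
                           other_set = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  sub <- labels[labels$condition == condition, ]
  sub <- sub[order(sub$neuron), ]

  f <- file.path(dir, sprintf("labels_%s.csv", condition))
  utils::write.csv(sub, f, row.names = FALSE)
  files <- c(files, f)

  f <- file.path(dir, sprintf("proportions_%s.csv", condition))
  pr <- class_proportions(labels, condition)
  utils::write.csv(data.frame(class = names(pr), percent = as.numeric(pr)),
                   f, row.names = FALSE)
  files <- c(files, f)

  resp <- which(sub$class == "responder")
  tavg <- apply(z_et$values, c(1, 3), mean, na.rm = TRUE)  # neurons x frames
  t_rel <- (seq_len(dim(z_et$values)[3]) - 1) / z_et$sampling_rate - z_et$window[1]

  f <- file.path(dir, sprintf("heatmap_%s.png", condition))
  grDevices::png(f, width = 700, height = 500)
  if (length(resp) == 0) {
    graphics::plot.new()
    graphics::title(main = sprintf("%s: no robust responders", condition))
  } else {
    m <- tavg[resp, , drop = FALSE]
    graphics::image(t_rel, seq_along(resp), t(m),
                    col = grDevices::hcl.colors(64, "viridis"),
                    xlab = "time from onset (s)", ylab = "responder #",
                    main = sprintf("z-scored responses, %s responders (n=%d)",
                                   condition, length(resp)))
    graphics::abline(v = 0, col = "white", lty = 2)
  }
  grDevices::dev.off()
  files <- c(files, f)

  f <- file.path(dir, sprintf("mean_trace_%s.png", condition))
  grDevices::png(f, width = 700, height = 450)
  mt <- colMeans(tavg, na.rm = TRUE)
  graphics::plot(t_rel, mt, type = "l", xlab = "time from onset (s)",
                 ylab = "mean z", main = sprintf("population mean, %s", condition))
  graphics::abline(v = 0, lty = 2)
  grDevices::dev.off()
  files <- c(files, f)

  if (!is.null(other_set)) {
    ov <- overlap_sets(sub$class == "responder", other_set)
    f <- file.path(dir, sprintf("venn_%s.csv", condition))
    utils::write.csv(data.frame(region = names(ov), count = as.integer(ov)),
                     f, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
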