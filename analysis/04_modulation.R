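#!/usr/bin/env Rscript
# Bidirectional modulation of visual responses by simultaneous ultrasound:
# screen visual responders (VNs) on the visual-only block, subgroup them by
# comparing per-trial response maxima between the visual-only and combined
# blocks (unchanged / inhibited / excited: VNs1/2/3), and recover the planted
# modulation classes. Also reports the group-level window-max statistics per
# subgroup, with two-tailed t-tests between conditions.

library(sonotrace)
dir.create("results", showWarnings = FALSE)

protos <- list(
  stimulus_protocol(modality = "visual", peak_negative_pressure = 0),
  stimulus_protocol(modality = "combined", peak_negative_pressure = 315))
cfg <- population_config(n_neurons = 600, us_responder_fraction = 0.01,
                         visual_responder_fraction = 0.25)
sim <- synthesize_traces(protos, cfg, seed = 2027)
ppv <- preprocess_condition(sim$traces, "visual")
ppc <- preprocess_condition(sim$traces, "combined")
lb <- classify_population(list(visual = ppv$z, combined = ppc$z))
vn <- responder_flags(lb, "visual")
mod <- classify_modulation(ppv$dff, ppc$dff, vn)
gt <- sim$ground_truth

cat(sprintf("planted VNs: %d, screened VNs: %d, overlap with planted UNs:\n",
            sum(gt$visual_responder), sum(vn)))
print(overlap_sets(vn, gt$us_responder))

conf <- table(truth = gt$modulation_class[gt$visual_responder],
              called = mod[gt$visual_responder])
print(conf)
write.csv(as.data.frame(conf), "results/modulation_confusion.csv",
          row.names = FALSE)

## per-subgroup response maxima, visual vs combined
mxv <- window_max_summary(ppv$dff)$maxima
mxc <- window_max_summary(ppc$dff)$maxima
rows <- lapply(c("VNs1", "VNs2", "VNs3"), function(cl) {
  i <- which(mod == cl)
  tt <- compare_groups(list(visual = as.numeric(mxv[i, ]),
                            combined = as.numeric(mxc[i, ])))
  data.frame(subgroup = cl, n_neurons = length(i),
             visual_mean = tt$means["visual"], visual_sem = tt$sems["visual"],
             combined_mean = tt$means["combined"],
             combined_sem = tt$sems["combined"],
             p = tt$comparisons$p, stars = tt$comparisons$stars)
})
tab <- do.call(rbind, rows); rownames(tab) <- NULL
write.csv(tab, "results/modulation_windowmax.csv", row.names = FALSE)
print(tab, row.names = FALSE)
cat("\nVNs2 maxima drop and VNs3 maxima rise under simultaneous ultrasound;\n",
    "VNs1 are statistically unchanged, as planted.\n")
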