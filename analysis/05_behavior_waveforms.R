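#!/usr/bin/env Rscript
# Behavioral control: apply the reliability machinery to the running-speed
# trace and correlate trial-by-trial neural and speed modulation; then
# type units as regular- vs fast-spiking from their mean waveforms.

source(file.path("analysis", "00_settings.R"))

g <- main_session()
pr <- analyze_perturbation(g$session, n_shuffles = N_SHUFFLES,
                           seed = MASTER_SEED + 2L)
beh <- analyze_behavior(g$session, pr, n_shuffles = N_SHUFFLES,
                        seed = MASTER_SEED + 4L)

if (isTRUE(beh$speed$evaluable)) {
  cat(sprintf("speed-change classifier: AUC %.3f (null p95 %.3f) -> %s\n",
              beh$speed$auc, beh$speed$null_p95,
              if (beh$speed$reliable) "reliable speed changes" else
                "no reliable speed changes"))
  cat(sprintf("units with neural-speed MI correlation (p < 0.05): %d/%d\n",
              sum(beh$table$significant, na.rm = TRUE), nrow(beh$table)))
  write.csv(beh$table, file.path(RESULTS_DIR, "behavior_correlation.csv"),
            row.names = FALSE)
}

wav <- analyze_waveforms(g$session)
truth <- g$ground_truth$waveform_class
cat(sprintf("waveform typing: %d regular, %d fast (3 PCs explain %.0f%% variance)\n",
            sum(wav$cluster == "regular"), sum(wav$cluster == "fast"),
            100 * attr(wav, "variance_explained")))
cat(sprintf("  agreement with generator classes: %.0f%%\n",
            100 * mean(wav$cluster == truth)))
write.csv(wav, file.path(RESULTS_DIR, "waveform_classes.csv"), row.names = FALSE)
cat("wrote behavior_correlation.csv, waveform_classes.csv\n")
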