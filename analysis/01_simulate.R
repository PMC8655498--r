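#!/usr/bin/env Rscript
# Build the synthetic study session: 160 grating trials (8 directions x 20),
# a random 25% with a 1-s visual-flow perturbation, 8 zero-contrast trials,
# a bout-structured running trace, and 40 ground-truth units. Writes the
# ground-truth sidecar and the protocol tables.

source(file.path("analysis", "00_settings.R"))

g <- main_session()
session <- g$session

v <- validate_session(session)
stopifnot(v$ok)

tr <- session$trials
cat(sprintf("session: %d units, %.0f s\n", length(session$units), session$duration))
cat(sprintf("grating trials: %d (%d perturbation, %.0f%%), blank trials: %d\n",
            sum(!tr$blank), sum(tr$has_perturbation),
            100 * mean(tr$has_perturbation[!tr$blank]), sum(tr$blank)))
sp <- split_trials_by_running(session)
cat(sprintf("perturbation trials by state: %d running, %d stationary\n",
            length(sp$running), length(sp$stationary)))

write.csv(g$ground_truth, file.path(RESULTS_DIR, "ground_truth.csv"),
          row.names = FALSE)
write_protocol(tr, json_path = file.path(RESULTS_DIR, "protocol_trials.json"))
write.csv(tr, file.path(RESULTS_DIR, "trial_table.csv"), row.names = FALSE)
cat("wrote ground_truth.csv, protocol_trials.json, trial_table.csv\n")
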