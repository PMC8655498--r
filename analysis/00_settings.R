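# Shared settings for the analysis scripts. Every script regenerates the
# synthetic sessions deterministically from these seeds, so the scripts
# can be run independently and in any order.

library(pertflow)

MASTER_SEED <- 20260920L
N_UNITS <- 40L
N_SHUFFLES <- 200L   # label shuffles for the classifier null
N_BOOT <- 500L       # bootstrap draws for the running test

RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

# the study cohort: mixed positive/negative perturbation modulation,
# TF preference coupled to MI sign, locomotion gain on the perturbation
study_config <- cohort_config(n_units = N_UNITS)

main_session <- function() generate_session(study_config, seed = MASTER_SEED)

# same units probed with the accelerating-grating TF protocol
tf_session <- function(ground_truth) {
  generate_session(study_config, seed = MASTER_SEED + 1L, protocol = "tf",
                   unit_params = ground_truth)
}
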