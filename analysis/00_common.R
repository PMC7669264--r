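# Shared settings for the analysis drivers: one study-like synthetic cohort
# (24 subjects per language x reading-ability cell, two runs, three visual
# categories) under the reduced-amplitude pathology scenario, on the
# reduced ventral-temporal grid used throughout the simulation studies.

library(readcircuit)

dir.create("results", showWarnings = FALSE)

STUDY_SEED <- 20201029

study_cohort <- function() {
  generate_cohort(cohort_spec(n_per_group = 24, n_runs = 2,
                              grid = reduced_grid(), scenario = "amplitude",
                              seed = STUDY_SEED))
}

# wide ventral grid holding both hemispheres of the y-axis sphere chains
bilateral_ventral_grid <- function() {
  make_grid(c(-60, -81, -30), c(60, -12, 0), 3)
}
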