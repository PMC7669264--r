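# Which analyses fire under which pathology scenario: repeated-cohort
# detection rates of the ROI-mean, peak-distance, peak-amplitude and
# pattern-reliability effects under the amplitude / dispersion /
# instability generators. This is the qualitative dissociation table that
# justifies interpreting group hypoactivation together with individual
# peak and MVPA analyses. (Small Monte-Carlo here: 20 cohorts per
# scenario; the test suite and acceptance script run larger versions.)

source("analysis/00_common.R")

n <- 20
rows <- list(
  amplitude = dissociation_study("amplitude", n_cohorts = n, seed = 101,
                                 analyses = c("roi", "peaks", "mvpa_word")),
  dispersion = dissociation_study("dispersion", n_cohorts = n, seed = 102,
                                  analyses = c("roi", "peaks")),
  instability = dissociation_study("instability", n_cohorts = n, seed = 103,
                                   analyses = c("roi", "peaks", "mvpa_word",
                                                "mvpa_face")))

tab <- do.call(rbind, lapply(names(rows), function(s)
  data.frame(scenario = s, t(rows[[s]]$rates))))
write.table(tab, "results/scenario_dissociation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Detection rates (proportion of", n, "cohorts with p < 0.05):\n")
print(tab, digits = 2)
cat("\nReading of the table: reduced amplitude fires the ROI-mean and\n",
    "peak-amplitude tests but not peak distance; spatial dispersion fires\n",
    "the distance test; pattern instability fires the word-ROI condition x\n",
    "group MVPA interaction while sparing the face ROI.\n")
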