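# Bayesian ROI table: BIC-approximate Bayes factors for the main effects
# and the language x reading-ability interaction, plus directional JZS
# Bayes factors for the four post-hoc group comparisons with Cauchy-width
# sensitivity verdicts.

source("analysis/00_common.R")

co <- study_cohort()
means <- roi_mean_table(co, "words", merge_foci(read_foci()))
bt <- bayes_roi_stage(means, co$meta)

write.table(bt, "results/roi_bayes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Evidence for a reading-ability effect (BF10 > 3 is moderate):\n")
print(bt[, c("roi", "bf_reading", "bf_interaction")], digits = 3)
cat("\nInteraction BF10 < 1/3 (moderate evidence for the null, i.e. a\n",
    "cross-language invariant reading-ability deficit):",
    paste(bt$roi[bt$bf_interaction < 1 / 3], collapse = ", "), "\n")
cat("\nDirectional post-hoc BFs (typical > poor) with sensitivity:\n")
print(bt[, c("roi", "bf_typ_vs_poor_ZH", "sens_typ_vs_poor_ZH",
             "bf_typ_vs_poor_FR", "sens_typ_vs_poor_FR")], digits = 3)
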