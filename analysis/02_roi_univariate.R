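# Literature-driven ROI univariate analysis: mean word-vs-fixation betas in
# the 6-mm literature spheres, 2x2 language x reading-ability ANOVAs with
# FDR over ROIs, and ROI-activation / reading-score correlations.

source("analysis/00_common.R")

co <- study_cohort()
st <- univariate_roi_stage(co)

write.table(st$anova, "results/roi_anova.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(st$correlations, "results/roi_reading_correlations.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

sig <- subset(st$anova, effect == "reading_group" & p_fdr < 0.05)
cat("ROIs with an FDR-significant reading-ability effect on word betas:\n")
print(sig[, c("roi", "F", "df_num", "df_den", "p", "p_fdr")], digits = 3)
int <- subset(st$anova, effect == "language:reading_group" & p_fdr < 0.05)
cat("\nROIs with a language x reading-ability interaction:",
    if (nrow(int)) paste(int$roi, collapse = ", ") else "none", "\n")
cat("\nROI / reading-score correlations (FDR-significant):\n")
print(subset(st$correlations, p_fdr < 0.05), digits = 3)
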