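# Anterior-posterior gradient of the ventral temporal cortex: mean betas in
# six 6-mm spheres along y (constant |x| per category, z = -16), both
# hemispheres, with the language x reading-ability x position x hemisphere
# mixed ANOVA and per-position group contrasts.

source("analysis/00_common.R")

co <- generate_cohort(cohort_spec(n_per_group = 24, n_runs = 1,
                                  grid = bilateral_ventral_grid(),
                                  scenario = "amplitude",
                                  seed = STUDY_SEED))

for (cc in c("words", "faces", "houses")) {
  gs <- gradient_stage(co, cc)
  write.table(gs$anova, sprintf("results/gradient_%s_anova.tsv", cc),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(gs$followup, sprintf("results/gradient_%s_followup.tsv", cc),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat("\n==", cc, "==\n")
  keep <- gs$anova$effect %in% c("y", "reading_group:y", "hemisphere",
                                 "reading_group")
  print(gs$anova[keep, c("effect", "df_num", "df_den", "F", "p")],
        digits = 3)
  sig <- subset(gs$followup, p_fdr < 0.05)
  cat("positions with FDR-significant typical > poor contrast:",
      if (nrow(sig)) paste(sig$y, collapse = ", ") else "none", "\n")
}
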