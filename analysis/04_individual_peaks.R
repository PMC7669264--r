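# Individual-peak analysis: per-subject best-responding voxels in 12-mm
# spheres around the group [words > faces+houses] peaks, centre-of-mass
# distance (anatomical dispersion) and peak amplitude, with 2x2 group
# ANOVAs per ROI.

source("analysis/00_common.R")

co <- study_cohort()
rois <- merge_foci(read_foci())
on_grid <- vapply(seq_len(nrow(rois)), function(i)
  mask_size(sphere_mask(co$grid, c(rois$x[i], rois$y[i], rois$z[i]), 12)) > 200,
  TRUE)
rois <- rois[on_grid, ]

ct <- preference_contrast(co, "words")
tv <- voxelwise_t(ct, "one_sample")
gp <- lapply(seq_len(nrow(rois)), function(i)
  group_peak(co$grid, tv$t, seed_mm = c(rois$x[i], rois$y[i], rois$z[i]),
             radius_mm = 12)$mm)
names(gp) <- rois$name

pk <- cohort_individual_peaks(co, "words", gp)
tests <- peak_group_tests(pk, co$meta)

write.table(pk, "results/individual_peaks.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(tests, "results/peak_anova.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

rd <- subset(tests, effect == "reading_group")
cat("Reading-ability effect on peak ACTIVATION vs peak LOCATION:\n")
print(rd[, c("roi", "measure", "F", "p", "p_fdr", "bf10_interaction")],
      digits = 3)
cat("\nUnder the amplitude scenario the activation measure should fire\n",
    "while the distance measure stays null (no anatomical dispersion).\n")
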