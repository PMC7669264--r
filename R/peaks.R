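# ---------------------------------------------------------------------------
# Individual activation-peak analysis: best-responding voxels per subject in
# a search sphere, centre-of-mass dispersion, and group tests.
# ---------------------------------------------------------------------------

#' Individual peak selection for one subject
#'
#' Within a search sphere around the group peak, keeps the voxels whose t
#' exceeds \code{t_min} and selects the \code{k} most active (by t, default,
#' or by beta); ties at the kth rank are broken by ascending voxel index.
#' Returns the unweighted centre of mass of the selected voxel centres, its
#' Euclidean distance to the group peak, and the mean selected beta. With
#' zero candidates the result is flagged missing (to be excluded pairwise
#' from group tests).
#'
#' @param grid A \code{vol_grid}.
#' @param beta Subject beta volume (vector/array over the grid).
#' @param tvol Subject t volume.
#' @param group_peak_mm Search-sphere centre (group peak), mm.
#' @param radius_mm Search radius (default 12).
#' @param t_min Candidate threshold on t (default 1).
#' @param k Number of voxels to select (default 10).
#' @param rank_by "t" (default) or "beta".
#' @param weighted Use t-weighted centre of mass (default FALSE, unweighted).
#' @return One-row data.frame: n_candidates, n_selected, com_x/y/z,
#'   distance_mm, mean_beta, missing.
#' @export
individual_peak <- function(grid, beta, tvol, group_peak_mm, radius_mm = 12,
                            t_min = 1, k = 10, rank_by = c("t", "beta"),
                            weighted = FALSE) {
  rank_by <- match.arg(rank_by)
  beta <- as.vector(beta); tvol <- as.vector(tvol)
  stopifnot(length(beta) == n_voxels(grid), length(tvol) == n_voxels(grid))
  sph <- sphere_mask(grid, group_peak_mm, radius_mm)
  cand <- sph$linear[tvol[sph$linear] >= t_min]
  if (length(cand) == 0L)
    return(data.frame(n_candidates = 0L, n_selected = 0L,
                      com_x = NA_real_, com_y = NA_real_, com_z = NA_real_,
                      distance_mm = NA_real_, mean_beta = NA_real_,
                      missing = TRUE))
  score <- if (rank_by == "t") tvol[cand] else beta[cand]
  sel <- cand[order(-score, cand)][seq_len(min(k, length(cand)))]
  ijk <- linear_to_ijk(grid, sel); attr(ijk, "keep") <- TRUE
  mm <- voxel_to_mm(grid, ijk)
  w <- if (weighted) tvol[sel] / sum(tvol[sel]) else rep(1 / length(sel), length(sel))
  com <- as.vector(t(mm) %*% w)
  data.frame(n_candidates = length(cand), n_selected = length(sel),
             com_x = com[1], com_y = com[2], com_z = com[3],
             distance_mm = sqrt(sum((com - group_peak_mm)^2)),
             mean_beta = mean(beta[sel]), missing = FALSE)
}

#' Individual peaks for a whole cohort and ROI set
#'
#' @param cohort A \code{cohort}.
#' @param condition Condition whose beta/t volumes are searched.
#' @param group_peaks Named list of group-peak mm coordinates (one per ROI).
#' @param ... Passed to \code{individual_peak}.
#' @return data.frame with one row per subject x ROI.
#' @export
cohort_individual_peaks <- function(cohort, condition, group_peaks, ...) {
  B <- subject_betas(cohort, condition)
  Tm <- subject_tvols(cohort, condition)
  out <- list()
  for (roi in names(group_peaks)) {
    for (s in seq_len(ncol(B))) {
      row <- individual_peak(cohort$grid, B[, s], Tm[, s],
                             group_peaks[[roi]], ...)
      row$id <- cohort$meta$id[s]; row$roi <- roi
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  n_missing <- sum(res$missing)
  if (n_missing > 0)
    message(n_missing, " subject x ROI peak result(s) flagged missing ",
            "(no suprathreshold candidates); excluded pairwise")
  res[, c("id", "roi", "n_candidates", "n_selected", "com_x", "com_y",
          "com_z", "distance_mm", "mean_beta", "missing")]
}

#' Group tests on individual-peak distance and amplitude
#'
#' For each ROI, runs language x reading-ability between-subject ANOVAs on
#' (a) the centre-of-mass distance to the group peak and (b) the mean beta
#' of the selected voxels, FDR-corrected over ROIs within each measure, and
#' computes the BIC-approximate Bayes factor for the interaction.
#'
#' @param peaks data.frame from \code{cohort_individual_peaks}.
#' @param meta Cohort metadata (id, language, reading_group).
#' @param q FDR level (default 0.05).
#' @return data.frame: roi, measure, effect, F, df, p, p_fdr,
#'   bf10_interaction.
#' @export
peak_group_tests <- function(peaks, meta, q = 0.05) {
  d <- merge(peaks[!peaks$missing, ], meta, by = "id")
  out <- list()
  for (measure in c("distance_mm", "mean_beta")) {
    for (roi in unique(d$roi)) {
      dd <- d[d$roi == roi, ]
      cells <- table(dd$language, dd$reading_group)
      if (any(cells < 2)) stop("fewer than 2 subjects in a cell for ROI ", roi)
      dd$value <- dd[[measure]]
      dd$subject <- dd$id
      aov_tab <- mixed_anova(dd, "value", "subject",
                             between = c("language", "reading_group"))
      bf <- anova_effect_bf(dd, "value", c("language", "reading_group"),
                            "language:reading_group")
      aov_tab$roi <- roi; aov_tab$measure <- measure
      aov_tab$bf10_interaction <- bf$bf10
      out[[length(out) + 1L]] <- aov_tab
    }
  }
  res <- do.call(rbind, out)
  res$p_fdr <- NA_real_
  for (measure in unique(res$measure)) for (eff in unique(res$effect)) {
    ii <- res$measure == measure & res$effect == eff
    res$p_fdr[ii] <- bh_fdr(res$p[ii], q)$p_adj
  }
  res[, c("roi", "measure", "effect", "df_num", "df_den", "F", "p", "p_fdr",
          "bf10_interaction")]
}
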