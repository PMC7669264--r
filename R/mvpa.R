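# ---------------------------------------------------------------------------
# Split-run multivoxel pattern reliability: within- vs between-category
# run-1/run-2 correlations in sphere ROIs intersected with preference masks.
# ---------------------------------------------------------------------------

#' Pattern-analysis ROI: sphere intersected with a preference mask
#'
#' 9-mm sphere around the ROI centre, restricted to the group
#' category-preference mask so that only reliably activated voxels enter
#' the pattern correlations. ROIs whose intersection falls below
#' \code{min_voxels} are excluded (returns NULL with a warning naming the
#' ROI): correlations over a handful of voxels are too unstable to
#' interpret.
#'
#' @param grid A \code{vol_grid}.
#' @param center_mm ROI centre.
#' @param preference_mask A \code{voxel_mask}.
#' @param radius_mm Sphere radius (default 9).
#' @param min_voxels Minimum intersection size (default 5).
#' @param name ROI name for messages.
#' @export
mvpa_roi_mask <- function(grid, center_mm, preference_mask, radius_mm = 9,
                          min_voxels = 5, name = "roi") {
  sph <- sphere_mask(grid, center_mm, radius_mm, name)
  m <- mask_intersect(sph, preference_mask)
  m$name <- name
  if (mask_size(m) < min_voxels) {
    warning("ROI '", name, "' excluded from pattern analysis: only ",
            mask_size(m), " voxel(s) inside the preference mask")
    return(NULL)
  }
  m
}

#' Split-run pattern correlations for one ROI
#'
#' For every subject with at least two runs (subjects with a single run are
#' excluded; with more than two, the first two are used), correlates the
#' run-1 pattern of the family's reference category with the run-2 pattern
#' of each category over the ROI voxels. For the word family the pairs are
#' words-words (within) and words-faces, words-houses, faces-houses
#' (between); for the face family, faces-faces (within) and faces-words,
#' faces-houses, words-houses (between). Correlations are Fisher
#' z-transformed before averaging the three between pairs.
#'
#' @param cohort A \code{cohort} with all three conditions and >= 2 runs.
#' @param mask ROI \code{voxel_mask}.
#' @param family "words" or "faces" (the within category).
#' @return data.frame: id, roi, n_vox, r_within, r_b1, r_b2, r_b3,
#'   z_within, z_between, flag.
#' @export
run_pair_correlations <- function(cohort, mask, family = c("words", "faces")) {
  family <- match.arg(family)
  conds <- names(cohort$beta)
  if (length(conds) < 3) stop("pattern analysis needs all three conditions")
  others <- setdiff(c("words", "faces", "houses"), family)
  # pairs: (within) family~family, then family~other1, family~other2, other1~other2
  pairs <- rbind(c(family, family), c(family, others[1]), c(family, others[2]),
                 c(others[1], others[2]))
  vox <- mask$linear
  out <- list()
  for (s in seq_len(nrow(cohort$meta))) {
    if (cohort$meta$n_runs[s] < 2) next
    r <- numeric(4); bad <- FALSE
    for (pp in 1:4) {
      p1 <- cohort$beta[[pairs[pp, 1]]][[1]][vox, s]
      p2 <- cohort$beta[[pairs[pp, 2]]][[2]][vox, s]
      if (stats::sd(p1) == 0 || stats::sd(p2) == 0) { bad <- TRUE; break }
      r[pp] <- stats::cor(p1, p2)
    }
    out[[length(out) + 1L]] <- data.frame(
      id = cohort$meta$id[s], roi = if (is.null(mask$name)) "roi" else mask$name,
      n_vox = length(vox),
      r_within = r[1], r_b1 = r[2], r_b2 = r[3], r_b3 = r[4],
      z_within = fisher_z(r[1]), z_between = mean(fisher_z(r[2:4])),
      flag = bad, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  n_excl <- nrow(cohort$meta) - nrow(res)
  if (n_excl > 0)
    message(n_excl, " subject(s) excluded from pattern analysis ",
            "(single run)")
  if (any(res$flag))
    message(sum(res$flag), " subject(s) flagged for zero-variance patterns; ",
            "excluded")
  res[!res$flag, ]
}

#' Condition (within vs between) x group reliability ANOVA for one ROI
#'
#' Mixed ANOVA on Fisher-z pattern correlations with language and reading
#' ability as between-subject factors and condition (within-category vs
#' between-category correlation) as a within-subject factor.
#'
#' @param records As from \code{run_pair_correlations}.
#' @param meta Cohort metadata.
#' @return Effect table from \code{mixed_anova}.
#' @export
reliability_anova <- function(records, meta) {
  d <- merge(records, meta, by = "id")
  long <- rbind(
    data.frame(subject = d$id, language = d$language,
               reading_group = d$reading_group, condition = "within",
               value = d$z_within),
    data.frame(subject = d$id, language = d$language,
               reading_group = d$reading_group, condition = "between",
               value = d$z_between))
  mixed_anova(long, "value", "subject",
              between = c("language", "reading_group"), within = "condition")
}

#' Triple category x condition x reading-ability reliability ANOVA
#'
#' Combines word-family and face-family pattern records from the fusiform
#' ROIs into one design with category (words vs faces) and condition
#' (within vs between) as within-subject factors, testing whether reduced
#' pattern stability is specific to words.
#'
#' @param word_records,face_records Records from
#'   \code{run_pair_correlations} for the word ROI and the face ROI.
#' @param meta Cohort metadata.
#' @return Effect table from \code{mixed_anova}.
#' @export
reliability_triple_anova <- function(word_records, face_records, meta) {
  mk <- function(rec, cat) rbind(
    data.frame(subject = rec$id, category = cat, condition = "within",
               value = rec$z_within),
    data.frame(subject = rec$id, category = cat, condition = "between",
               value = rec$z_between))
  long <- rbind(mk(word_records, "words"), mk(face_records, "faces"))
  long <- merge(long, meta[, c("id", "language", "reading_group")],
                by.x = "subject", by.y = "id")
  mixed_anova(long, "value", "subject",
              between = c("language", "reading_group"),
              within = c("category", "condition"))
}
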