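# ---------------------------------------------------------------------------
# Orchestration: ROI univariate + Bayes + peaks + MVPA + gradient stages
# over one cohort, with provenance-stamped tidy outputs.
# ---------------------------------------------------------------------------

fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 5381
  # polynomial rolling hash in doubles (stays far below 2^53)
  for (b in bytes) h <- (h * 131 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

write_tsv_prov <- function(df, path, provenance) {
  con <- file(path, "w")
  on.exit(close(con))
  for (l in provenance) writeLines(paste0("# ", l), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-subject ROI means for a set of sphere ROIs
#'
#' @param cohort A \code{cohort}.
#' @param condition Condition to extract (run-averaged betas).
#' @param rois ROI data.frame (name/x/y/z/radius_mm).
#' @param radius_mm Optional radius override.
#' @return Matrix subjects x ROIs of mean betas (ROIs with empty masks on
#'   this grid are dropped with a message).
#' @export
roi_mean_table <- function(cohort, condition, rois, radius_mm = NULL) {
  masks <- roi_masks(rois, cohort$grid, radius_mm)
  keep <- vapply(masks, mask_size, 1L) > 0
  if (any(!keep))
    message("ROI(s) outside the grid dropped: ",
            paste(names(masks)[!keep], collapse = ", "))
  masks <- masks[keep]
  B <- subject_betas(cohort, condition)
  out <- vapply(masks, function(m) colMeans(B[m$linear, , drop = FALSE]),
                numeric(ncol(B)))
  rownames(out) <- cohort$meta$id
  out
}

#' Literature-driven ROI univariate stage
#'
#' For each ROI: the language x reading-ability between-subject ANOVA on
#' run-averaged condition betas, FDR-corrected over ROIs within each
#' effect, plus the Pearson correlation of ROI activation with reading
#' scores across all subjects (also FDR-corrected).
#'
#' @param cohort A \code{cohort}.
#' @param rois ROI data.frame (default: merged literature foci, 6 mm).
#' @param condition Condition (default "words").
#' @param q FDR level.
#' @return List with \code{means} (subject x ROI), \code{anova}
#'   (effect rows with p_fdr), \code{correlations}.
#' @export
univariate_roi_stage <- function(cohort, rois = merge_foci(read_foci()),
                                 condition = "words", q = 0.05) {
  M <- roi_mean_table(cohort, condition, rois)
  meta <- cohort$meta
  tabs <- list(); cors <- list()
  for (roi in colnames(M)) {
    d <- data.frame(subject = meta$id, language = meta$language,
                    reading_group = meta$reading_group, value = M[, roi])
    tab <- mixed_anova(d, "value", "subject",
                       between = c("language", "reading_group"))
    tab$roi <- roi
    tabs[[roi]] <- tab
    ct <- pearson_test(M[, roi], meta$reading_z)
    cors[[roi]] <- data.frame(roi = roi, r = ct$r, p = ct$p, n = ct$n)
  }
  av <- do.call(rbind, tabs); rownames(av) <- NULL
  av$p_fdr <- NA_real_
  for (eff in unique(av$effect)) {
    ii <- av$effect == eff
    av$p_fdr[ii] <- bh_fdr(av$p[ii], q)$p_adj
  }
  co <- do.call(rbind, cors); rownames(co) <- NULL
  co$p_fdr <- bh_fdr(co$p, q)$p_adj
  list(means = M, anova = av, correlations = co)
}

#' Bayesian ROI table (main effects, interaction, directional post-hocs)
#'
#' Mirrors the layout of a Bayesian ANOVA summary per ROI: BIC-approximate
#' Bayes factors for the two main effects and the interaction, and
#' directional JZS Bayes factors for the four post-hoc comparisons
#' (typical > poor within each language; Chinese > French within each
#' reading group), each with a Cauchy-width sensitivity verdict.
#'
#' @param means Subject x ROI matrix from \code{univariate_roi_stage}.
#' @param meta Cohort metadata.
#' @param width Cauchy width for post-hoc BFs (default 0.707).
#' @return data.frame, one row per ROI.
#' @export
bayes_roi_stage <- function(means, meta, width = 0.707) {
  out <- lapply(colnames(means), function(roi) {
    v <- means[, roi]
    d <- data.frame(value = v, language = meta$language,
                    reading_group = meta$reading_group)
    bf_lang <- anova_effect_bf(d, "value", c("language", "reading_group"),
                               "language")$bf10
    bf_read <- anova_effect_bf(d, "value", c("language", "reading_group"),
                               "reading_group")$bf10
    bf_int <- anova_effect_bf(d, "value", c("language", "reading_group"),
                              "language:reading_group")$bf10
    ph <- function(g1, g2) jzs_bf_two_sample(g1, g2, width,
                                             "group1_greater")
    sl <- function(lang) list(
      t = v[meta$language == lang & meta$reading_group == "typical"],
      p = v[meta$language == lang & meta$reading_group == "poor"])
    zh <- sl("ZH"); fr <- sl("FR")
    bf_zh <- ph(zh$t, zh$p); bf_fr <- ph(fr$t, fr$p)
    bf_typ <- ph(zh$t, fr$t); bf_poor <- ph(zh$p, fr$p)
    sens <- function(g1, g2) bf_sensitivity(g1, g2,
                                            direction = "group1_greater")$verdict
    data.frame(
      roi = roi, bf_language = bf_lang, bf_reading = bf_read,
      bf_interaction = bf_int,
      bf_typ_vs_poor_ZH = bf_zh$bf10, bf_typ_vs_poor_FR = bf_fr$bf10,
      bf_ZH_vs_FR_typical = bf_typ$bf10, bf_ZH_vs_FR_poor = bf_poor$bf10,
      sens_typ_vs_poor_ZH = sens(zh$t, zh$p),
      sens_typ_vs_poor_FR = sens(fr$t, fr$p),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out); rownames(res) <- NULL
  res
}

#' Anterior-posterior gradient stage
#'
#' Mean run-averaged beta in six 6-mm spheres along y at the category's
#' privileged |x| (and z = -16) per hemisphere, followed by the
#' language x reading-ability x position x hemisphere mixed ANOVA and
#' per-position typical-vs-poor Welch contrasts FDR-corrected across the
#' six positions.
#'
#' @param cohort A \code{cohort}.
#' @param condition "words", "faces" or "houses".
#' @param hemispheres Hemispheres to analyse (default both; use "L" on
#'   grids that crop the right hemisphere).
#' @return List with \code{table} (subject x hemisphere x position rows),
#'   \code{anova}, \code{followup}.
#' @export
gradient_stage <- function(cohort, condition, hemispheres = c("L", "R")) {
  chain <- build_ap_chain(condition)
  B <- subject_betas(cohort, condition)
  meta <- cohort$meta
  rows <- list()
  for (h in hemispheres) {
    masks <- chain_masks(chain, cohort$grid, h)
    for (yy in names(masks)) {
      m <- masks[[yy]]
      if (mask_size(m) == 0L)
        stop("empty chain sphere ", condition, " ", h, " ", yy)
      vals <- colMeans(B[m$linear, , drop = FALSE])
      rows[[paste(h, yy)]] <- data.frame(
        subject = meta$id, language = meta$language,
        reading_group = meta$reading_group, hemisphere = h, y = yy,
        value = vals, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows); rownames(tab) <- NULL
  within <- c("y", if (length(hemispheres) > 1) "hemisphere")
  av <- mixed_anova(tab, "value", "subject",
                    between = c("language", "reading_group"), within = within)
  # per-position typical vs poor (hemisphere-averaged), FDR over positions
  fo <- lapply(sort(unique(tab$y)), function(yy) {
    d <- tab[tab$y == yy, ]
    ag <- tapply(d$value, d$subject, mean)
    grp <- meta$reading_group[match(names(ag), meta$id)]
    tt <- tryCatch(stats::t.test(ag[grp == "typical"], ag[grp == "poor"]),
                   error = function(e) NULL)   # constant data
    data.frame(y = yy,
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
               p = if (is.null(tt)) NA_real_ else tt$p.value,
               mean_typical = mean(ag[grp == "typical"]),
               mean_poor = mean(ag[grp == "poor"]))
  })
  fo <- do.call(rbind, fo)
  fo$p_fdr <- NA_real_
  ok <- is.finite(fo$p)
  if (any(ok)) fo$p_fdr[ok] <- bh_fdr(fo$p[ok], 0.05)$p_adj
  list(table = tab, anova = av, followup = fo)
}

#' Default analysis configuration
#'
#' @param out Output directory.
#' @param cohort_args Arguments to \code{cohort_spec()} (synthetic input
#'   mode) or NULL with \code{input_dir} set.
#' @param input_dir Existing cohort directory (alternative to synthetic).
#' @param stages Stages to run, in dependency order.
#' @param p_voxel,q_fdr,n_perm Analysis thresholds.
#' @param seed Analysis seed (permutations).
#' @export
analysis_config <- function(out, cohort_args = list(), input_dir = NULL,
                            stages = c("simulate", "masks", "univariate",
                                       "bayes", "peaks", "mvpa", "gradient"),
                            p_voxel = 0.001, q_fdr = 0.05, n_perm = 1000,
                            seed = 1) {
  list(out = out, cohort_args = cohort_args, input_dir = input_dir,
       stages = stages, p_voxel = p_voxel, q_fdr = q_fdr,
       n_perm = as.integer(n_perm), seed = as.integer(seed))
}

#' Run the full analysis pipeline from one configuration
#'
#' Executes the enabled stages in dependency order over a synthetic or
#' on-disk cohort, writing tidy TSV tables (with provenance headers:
#' configuration hash, seed, package version) and NIfTI masks under the
#' output directory. Identical configuration and seed yield byte-identical
#' tables. A stage failure aborts with the stage name; earlier outputs are
#' kept.
#'
#' @param config As from \code{analysis_config()}.
#' @return Invisible list of in-memory stage results.
#' @export
run_full_analysis <- function(config) {
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  prov <- c(paste0("config_hash: ", fnv1a_hash(config[setdiff(names(config), "out")])),
            paste0("seed: ", config$seed),
            paste0("readcircuit_version: ",
                   as.character(utils::packageVersion("readcircuit"))))
  res <- list()
  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    t0 <- proc.time()[3]
    out <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("[stage %s] done in %.1fs", name, proc.time()[3] - t0))
    out
  }

  if (!is.null(config$input_dir)) {
    if (!dir.exists(config$input_dir))
      stop("input cohort directory does not exist: ", config$input_dir)
    cohort <- read_cohort(config$input_dir)
  } else {
    cohort <- run_stage("simulate", function()
      generate_cohort(do.call(cohort_spec, config$cohort_args)))
    if (is.null(cohort))
      stop("no input: enable the simulate stage or set input_dir")
  }
  res$cohort <- cohort
  rois <- merge_foci(read_foci())
  on_grid <- vapply(seq_len(nrow(rois)), function(i)
    mask_size(sphere_mask(cohort$grid, c(rois$x[i], rois$y[i], rois$z[i]),
                          rois$radius_mm[i])) > 0, TRUE)
  rois <- rois[on_grid, , drop = FALSE]

  res$masks <- run_stage("masks", function() {
    out <- list()
    for (cc in names(cohort$beta)) {
      pm <- category_preference_mask(cohort, cc, p_voxel = config$p_voxel,
                                     n_perm = config$n_perm,
                                     seed = config$seed)
      write_mask(pm$mask, file.path(config$out, paste0(cc, "_pref_mask.nii.gz")))
      if (!is.null(pm$peak_table))
        write_tsv_prov(pm$peak_table,
                       file.path(config$out, paste0(cc, "_pref_peaks.tsv")), prov)
      out[[cc]] <- pm
    }
    out
  })

  res$univariate <- run_stage("univariate", function() {
    st <- univariate_roi_stage(cohort, rois, q = config$q_fdr)
    write_tsv_prov(st$anova, file.path(config$out, "roi_anova.tsv"), prov)
    write_tsv_prov(st$correlations,
                   file.path(config$out, "roi_reading_correlations.tsv"), prov)
    st
  })

  res$bayes <- run_stage("bayes", function() {
    means <- if (!is.null(res$univariate)) res$univariate$means
             else roi_mean_table(cohort, "words", rois)
    bt <- bayes_roi_stage(means, cohort$meta)
    write_tsv_prov(bt, file.path(config$out, "roi_bayes.tsv"), prov)
    bt
  })

  res$peaks <- run_stage("peaks", function() {
    ct <- preference_contrast(cohort, "words")
    tv <- voxelwise_t(ct, "one_sample")
    gp <- lapply(seq_len(nrow(rois)), function(i)
      group_peak(cohort$grid, tv$t, seed_mm = c(rois$x[i], rois$y[i], rois$z[i]),
                 radius_mm = 12)$mm)
    names(gp) <- rois$name
    pk <- cohort_individual_peaks(cohort, "words", gp)
    tests <- peak_group_tests(pk, cohort$meta, q = config$q_fdr)
    write_tsv_prov(pk, file.path(config$out, "individual_peaks.tsv"), prov)
    write_tsv_prov(tests, file.path(config$out, "peak_anova.tsv"), prov)
    list(peaks = pk, tests = tests, group_peaks = gp)
  })

  res$mvpa <- run_stage("mvpa", function() {
    masks <- res$masks
    if (is.null(masks)) stop("mvpa stage needs the masks stage")
    eff <- list(); recs <- list()
    for (i in seq_len(nrow(rois))) {
      m <- mvpa_roi_mask(cohort$grid, c(rois$x[i], rois$y[i], rois$z[i]),
                         masks$words$mask, name = rois$name[i])
      if (is.null(m)) next
      rec <- run_pair_correlations(cohort, m, "words")
      recs[[rois$name[i]]] <- rec
      tab <- reliability_anova(rec, cohort$meta)
      tab$roi <- rois$name[i]
      eff[[rois$name[i]]] <- tab
    }
    ffa <- ffa_rois()
    for (i in seq_len(nrow(ffa))) {
      m <- mvpa_roi_mask(cohort$grid, c(ffa$x[i], ffa$y[i], ffa$z[i]),
                         masks$faces$mask, name = ffa$name[i])
      if (is.null(m)) next
      rec <- run_pair_correlations(cohort, m, "faces")
      recs[[ffa$name[i]]] <- rec
      tab <- reliability_anova(rec, cohort$meta)
      tab$roi <- ffa$name[i]
      eff[[ffa$name[i]]] <- tab
    }
    av <- do.call(rbind, eff); rownames(av) <- NULL
    av$p_fdr <- NA_real_
    for (e in unique(av$effect)) {
      ii <- av$effect == e
      av$p_fdr[ii] <- bh_fdr(av$p[ii], config$q_fdr)$p_adj
    }
    allrec <- do.call(rbind, recs); rownames(allrec) <- NULL
    write_tsv_prov(allrec, file.path(config$out, "mvpa_records.tsv"), prov)
    write_tsv_prov(av, file.path(config$out, "mvpa_anova.tsv"), prov)
    triple <- if (all(c("FFG", "L_FFA") %in% names(recs)))
      reliability_triple_anova(recs$FFG, recs$L_FFA, cohort$meta)
    if (!is.null(triple))
      write_tsv_prov(triple, file.path(config$out, "mvpa_triple_anova.tsv"), prov)
    list(records = recs, anova = av, triple = triple)
  })

  res$gradient <- run_stage("gradient", function() {
    hemis <- if (mask_size(sphere_mask(cohort$grid, c(48, -46, -16), 6)) > 0)
      c("L", "R") else "L"
    out <- list()
    for (cc in names(cohort$beta)) {
      gs <- gradient_stage(cohort, cc, hemis)
      write_tsv_prov(gs$anova,
                     file.path(config$out, paste0("gradient_", cc, "_anova.tsv")),
                     prov)
      write_tsv_prov(gs$followup,
                     file.path(config$out, paste0("gradient_", cc, "_followup.tsv")),
                     prov)
      out[[cc]] <- gs
    }
    out
  })

  sanitize <- function(x) {
    if (inherits(x, "vol_grid"))
      return(list(shape = x$shape, affine = as.vector(x$affine)))
    if (is.list(x) && !is.data.frame(x)) return(lapply(x, sanitize))
    x
  }
  cfg_json <- sanitize(config[setdiff(names(config), "out")])
  jsonlite::write_json(
    list(config = cfg_json,
         hash = fnv1a_hash(config[setdiff(names(config), "out")])),
    file.path(config$out, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(res)
}
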