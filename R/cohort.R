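# ---------------------------------------------------------------------------
# Synthetic cohort generation: 2 languages x 2 reading groups x 2 runs x
# 3 visual categories, with named pathology scenarios.
# ---------------------------------------------------------------------------

COHORT_GROUPS <- c("ZH_typical", "ZH_poor", "FR_typical", "FR_poor")
COHORT_CONDITIONS <- c("words", "faces", "houses")

#' Default analysis grid (3 mm isotropic, whole-brain bounding box)
#' @export
default_grid <- function() make_grid(c(-78, -112, -70), c(78, 76, 85), 3)

#' Reduced grid for simulation studies (32^3 voxels, ventral/temporal cortex)
#'
#' A 3 mm isotropic 32 x 32 x 32 grid covering the left ventral
#' occipito-temporal territory where the category-selective blobs and all
#' sphere ROIs used in calibration studies live. Keeping Monte-Carlo cohorts
#' on this grid makes repeated-cohort studies tractable on one CPU.
#' @export
reduced_grid <- function() make_grid(c(-72, -82, -42), c(21, 11, 51), 3)

#' Default category-selective activation blobs
#'
#' Gaussian activation foci per category at canonical ventral/temporal/frontal
#' MNI sites: words in the left fusiform (the visual word-form area) and left
#' superior temporal gyrus/sulcus; faces in bilateral fusiform (FFA); houses
#' in bilateral medial fusiform/parahippocampal cortex.
#'
#' @param base_amplitude Peak beta of the principal word blob (arbitrary units).
#' @param sd_mm Spatial standard deviation of each Gaussian blob.
#' @return data.frame with columns condition, name, x, y, z, sd_mm, amplitude.
#' @export
default_blobs <- function(base_amplitude = 1.0, sd_mm = 5) {
  data.frame(
    condition = c("words", "words", "faces", "faces", "houses", "houses"),
    name = c("L_FFG_words", "L_STS_words", "L_FFA", "R_FFA", "L_PPA", "R_PPA"),
    x = c(-48, -57, -39, 42, -30, 30),
    y = c(-57, -30, -48, -54, -48, -45),
    z = c(-15, 3, -21, -18, -6, -9),
    sd_mm = sd_mm,
    amplitude = base_amplitude * c(1.0, 0.8, 0.8, 1.0, 1.0, 1.0),
    stringsAsFactors = FALSE)
}

#' Named scenario presets for the cohort generator
#'
#' Each preset manipulates the poor-reader groups of both languages in one
#' specific way, embodying one candidate explanation of group-level
#' hypoactivation in poor readers:
#' \describe{
#'   \item{null}{no group differences (calibration scenario).}
#'   \item{amplitude}{poor readers' word-blob amplitude scaled by 0.6;
#'     location and run-to-run pattern stability untouched.}
#'   \item{dispersion}{poor readers' word-blob centre jittered with sd 6 mm
#'     (vs 2 mm); amplitude and stability untouched.}
#'   \item{instability}{poor readers' run-to-run word-pattern reliability
#'     rho = 0.2 (vs 0.8); amplitude and location untouched.}
#'   \item{mixed}{all three manipulations, mildly (multiplier 0.8,
#'     jitter 4 mm, rho 0.5).}
#' }
#' Manipulations apply to the word condition only; faces and houses always
#' use the baseline parameters, so face-pattern analyses act as a negative
#' control.
#'
#' @param name One of "null", "amplitude", "dispersion", "instability",
#'   "mixed".
#' @return A list with per-group \code{amp_multiplier}, \code{jitter_sd_mm},
#'   \code{rho}, plus \code{noise_sd}, \code{fwhm_mm}, \code{affects}.
#' @export
scenario_preset <- function(name) {
  valid <- c("null", "amplitude", "dispersion", "instability", "mixed")
  if (!is.character(name) || length(name) != 1L || !name %in% valid)
    stop("unknown scenario '", paste(name, collapse = ","),
         "'; valid scenarios: ", paste(valid, collapse = ", "))
  base <- list(
    name = name,
    amp_multiplier = setNames(rep(1, 4), COHORT_GROUPS),
    jitter_sd_mm = setNames(rep(2, 4), COHORT_GROUPS),
    rho = setNames(rep(0.8, 4), COHORT_GROUPS),
    noise_sd = 0.5,
    fwhm_mm = 6,
    affects = "words")
  poor <- grepl("_poor$", COHORT_GROUPS)
  switch(name,
    null = base,
    amplitude = { base$amp_multiplier[poor] <- 0.6; base },
    dispersion = { base$jitter_sd_mm[poor] <- 6; base },
    instability = { base$rho[poor] <- 0.2; base },
    mixed = {
      base$amp_multiplier[poor] <- 0.8
      base$jitter_sd_mm[poor] <- 4
      base$rho[poor] <- 0.5
      base
    })
}

#' Reading-score model matched to the study-design group profiles
#'
#' Group means/sds of the standardised reading score (z units): typical
#' readers around +0.7, poor readers around -1.7 (Chinese) and -2.2 (French),
#' with sds back-computed from 95 percent confidence intervals at n = 24.
#' @export
default_reading_model <- function() {
  list(mean = setNames(c(0.67, -1.74, 0.73, -2.16), COHORT_GROUPS),
       sd = setNames(c(0.46, 0.51, 0.85, 0.55), COHORT_GROUPS),
       alpha = 0.6)   # coupling between reading score and word amplitude
}

#' Specification of a synthetic cohort
#'
#' @param n_per_group Subjects per language x reading-ability cell
#'   (default 24, i.e. 96 subjects).
#' @param n_runs Runs per subject (default 2).
#' @param n_single_run Number of French subjects given only one run (to
#'   exercise run-count filtering; default 0, study-like value 9).
#' @param grid A \code{vol_grid} (default \code{default_grid()}).
#' @param blobs Blob table as from \code{default_blobs()}.
#' @param scenario A preset name or a scenario list from
#'   \code{scenario_preset()}.
#' @param reading_model As from \code{default_reading_model()}.
#' @param conditions Conditions to simulate (subset of words/faces/houses).
#' @param amplitude_tau Between-subject sd of blob amplitudes.
#' @param seed Integer master seed; per-subject substreams are derived from
#'   it by a counter scheme so subject draws are stable under cohort-size
#'   changes.
#' @export
cohort_spec <- function(n_per_group = 24, n_runs = 2, n_single_run = 0,
                        grid = default_grid(), blobs = default_blobs(),
                        scenario = "null",
                        reading_model = default_reading_model(),
                        conditions = COHORT_CONDITIONS,
                        amplitude_tau = 0.2, seed = 20201029) {
  if (is.character(scenario)) scenario <- scenario_preset(scenario)
  stopifnot(n_per_group >= 1, n_runs >= 1, n_single_run >= 0,
            all(conditions %in% COHORT_CONDITIONS),
            all(scenario$amp_multiplier >= 0), all(scenario$jitter_sd_mm >= 0),
            all(scenario$rho >= 0 & scenario$rho <= 1))
  list(n_per_group = as.integer(n_per_group), n_runs = as.integer(n_runs),
       n_single_run = as.integer(n_single_run), grid = grid, blobs = blobs,
       scenario = scenario, reading_model = reading_model,
       conditions = conditions, amplitude_tau = amplitude_tau,
       seed = as.integer(seed))
}

subject_seed <- function(master, idx) {
  as.integer((as.double(master) + 99991 * as.double(idx)) %% 2147483587)
}

# Separable evaluation of a Gaussian blob over its 4-sd bounding box.
# Returns list(linear indices, values) or NULL if outside the grid.
blob_field <- function(grid, center, sd_mm, amplitude) {
  vox <- mm_to_voxel(grid, center)
  half <- 4 * sd_mm / grid$voxel_size_mm
  lo <- pmax(ceiling(vox - half), 0); hi <- pmin(floor(vox + half), grid$shape - 1)
  if (any(lo > hi)) return(NULL)
  ax <- lapply(1:3, function(a) {
    idx <- lo[a]:hi[a]
    mmv <- grid$affine[a, a] * idx + grid$affine[a, 4]
    list(idx = idx, w = exp(-(mmv - center[a])^2 / (2 * sd_mm^2)))
  })
  w <- amplitude * as.vector(outer(outer(ax[[1]]$w, ax[[2]]$w), ax[[3]]$w))
  ijk <- as.matrix(expand.grid(ax[[1]]$idx, ax[[2]]$idx, ax[[3]]$idx))
  list(linear = ijk_to_linear(grid, ijk), values = w)
}

#' Generate a synthetic cohort
#'
#' Draws, for every subject x run x condition, a beta field equal to the sum
#' of the subject's (amplitude-scaled, jittered) category blobs, mixed across
#' runs with reliability rho, plus Gaussian measurement noise smoothed to the
#' scenario FWHM. The run-specific pattern component is multiplicative
#' (proportional to the subject's signal envelope), so instability degrades
#' pattern reproducibility without changing expected amplitude. Standard
#' errors are the analytic post-smoothing noise sd map, and t = beta / se.
#'
#' Reading scores couple to the subject's principal word-blob amplitude with
#' correlation alpha inside each group, then are shifted/scaled to the group
#' reading profile.
#'
#' @param spec A specification from \code{cohort_spec()}.
#' @return An object of class \code{cohort}: list with \code{grid},
#'   \code{meta} (subject table), \code{beta[[condition]][[run]]}
#'   (nvox x nsubj matrices), \code{se_map}, \code{truth}, \code{spec}.
#' @export
generate_cohort <- function(spec) {
  grid <- spec$grid; sc <- spec$scenario
  nvox <- n_voxels(grid)
  n <- 4L * spec$n_per_group
  groups <- rep(COHORT_GROUPS, each = spec$n_per_group)
  language <- sub("_.*", "", groups)
  reading_group <- sub(".*_", "", groups)
  id <- sprintf("sub-%03d", seq_len(n))

  # deterministic study-like sex ratios (13M/11F typical, 16M/8F poor at n=24)
  sex <- unlist(lapply(seq_len(4L), function(g) {
    nm <- round(spec$n_per_group * ifelse(grepl("poor", COHORT_GROUPS[g]), 16, 13) / 24)
    rep(c("M", "F"), c(nm, spec$n_per_group - nm))
  }), use.names = FALSE)

  n_runs_subj <- rep(spec$n_runs, n)
  if (spec$n_single_run > 0) {  # single-run subjects drawn from the French groups
    fr <- which(language == "FR")
    n_runs_subj[fr[seq_len(min(spec$n_single_run, length(fr)))]] <- 1L
  }

  conds <- spec$conditions
  blobs <- spec$blobs[spec$blobs$condition %in% conds, , drop = FALSE]
  rm_mod <- spec$reading_model
  word_amp <- numeric(n); age <- integer(n); read_z <- numeric(n)

  # one big noise matrix in (condition, run)-block column layout: smoothed
  # in a single pass and then reused as beta storage (signal added on top)
  n_fields <- length(conds) * spec$n_runs * n
  noise <- matrix(0, nvox, n_fields)
  block_col <- function(cc, r, s)
    ((match(cc, conds) - 1L) * spec$n_runs + (r - 1L)) * n + s
  sig_store <- vector("list", n_fields)  # per-field signal on its blob support

  for (s in seq_len(n)) {
    set.seed(subject_seed(spec$seed, s))
    g <- groups[s]
    age[s] <- as.integer(round(rnorm(1, 123, 10.5)))
    sig <- vector("list", length(conds)); names(sig) <- conds
    amp_first_word <- NA_real_
    for (cc in conds) {
      bl <- blobs[blobs$condition == cc, , drop = FALSE]
      affected <- cc %in% sc$affects
      mult <- if (affected) sc$amp_multiplier[[g]] else 1
      jit_sd <- if (affected) sc$jitter_sd_mm[[g]] else sc$jitter_sd_mm[["ZH_typical"]]
      idx <- integer(0); acc <- NULL
      for (b in seq_len(nrow(bl))) {
        amp <- rnorm(1, bl$amplitude[b] * mult, spec$amplitude_tau)
        jit <- rnorm(3, 0, jit_sd)
        if (cc == "words" && is.na(amp_first_word)) amp_first_word <- amp
        bf <- blob_field(grid, c(bl$x[b], bl$y[b], bl$z[b]) + jit, bl$sd_mm[b], amp)
        if (!is.null(bf)) {
          if (is.null(acc)) acc <- numeric(nvox)
          acc[bf$linear] <- acc[bf$linear] + bf$values  # overlaps sum
          idx <- c(idx, bf$linear)
        }
      }
      idx <- sort.int(unique(idx))
      sig[[cc]] <- list(idx = idx, val = if (length(idx)) acc[idx] else numeric(0))
    }
    word_amp[s] <- if (is.na(amp_first_word)) 0 else amp_first_word
    eps <- rnorm(1)
    z_amp <- (word_amp[s] - 1.0 * sc$amp_multiplier[[g]]) / spec$amplitude_tau
    read_z[s] <- rm_mod$mean[[g]] + rm_mod$sd[[g]] *
      (rm_mod$alpha * z_amp + sqrt(1 - rm_mod$alpha^2) * eps)

    for (cc in conds) {
      affected <- cc %in% sc$affects
      rho <- if (affected) sc$rho[[g]] else sc$rho[["ZH_typical"]]
      for (r in seq_len(n_runs_subj[s])) {
        # run-specific pattern component, proportional to the signal envelope
        z_run <- rnorm(length(sig[[cc]]$idx))
        run_val <- rho * sig[[cc]]$val +
          sqrt(1 - rho^2) * (sig[[cc]]$val * z_run)
        fc <- block_col(cc, r, s)
        if (sc$noise_sd > 0) noise[, fc] <- rnorm(nvox, 0, sc$noise_sd)
        sig_store[[fc]] <- list(idx = sig[[cc]]$idx, val = run_val)
      }
    }
  }

  # smooth all measurement-noise fields at once, then add signal on top and
  # slice the blocks out as the per-condition/run beta matrices
  if (sc$noise_sd > 0)
    noise <- smooth_volume(grid, noise, sc$fwhm_mm)
  beta <- lapply(conds, function(cc) vector("list", spec$n_runs))
  names(beta) <- conds
  for (cc in conds) for (r in seq_len(spec$n_runs)) {
    cols <- block_col(cc, r, seq_len(n))
    M <- noise[, cols, drop = FALSE]
    for (s in seq_len(n)) {
      st <- sig_store[[cols[s]]]
      if (!is.null(st) && length(st$idx))
        M[st$idx, s] <- M[st$idx, s] + st$val
    }
    beta[[cc]][[r]] <- M
  }

  # analytic post-smoothing noise sd map (shared across subjects/runs)
  se_map <- if (sc$noise_sd > 0) {
    sds <- sc$fwhm_mm / (2 * sqrt(2 * log(2))) / grid$voxel_size_mm
    axf <- lapply(1:3, function(a)
      rowSums(gaussian_kernel_matrix(grid$shape[a], sds[a])^2))
    sc$noise_sd * sqrt(as.vector(outer(outer(axf[[1]], axf[[2]]), axf[[3]])))
  } else rep(1e-6, nvox)  # degenerate: noiseless cohorts get a tiny floor

  meta <- data.frame(id = id, language = language,
                     reading_group = reading_group, group = groups,
                     reading_z = read_z, age_months = age, sex = sex,
                     n_runs = n_runs_subj, stringsAsFactors = FALSE)
  structure(list(grid = grid, meta = meta, beta = beta, se_map = se_map,
                 truth = data.frame(id = id, word_amplitude = word_amp),
                 spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%s), %d run(s), conditions: %s, scenario '%s'\n",
              nrow(x$meta), paste(table(x$meta$group), collapse = "/"),
              x$spec$n_runs, paste(x$spec$conditions, collapse = ","),
              x$spec$scenario$name))
  invisible(x)
}

#' Subject-level contrast volume (mean of available runs)
#'
#' @param cohort A \code{cohort}.
#' @param condition Condition name.
#' @return nvox x nsubj matrix of run-averaged betas.
#' @export
subject_betas <- function(cohort, condition) {
  stopifnot(condition %in% names(cohort$beta))
  runs <- cohort$beta[[condition]]
  out <- matrix(0, nrow(runs[[1]]), ncol(runs[[1]]))
  for (s in seq_len(ncol(out))) {
    k <- cohort$meta$n_runs[s]
    for (r in seq_len(k)) out[, s] <- out[, s] + runs[[r]][, s]
    out[, s] <- out[, s] / k
  }
  out
}

#' Per-subject t volume for one condition (beta / analytic se)
#'
#' Run-averaged beta divided by the run-averaged standard-error map.
#' @param cohort A \code{cohort}.
#' @param condition Condition name.
#' @export
subject_tvols <- function(cohort, condition) {
  b <- subject_betas(cohort, condition)
  # averaging k runs shrinks the noise se by sqrt(k)
  b / outer(cohort$se_map, 1 / sqrt(cohort$meta$n_runs))
}

#' Write a cohort to disk in a BIDS-inspired layout
#'
#' Writes \code{sub-XXX/run-R/<condition>_<beta|se|t>.nii.gz} for every
#' subject, run and condition, plus \code{participants.tsv} and
#' \code{scenario.json} (full generator provenance).
#'
#' @param cohort A \code{cohort}.
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  grid <- cohort$grid
  for (s in seq_len(nrow(cohort$meta))) {
    for (r in seq_len(cohort$meta$n_runs[s])) {
      rd <- file.path(dir, cohort$meta$id[s], sprintf("run-%d", r))
      dir.create(rd, recursive = TRUE, showWarnings = FALSE)
      for (cc in names(cohort$beta)) {
        b <- cohort$beta[[cc]][[r]][, s]
        write_volume(grid, b, file.path(rd, paste0(cc, "_beta.nii.gz")))
        write_volume(grid, cohort$se_map, file.path(rd, paste0(cc, "_se.nii.gz")))
        write_volume(grid, b / cohort$se_map, file.path(rd, paste0(cc, "_t.nii.gz")))
      }
    }
  }
  write.table(cohort$meta, file.path(dir, "participants.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sc <- cohort$spec$scenario
  jsonlite::write_json(
    list(scenario = sc, seed = cohort$spec$seed,
         n_per_group = cohort$spec$n_per_group, n_runs = cohort$spec$n_runs,
         n_single_run = cohort$spec$n_single_run,
         amplitude_tau = cohort$spec$amplitude_tau,
         blobs = cohort$spec$blobs,
         grid = list(shape = cohort$grid$shape,
                     affine = as.vector(cohort$grid$affine))),
    file.path(dir, "scenario.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort previously written by \code{write_cohort}
#'
#' @param dir Cohort directory.
#' @return A \code{cohort} object (truth table absent).
#' @export
read_cohort <- function(dir) {
  meta <- read.delim(file.path(dir, "participants.tsv"), stringsAsFactors = FALSE)
  prov <- jsonlite::read_json(file.path(dir, "scenario.json"), simplifyVector = TRUE)
  first <- list.files(file.path(dir, meta$id[1], "run-1"),
                      pattern = "_beta\\.nii", full.names = TRUE)
  v0 <- read_volume(first[1])
  grid <- v0$grid
  conds <- intersect(COHORT_CONDITIONS,
                     sub("_beta\\.nii(\\.gz)?$", "", basename(first)))
  n <- nrow(meta); n_runs <- max(meta$n_runs)
  beta <- lapply(conds, function(cc)
    lapply(seq_len(n_runs), function(r) matrix(0, n_voxels(grid), n)))
  names(beta) <- conds
  for (s in seq_len(n)) for (r in seq_len(meta$n_runs[s])) for (cc in conds) {
    f <- file.path(dir, meta$id[s], sprintf("run-%d", r), paste0(cc, "_beta.nii.gz"))
    beta[[cc]][[r]][, s] <- read_volume(f)$values
  }
  se <- read_volume(file.path(dir, meta$id[1], "run-1",
                              paste0(conds[1], "_se.nii.gz")))$values
  structure(list(grid = grid, meta = meta, beta = beta, se_map = se,
                 truth = NULL,
                 spec = list(conditions = conds, n_runs = n_runs,
                             scenario = prov$scenario, seed = prov$seed)),
            class = "cohort")
}
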