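# small grid for fast generator checks: covers the left fusiform word blob
small_grid <- function() make_grid(c(-69, -78, -36), c(-24, -33, 9), 3)

quiet_spec <- function(...) cohort_spec(grid = small_grid(), ...)

test_that("scenario presets encode the three pathology hypotheses", {
  null <- scenario_preset("null")
  expect_true(all(null$amp_multiplier == 1))
  expect_equal(length(unique(null$jitter_sd_mm)), 1L)
  expect_equal(length(unique(null$rho)), 1L)

  disp <- scenario_preset("dispersion")
  poor <- grepl("poor", names(disp$jitter_sd_mm))
  expect_true(all(disp$jitter_sd_mm[poor] > disp$jitter_sd_mm[!poor]))
  expect_true(all(disp$amp_multiplier == 1))

  inst <- scenario_preset("instability")
  expect_true(all(inst$rho[poor] < inst$rho[!poor]))
  expect_true(all(inst$amp_multiplier == 1))

  amp <- scenario_preset("amplitude")
  expect_true(all(amp$amp_multiplier[poor] < 1))

  expect_error(scenario_preset("wobble"), "null.*amplitude.*dispersion")
})

test_that("noiseless, perfectly reliable cohorts have identical runs", {
  sc <- scenario_preset("null")
  sc$noise_sd <- 0
  sc$rho[] <- 1
  sc$jitter_sd_mm[] <- 0
  co <- generate_cohort(quiet_spec(n_per_group = 2, scenario = sc,
                                   conditions = "words", seed = 4))
  expect_identical(co$beta$words[[1]], co$beta$words[[2]])
})

test_that("a zero amplitude multiplier removes the poor readers' word signal", {
  sc <- scenario_preset("amplitude")
  sc$amp_multiplier[grepl("poor", names(sc$amp_multiplier))] <- 0
  sc$jitter_sd_mm[] <- 0
  co <- generate_cohort(quiet_spec(n_per_group = 8, scenario = sc,
                                   conditions = "words", seed = 5,
                                   amplitude_tau = 0))
  sph <- sphere_mask(co$grid, c(-48, -57, -15), 6)
  m <- colMeans(subject_betas(co, "words")[sph$linear, ])
  poor <- grepl("poor", co$meta$group)
  expect_lt(abs(mean(m[poor])), 0.1)       # noise-level only
  expect_gt(mean(m[!poor]), 0.3)
})

test_that("cohorts are reproducible from the seed, including on disk", {
  a <- generate_cohort(quiet_spec(n_per_group = 2, seed = 20201029,
                                  scenario = "amplitude"))
  b <- generate_cohort(quiet_spec(n_per_group = 2, seed = 20201029,
                                  scenario = "amplitude"))
  expect_identical(a$beta, b$beta)
  expect_identical(a$meta, b$meta)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  write_cohort(a, d1); write_cohort(b, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("early subjects are unchanged when the cohort grows", {
  a <- generate_cohort(quiet_spec(n_per_group = 2, seed = 77,
                                  conditions = "words"))
  b <- generate_cohort(quiet_spec(n_per_group = 3, seed = 77,
                                  conditions = "words"))
  expect_identical(a$beta$words[[1]][, 1], b$beta$words[[1]][, 1])
  expect_identical(a$beta$words[[2]][, 2], b$beta$words[[2]][, 2])
})

test_that("the cohort layout written to disk round-trips", {
  co <- generate_cohort(quiet_spec(n_per_group = 2, seed = 9,
                                   conditions = c("words", "faces", "houses")))
  d <- file.path(tempdir(), "coh_rt")
  write_cohort(co, d)
  expect_true(file.exists(file.path(d, "participants.tsv")))
  expect_true(file.exists(file.path(d, "scenario.json")))
  expect_true(file.exists(file.path(d, "sub-001", "run-1", "words_beta.nii.gz")))
  expect_true(file.exists(file.path(d, "sub-008", "run-2", "houses_t.nii.gz")))
  back <- read_cohort(d)
  expect_equal(back$meta$reading_z, co$meta$reading_z, tolerance = 1e-6)
  expect_equal(back$beta$words[[1]][, 1], co$beta$words[[1]][, 1],
               tolerance = 1e-5)
  prov <- jsonlite::read_json(file.path(d, "scenario.json"),
                              simplifyVector = TRUE)
  expect_equal(prov$scenario$noise_sd, 0.5)
  unlink(d, recursive = TRUE)
})

test_that("extracted sphere betas track the true subject amplitudes", {
  sc <- scenario_preset("null")
  sc$noise_sd <- 0.1   # low measurement noise regime
  sc$rho[] <- 1        # isolate measurement noise from run instability
  sc$jitter_sd_mm[] <- 0
  co <- generate_cohort(quiet_spec(n_per_group = 25, scenario = sc,
                                   conditions = "words", seed = 31))
  sph <- sphere_mask(co$grid, c(-48, -57, -15), 6)
  m <- colMeans(subject_betas(co, "words")[sph$linear, ])
  expect_gt(stats::cor(m, co$truth$word_amplitude), 0.9)
})

test_that("group-mean sphere beta decreases monotonically with jitter", {
  means <- vapply(c(0, 3, 6, 9), function(j) {
    sc <- scenario_preset("null")
    sc$jitter_sd_mm[] <- j
    co <- generate_cohort(quiet_spec(n_per_group = 50, scenario = sc,
                                     conditions = "words", seed = 55))
    sph <- sphere_mask(co$grid, c(-48, -57, -15), 6)
    mean(colMeans(subject_betas(co, "words")[sph$linear, ]))
  }, 0)
  expect_true(all(diff(means) < 0))
})

test_that("run-to-run pattern correlation rises with the reliability rho", {
  z_at_rho <- vapply(c(0.1, 0.5, 0.9), function(r) {
    sc <- scenario_preset("null")
    sc$rho[] <- r
    sc$jitter_sd_mm[] <- 0
    co <- generate_cohort(quiet_spec(n_per_group = 12, scenario = sc,
                                     conditions = "words", seed = 66))
    sph <- sphere_mask(co$grid, c(-48, -57, -15), 9)
    zs <- vapply(seq_len(nrow(co$meta)), function(s)
      fisher_z(stats::cor(co$beta$words[[1]][sph$linear, s],
                          co$beta$words[[2]][sph$linear, s])), 0)
    mean(zs)
  }, 0)
  expect_true(all(diff(z_at_rho) > 0))
})

test_that("metadata matches the study design profile", {
  co <- generate_cohort(quiet_spec(n_per_group = 24, seed = 20201029,
                                   conditions = "words"))
  expect_equal(nrow(co$meta), 96L)
  expect_equal(as.vector(table(co$meta$group)), rep(24L, 4))
  gm <- tapply(co$meta$reading_z, co$meta$group, mean)
  expect_equal(unname(gm["ZH_typical"]), 0.67, tolerance = 0.35)
  expect_equal(unname(gm["FR_poor"]), -2.16, tolerance = 0.4)
  expect_true(all(gm[c("ZH_poor", "FR_poor")] < -1))
  expect_true(all(gm[c("ZH_typical", "FR_typical")] > 0.2))
  # within each group, reading scores track the true word amplitude
  wg <- vapply(split(seq_len(96), co$meta$group), function(ii)
    stats::cor(co$meta$reading_z[ii], co$truth$word_amplitude[ii]), 0)
  expect_gt(mean(wg), 0.3)
})

test_that("single-run subjects are French and counted in metadata", {
  co <- generate_cohort(quiet_spec(n_per_group = 6, n_single_run = 5,
                                   seed = 8, conditions = "words"))
  expect_equal(sum(co$meta$n_runs == 1), 5L)
  expect_true(all(co$meta$language[co$meta$n_runs == 1] == "FR"))
})
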