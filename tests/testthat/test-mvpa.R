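# a tiny cohort-like object with hand-set patterns for correlation checks
mvpa_grid <- function() make_grid(c(0, 0, 0), c(27, 27, 27), 3)

hand_cohort <- function(patterns, grid = mvpa_grid(), n_runs = 2) {
  # patterns: list of beta[[cond]][[run]] nvox x nsubj matrices
  n <- ncol(patterns[[1]][[1]])
  structure(list(
    grid = grid, beta = patterns,
    se_map = rep(1, readcircuit:::n_voxels(grid)),
    meta = data.frame(id = sprintf("sub-%03d", seq_len(n)),
                      language = rep(c("ZH", "FR"), length.out = n),
                      reading_group = rep(c("typical", "poor"), each = n / 2),
                      n_runs = n_runs),
    spec = list(conditions = names(patterns), n_runs = n_runs)),
    class = "cohort")
}

test_that("sphere-mask intersection with the preference mask is exact", {
  g <- mvpa_grid()
  sph <- sphere_mask(g, c(12, 12, 12), 9)
  everything <- readcircuit:::new_mask(g, seq_len(readcircuit:::n_voxels(g)))
  m <- mvpa_roi_mask(g, c(12, 12, 12), everything, name = "roi")
  expect_identical(m$linear, sph$linear)
  far <- sphere_mask(g, c(27, 27, 27), 3)
  expect_warning(out <- mvpa_roi_mask(g, c(3, 3, 3), far, name = "lonely"),
                 "lonely")
  expect_null(out)
})

test_that("identical run patterns hit the Fisher-z ceiling", {
  g <- mvpa_grid()
  nv <- readcircuit:::n_voxels(g)
  set.seed(8)
  base <- matrix(rnorm(nv * 4), nv, 4)
  other <- matrix(rnorm(nv * 4), nv, 4)
  pats <- list(words = list(base, base),             # run 2 == run 1
               faces = list(other, other * 0.5 + matrix(rnorm(nv * 4), nv, 4)),
               houses = list(matrix(rnorm(nv * 4), nv, 4),
                             matrix(rnorm(nv * 4), nv, 4)))
  co <- hand_cohort(pats)
  m <- sphere_mask(g, c(12, 12, 12), 9, "roi")
  rec <- run_pair_correlations(co, m, "words")
  expect_equal(rec$z_within, rep(atanh(1 - 1e-7), 4))
  expect_true(all(rec$z_within > rec$z_between))
})

test_that("independent noise patterns decorrelate and tiny patterns match cor", {
  set.seed(9)
  p1 <- rnorm(500); p2 <- rnorm(500)
  expect_lt(abs(stats::cor(p1, p2)), 0.15)

  # 5-voxel hand-built patterns against the covariance-formula oracle
  g <- make_grid(c(0, 0, 0), c(12, 3, 3), 3)   # 5 x 2 x 2 voxels
  nv <- readcircuit:::n_voxels(g)
  w1 <- c(1, 2, 3, 4, 5); w2 <- c(2, 1, 4, 3, 6)
  f2 <- c(5, 4, 3, 2, 1); h2 <- c(1, 3, 2, 5, 4)
  mk <- function(v) { out <- matrix(0, nv, 2); out[1:5, ] <- v; out }
  pats <- list(words = list(mk(w1), mk(w2)),
               faces = list(mk(rnorm(5)), mk(f2)),
               houses = list(mk(rnorm(5)), mk(h2)))
  co <- hand_cohort(pats)
  m <- readcircuit:::new_mask(g, 1:5, "hand")
  rec <- run_pair_correlations(co, m, "words")
  cov_r <- function(a, b) {
    ac <- a - mean(a); bc <- b - mean(b)
    sum(ac * bc) / sqrt(sum(ac^2) * sum(bc^2))
  }
  expect_equal(rec$r_within[1], cov_r(w1, w2), tolerance = 1e-12)
  expect_equal(rec$r_b1[1], cov_r(w1, f2), tolerance = 1e-12)
  expect_equal(rec$r_b2[1], cov_r(w1, h2), tolerance = 1e-12)
  clip <- function(r) pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  expect_equal(rec$z_between[1],
               mean(atanh(clip(c(cov_r(w1, f2), cov_r(w1, h2),
                                 cov_r(pats$faces[[1]][1:5, 1], h2))))),
               tolerance = 1e-12)
})

test_that("single-run subjects are excluded from pattern records", {
  g <- mvpa_grid()
  nv <- readcircuit:::n_voxels(g)
  set.seed(10)
  pats <- lapply(setNames(nm = c("words", "faces", "houses")), function(cc)
    list(matrix(rnorm(nv * 4), nv, 4), matrix(rnorm(nv * 4), nv, 4)))
  co <- hand_cohort(pats)
  co$meta$n_runs <- c(2, 1, 2, 2)
  m <- sphere_mask(g, c(12, 12, 12), 9, "roi")
  expect_message(rec <- run_pair_correlations(co, m, "words"), "single run")
  expect_equal(nrow(rec), 3L)
  expect_false("sub-002" %in% rec$id)
})

test_that("equal within and between z values give a zero condition effect", {
  rec <- data.frame(id = sprintf("sub-%03d", 1:16),
                    roi = "FFG", n_vox = 20,
                    z_within = rep(c(0.3, 0.5), 8),
                    z_between = rep(c(0.3, 0.5), 8), flag = FALSE)
  meta <- data.frame(id = rec$id,
                     language = rep(c("ZH", "FR"), each = 8),
                     reading_group = rep(c("typical", "poor"), 8))
  tab <- reliability_anova(rec, meta)
  expect_equal(tab$F[tab$effect == "condition"], 0)
})

test_that("the triple category x condition x group design is well formed", {
  set.seed(11)
  ids <- sprintf("sub-%03d", 1:24)
  mk <- function() data.frame(id = ids, roi = "x", n_vox = 20,
                              z_within = rnorm(24, 0.5),
                              z_between = rnorm(24, 0.1), flag = FALSE)
  meta <- data.frame(id = ids, language = rep(c("ZH", "FR"), each = 12),
                     reading_group = rep(c("typical", "poor"), 12))
  tab <- reliability_triple_anova(mk(), mk(), meta)
  expect_true("reading_group:category:condition" %in% tab$effect)
  expect_equal(unique(tab$df_den), 20)  # 24 subjects - 4 cells
})
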