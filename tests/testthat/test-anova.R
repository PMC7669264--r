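test_that("the 2x2 between ANOVA reproduces hand-computed sums of squares", {
  d <- data.frame(
    subject = sprintf("s%d", 1:8),
    language = rep(c("A", "B"), each = 4),
    reading = rep(rep(c("typ", "poor"), each = 2), 2),
    value = c(1, 3, 0, 2, 2, 4, 1, 3))
  tab <- mixed_anova(d, "value", "subject",
                     between = c("language", "reading"))
  get <- function(eff) tab[tab$effect == eff, ]
  expect_equal(get("language")$F, 1)
  expect_equal(get("language")$df_num, 1)
  expect_equal(get("language")$df_den, 4)
  expect_equal(get("reading")$F, 1)
  expect_equal(get("language:reading")$F, 0)
})

test_that("constant data yield zero F throughout", {
  d <- expand.grid(subject = sprintf("s%d", 1:8), cond = c("w", "b"))
  d$group <- rep(rep(c("t", "p"), each = 4), 2)
  d$value <- 7
  tab <- mixed_anova(d, "value", "subject", between = "group",
                     within = "cond")
  expect_true(all(tab$F == 0))
})

test_that("balanced mixed designs match the aov decomposition to 1e-10", {
  set.seed(123)
  for (i in 1:20) {
    d <- random_mixed_design(n_per_cell = sample(3:6, 1),
                             n_within = sample(2:3, 1))
    mine <- mixed_anova(d, "value", "subject", between = c("A", "B"),
                        within = "W")
    oa <- summary(stats::aov(value ~ A * B * W + Error(subject / W), data = d))
    ref <- rbind(as.data.frame(oa$`Error: subject`[[1]]),
                 as.data.frame(oa$`Error: subject:W`[[1]]))
    ref <- ref[!grepl("Residuals", rownames(ref)), ]
    key <- function(x) vapply(strsplit(trimws(x), ":"),
                              function(p) paste(sort(p), collapse = ":"), "")
    ref_F <- setNames(ref$`F value`, key(rownames(ref)))
    for (r in seq_len(nrow(mine))) {
      expect_equal(mine$F[r], unname(ref_F[key(mine$effect[r])]),
                   tolerance = 1e-10)
    }
  }
})

test_that("two-within-factor designs match aov (triple-interaction layout)", {
  set.seed(9)
  subj <- data.frame(subject = sprintf("s%d", 1:16),
                     G = rep(c("typ", "poor"), each = 8))
  d <- merge(merge(subj, data.frame(cat = c("words", "faces"))),
             data.frame(cond = c("within", "between")))
  d$value <- rnorm(nrow(d))
  mine <- mixed_anova(d, "value", "subject", between = "G",
                      within = c("cat", "cond"))
  oa <- summary(stats::aov(value ~ G * cat * cond +
                             Error(subject / (cat * cond)), data = d))
  ref <- do.call(rbind, lapply(oa, function(s) as.data.frame(s[[1]])))
  ref <- ref[!grepl("Residuals", rownames(ref)), ]
  key <- function(x) vapply(strsplit(trimws(sub(".*\\.", "", rownames(ref))), ":"),
                            function(p) paste(sort(p), collapse = ":"), "")
  # match on sorted effect names
  nm <- vapply(strsplit(trimws(gsub("^.*\\.", "", rownames(ref))), ":"),
               function(p) paste(sort(p), collapse = ":"), "")
  ref_F <- setNames(ref$`F value`, nm)
  for (r in seq_len(nrow(mine))) {
    k <- paste(sort(strsplit(mine$effect[r], ":")[[1]]), collapse = ":")
    expect_equal(mine$F[r], unname(ref_F[k]), tolerance = 1e-10)
  }
})

test_that("unbalanced between cells use N - g denominator df (87 subjects)", {
  set.seed(5)
  subj <- data.frame(
    subject = sprintf("s%03d", 1:87),
    language = c(rep("ZH", 48), rep("FR", 39)),
    reading = c(rep(c("typ", "poor"), c(24, 24)),
                rep(c("typ", "poor"), c(18, 21))))
  d <- merge(subj, data.frame(cond = c("within", "between")))
  d$value <- rnorm(nrow(d))
  tab <- suppressWarnings(
    mixed_anova(d, "value", "subject", between = c("language", "reading"),
                within = "cond"))
  expect_true(all(tab$df_den[grepl("cond", tab$effect)] == 83))
  expect_true(all(tab$df_den[!grepl("cond", tab$effect)] == 83))
  expect_warning(
    mixed_anova(d, "value", "subject", between = c("language", "reading"),
                within = "cond"), "unweighted-means")
})

test_that("F statistics are location invariant and scale invariant", {
  set.seed(77)
  d <- random_mixed_design()
  base <- mixed_anova(d, "value", "subject", between = c("A", "B"),
                      within = "W")
  d2 <- d; d2$value <- d$value + 100
  d3 <- d; d3$value <- d$value * 3.7
  shift <- mixed_anova(d2, "value", "subject", between = c("A", "B"),
                       within = "W")
  scal <- mixed_anova(d3, "value", "subject", between = c("A", "B"),
                      within = "W")
  expect_equal(base$F, shift$F, tolerance = 1e-9)
  expect_equal(base$F, scal$F, tolerance = 1e-9)
})

test_that("subjects missing within cells are dropped with a warning", {
  d <- expand.grid(subject = sprintf("s%d", 1:8), cond = c("w", "b"))
  d$group <- rep(rep(c("t", "p"), each = 4), 2)
  d$value <- rnorm(nrow(d))
  d <- d[!(d$subject == "s1" & d$cond == "b"), ]
  # dropping the subject also unbalances the between cells: two warnings
  expect_warning(
    expect_warning(
      tab <- mixed_anova(d, "value", "subject", between = "group",
                         within = "cond"),
      "dropped"),
    "unweighted-means")
  expect_true(all(tab$df_den == 5))  # 7 subjects - 2 cells
})

test_that("pearson correlation matches its closed form and cor.test", {
  x <- c(1, 2, 4, 7, 11)
  expect_equal(pearson_test(x, x)$r, 1)
  expect_equal(pearson_test(x, -x)$r, -1)
  set.seed(21)
  for (i in 1:10) {
    a <- rnorm(20); b <- rnorm(20)
    mine <- pearson_test(a, b)
    ref <- stats::cor.test(a, b)
    expect_equal(mine$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
  expect_error(pearson_test(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_test(1:2, 2:3), "at least 3")
})

test_that("fisher z is atanh with clipping at |r| = 1", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493061, tolerance = 1e-7)
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_equal(fisher_z(-1), -atanh(1 - 1e-7))
  expect_true(is.finite(fisher_z(1)))
  expect_error(fisher_z(1.2), ">")
})

test_that("BH step-up matches the definition scan and p.adjust", {
  r <- bh_fdr(rep(1, 5))
  expect_false(any(r$reject))
  r2 <- bh_fdr(c(0.001, 0.01, 0.02, 0.04), q = 0.05)
  expect_true(all(r2$reject))
  set.seed(31)
  for (i in 1:50) {
    p <- runif(sample(3:20, 1))^sample(1:3, 1)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    r <- bh_fdr(p, q)
    expect_equal(r$p_adj, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    expect_identical(r$reject, oracle_bh_reject(p, q))
    # never fewer rejections than Bonferroni
    expect_gte(sum(r$reject), sum(p <= q / length(p)))
  }
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})
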