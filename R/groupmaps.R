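# ---------------------------------------------------------------------------
# Voxelwise group statistics, permutation cluster-size correction,
# category-preference masks and group peaks.
# ---------------------------------------------------------------------------

T_CAP <- 1e6  # ceiling for t at zero-variance/degenerate voxels

#' Voxelwise t statistics over subjects
#'
#' One-sample t against zero, two-sample pooled t, or the t of a per-voxel
#' regression slope on a subject covariate. Zero-variance voxels get t = 0
#' (or the documented cap \code{1e6} for a one-sample test of a nonzero
#' constant) and are listed in \code{flagged}.
#'
#' @param X nvox x nsubj matrix of subject volumes.
#' @param design "one_sample", "two_sample" or "correlation".
#' @param group For two_sample: factor/character with two levels; t is
#'   level1 minus level2.
#' @param covariate For correlation: numeric covariate per subject.
#' @return List with \code{t}, \code{df}, \code{flagged}.
#' @export
voxelwise_t <- function(X, design = c("one_sample", "two_sample", "correlation"),
                        group = NULL, covariate = NULL) {
  design <- match.arg(design)
  n <- ncol(X)
  if (n < 3) stop("need at least 3 subjects")
  if (design == "one_sample") {
    m <- rowMeans(X)
    v <- (rowSums(X^2) - n * m^2) / (n - 1)
    v[v < 0] <- 0
    se <- sqrt(v / n)
    tval <- ifelse(se > 0, m / se, ifelse(m == 0, 0, sign(m) * T_CAP))
    list(t = pmin(pmax(tval, -T_CAP), T_CAP), df = n - 1L,
         flagged = which(se == 0))
  } else if (design == "two_sample") {
    group <- factor(group)
    if (nlevels(group) != 2) stop("two_sample needs exactly 2 group levels")
    i1 <- group == levels(group)[1]
    n1 <- sum(i1); n2 <- n - n1
    if (n1 < 2 || n2 < 2) stop("need >= 2 subjects per group")
    m1 <- rowMeans(X[, i1, drop = FALSE]); m2 <- rowMeans(X[, !i1, drop = FALSE])
    ss1 <- rowSums(X[, i1, drop = FALSE]^2) - n1 * m1^2
    ss2 <- rowSums(X[, !i1, drop = FALSE]^2) - n2 * m2^2
    sp2 <- pmax(ss1 + ss2, 0) / (n - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    tval <- ifelse(se > 0, (m1 - m2) / se, 0)
    list(t = pmin(pmax(tval, -T_CAP), T_CAP), df = n - 2L,
         flagged = which(se == 0))
  } else {
    stopifnot(length(covariate) == n)
    cc <- covariate - mean(covariate)
    sc <- sqrt(sum(cc^2))
    if (sc == 0) stop("constant covariate")
    m <- rowMeans(X)
    num <- as.vector(X %*% cc)
    ssx <- pmax(rowSums(X^2) - n * m^2, 0)
    den <- sqrt(ssx) * sc
    r <- ifelse(den > 0, num / den, 0)
    r <- pmin(pmax(r, -1), 1)
    tval <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
    list(t = pmin(pmax(tval, -T_CAP), T_CAP), df = n - 2L,
         flagged = which(den == 0))
  }
}

# members of each connected component among `supra` (linear indices)
cc_members <- function(grid, supra, connectivity) {
  if (length(supra) == 0L) return(list())
  off <- neighbour_offsets(connectivity)
  in_set <- logical(n_voxels(grid)); in_set[supra] <- TRUE
  visited <- logical(n_voxels(grid))
  sh <- grid$shape
  comps <- list()
  for (seed in supra) {
    if (visited[seed]) next
    members <- integer(0); frontier <- seed; visited[seed] <- TRUE
    while (length(frontier)) {
      members <- c(members, frontier)
      ijk <- linear_to_ijk(grid, frontier)
      cand <- matrix(0L, nrow(ijk) * nrow(off), 3)
      for (ax in 1:3)
        cand[, ax] <- rep(ijk[, ax], each = nrow(off)) + rep(off[, ax], nrow(ijk))
      ok <- cand[, 1] >= 0 & cand[, 1] < sh[1] &
            cand[, 2] >= 0 & cand[, 2] < sh[2] &
            cand[, 3] >= 0 & cand[, 3] < sh[3]
      lin <- unique(ijk_to_linear(grid, cand[ok, , drop = FALSE]))
      lin <- lin[in_set[lin] & !visited[lin]]
      visited[lin] <- TRUE
      frontier <- lin
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps
}

# nvox x n_perm matrix of permutation t statistics, computed with batched
# GEMMs (one pass over the data for all permutations)
perm_t_matrix <- function(X, design, group = NULL, covariate = NULL,
                          n_perm) {
  n <- ncol(X)
  if (design == "one_sample") {
    S <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
    M <- (X %*% S) / n
    ss <- rowSums(X^2)                       # invariant under sign flips
    V <- pmax(ss - n * M^2, 0) / (n - 1)
    SE <- sqrt(V / n)
    Tm <- M / SE
    Tm[SE == 0] <- 0
    Tm
  } else if (design == "two_sample") {
    i1_lab <- as.numeric(group == levels(group)[1])
    P <- vapply(seq_len(n_perm), function(b) i1_lab[sample.int(n)],
                numeric(n))
    n1 <- sum(i1_lab); n2 <- n - n1
    X2 <- X^2
    s_tot <- rowSums(X); q_tot <- rowSums(X2)
    S1 <- X %*% P; Q1 <- X2 %*% P
    M1 <- S1 / n1; M2 <- (s_tot - S1) / n2
    SP2 <- pmax((Q1 - n1 * M1^2) + ((q_tot - Q1) - n2 * M2^2), 0) / (n - 2)
    SE <- sqrt(SP2 * (1 / n1 + 1 / n2))
    Tm <- (M1 - M2) / SE
    Tm[SE == 0] <- 0
    Tm
  } else {
    C <- vapply(seq_len(n_perm), function(b) {
      cc <- covariate[sample.int(n)]
      cc - mean(cc)
    }, numeric(n))
    num <- X %*% C
    m <- rowMeans(X)
    ssx <- pmax(rowSums(X^2) - n * m^2, 0)
    den <- outer(sqrt(ssx), sqrt(colSums(C^2)))
    R <- num / den
    R[den == 0] <- 0
    R <- pmin(pmax(R, -1), 1)
    R * sqrt((n - 2) / pmax(1 - R^2, 1e-12))
  }
}

#' Cluster-size permutation correction of a voxelwise test
#'
#' Forms clusters at the t quantile matching \code{p_voxel} (one-sided,
#' positive tail), then builds the null distribution of the maximum cluster
#' size by sign-flipping subject volumes (one-sample), permuting group
#' labels (two-sample) or permuting the covariate (correlation). The
#' corrected cluster p value is (1 + #\{perm max >= observed size\}) /
#' (1 + n_perm), so the smallest attainable p is 1/(n_perm + 1).
#'
#' @param grid A \code{vol_grid}.
#' @param X nvox x nsubj matrix of subject volumes.
#' @param design,group,covariate As in \code{voxelwise_t}.
#' @param p_voxel Cluster-forming voxel threshold (default 0.001).
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param seed Integer seed for the permutation stream.
#' @param connectivity Cluster connectivity (default 18).
#' @return List with \code{t}, \code{df}, \code{t_threshold},
#'   \code{clusters} (each with mask, size, peak and corrected p),
#'   \code{peak_table}, \code{null_max_size}.
#' @export
cluster_correct <- function(grid, X, design = c("one_sample", "two_sample",
                                                "correlation"),
                            group = NULL, covariate = NULL,
                            p_voxel = 0.001, n_perm = 1000, seed = 1,
                            connectivity = 18L) {
  design <- match.arg(design)
  if (n_perm < 100) stop("n_perm must be >= 100")
  obs <- voxelwise_t(X, design, group = group, covariate = covariate)
  thr <- stats::qt(1 - p_voxel, obs$df)
  comps <- cc_members(grid, which(obs$t > thr), connectivity)
  sizes <- vapply(comps, length, 1L)

  if (design == "two_sample") group <- factor(group)
  set.seed(as.integer(seed))
  Tm <- perm_t_matrix(X, design, group = group, covariate = covariate,
                      n_perm = n_perm)
  null_max <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    supra <- which(Tm[, b] > thr)
    null_max[b] <- if (length(supra))
      max(vapply(cc_members(grid, supra, connectivity), length, 1L)) else 0L
  }

  clusters <- lapply(order(-sizes), function(i) {
    members <- comps[[i]]
    pk <- members[which.max(obs$t[members])]
    list(mask = new_mask(grid, members), size = length(members),
         peak_ijk = drop(linear_to_ijk(grid, pk)),
         peak_mm = voxel_to_mm(grid, drop(linear_to_ijk(grid, pk))),
         peak_t = obs$t[pk],
         p_corrected = (1 + sum(null_max >= length(members))) / (1 + n_perm))
  })
  peak_table <- if (length(clusters)) do.call(rbind, lapply(clusters, function(cl)
    data.frame(x = cl$peak_mm[1], y = cl$peak_mm[2], z = cl$peak_mm[3],
               size = cl$size, t = cl$peak_t,
               z_value = t_to_z(cl$peak_t, obs$df),
               p_corrected = cl$p_corrected)))
  else data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                  size = integer(0), t = numeric(0), z_value = numeric(0),
                  p_corrected = numeric(0))
  list(t = obs$t, df = obs$df, t_threshold = thr, clusters = clusters,
       peak_table = peak_table, null_max_size = null_max,
       correction = "permutation_max_cluster_size")
}

# standard-normal quantile equivalent of a t value (peak "Z value")
t_to_z <- function(tval, df) {
  sgn <- sign(tval)
  lp <- stats::pt(abs(tval), df, lower.tail = FALSE, log.p = TRUE)
  sgn * stats::qnorm(lp, lower.tail = FALSE, log.p = TRUE)
}

#' Per-subject category-preference contrast volumes
#'
#' Run-averaged beta of one category minus the mean of the other two
#' (weights +1, -1/2, -1/2).
#' @param cohort A \code{cohort} with all three conditions.
#' @param condition The preferred category.
#' @return nvox x nsubj matrix.
#' @export
preference_contrast <- function(cohort, condition) {
  conds <- names(cohort$beta)
  if (length(conds) < 3) stop("preference contrast needs all three conditions")
  others <- setdiff(conds, condition)
  subject_betas(cohort, condition) -
    (subject_betas(cohort, others[1]) + subject_betas(cohort, others[2])) / 2
}

#' Category-preference group mask
#'
#' Voxels preferring one category over the mean of the other two across all
#' subjects: one-sample t on the preference contrast, cluster-formed at
#' \code{p_voxel}, and (by default) restricted to clusters surviving the
#' permutation cluster-size correction at \code{p_cluster}. With
#' \code{correct = FALSE} the mask is simply all suprathreshold voxels
#' (used inside Monte-Carlo loops where a nested permutation would be
#' wasteful).
#'
#' @param cohort A \code{cohort}.
#' @param condition Preferred category.
#' @param p_voxel Voxelwise threshold (default 0.001).
#' @param p_cluster Cluster-level threshold (default 0.05).
#' @param n_perm,seed,connectivity Permutation parameters.
#' @param correct Apply cluster-size correction (default TRUE).
#' @return List with \code{mask}, \code{peak_table} (empty mask allowed,
#'   with a warning).
#' @export
category_preference_mask <- function(cohort, condition, p_voxel = 0.001,
                                     p_cluster = 0.05, n_perm = 1000,
                                     seed = 1, connectivity = 18L,
                                     correct = TRUE) {
  Xc <- preference_contrast(cohort, condition)
  grid <- cohort$grid
  if (!correct) {
    obs <- voxelwise_t(Xc, "one_sample")
    thr <- stats::qt(1 - p_voxel, obs$df)
    keep <- which(obs$t > thr)
    if (!length(keep)) warning("empty ", condition, "-preference mask")
    return(list(mask = new_mask(grid, keep, paste0(condition, "_pref")),
                peak_table = NULL, t = obs$t, df = obs$df))
  }
  res <- cluster_correct(grid, Xc, "one_sample", p_voxel = p_voxel,
                         n_perm = n_perm, seed = seed,
                         connectivity = connectivity)
  keep <- integer(0)
  for (cl in res$clusters)
    if (cl$p_corrected < p_cluster) keep <- c(keep, cl$mask$linear)
  if (!length(keep)) warning("empty ", condition, "-preference mask")
  list(mask = new_mask(grid, keep, paste0(condition, "_pref")),
       peak_table = res$peak_table, t = res$t, df = res$df)
}

#' Group peak location within a search region
#'
#' mm coordinate of the maximum of a statistic volume inside a mask or
#' within a radius of a seed; ties broken deterministically by the first
#' (lowest linear index) voxel.
#'
#' @param grid A \code{vol_grid}.
#' @param values Statistic volume (vector or 3D array).
#' @param mask Optional \code{voxel_mask} search region.
#' @param seed_mm,radius_mm Alternative search region: sphere around a seed.
#' @return List with \code{mm}, \code{ijk}, \code{value}.
#' @export
group_peak <- function(grid, values, mask = NULL, seed_mm = NULL,
                       radius_mm = NULL) {
  if (is.null(mask)) {
    if (is.null(seed_mm) || is.null(radius_mm))
      stop("provide a mask or a seed + radius")
    mask <- sphere_mask(grid, seed_mm, radius_mm)
  }
  if (mask_size(mask) == 0L) stop("empty search region for group peak")
  v <- as.vector(values)[mask$linear]
  best <- mask$linear[which.max(v)]
  ijk <- drop(linear_to_ijk(grid, best))
  list(mm = voxel_to_mm(grid, ijk), ijk = ijk, value = max(v))
}
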