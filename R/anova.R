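# ---------------------------------------------------------------------------
# Classical mixed-design ANOVA, Pearson correlation, Fisher z and
# Benjamini-Hochberg FDR, implemented from their definitions.
# ---------------------------------------------------------------------------

# Orthonormal contrast basis for a factor with l levels: l x (l-1) matrix
# with columns orthonormal and orthogonal to the constant vector.
helmert_basis <- function(l) {
  H <- stats::contr.helmert(l)
  sweep(H, 2, sqrt(colSums(H^2)), "/")
}

# Replace an array by its mean along one dim (broadcast back to full shape)
array_mean_along <- function(arr, dim_i) {
  d <- dim(arr)
  if (is.null(d)) d <- length(arr)
  others <- setdiff(seq_along(d), dim_i)
  if (length(others) == 0L) return(array(mean(arr), d))
  m <- apply(arr, others, mean)
  aperm(array(m, c(d[others], d[dim_i])), order(c(others, dim_i)))
}

#' Balanced (and unweighted-means) mixed-design ANOVA
#'
#' Classical univariate decomposition for designs with crossed
#' between-subject and within-subject factors: between effects are tested
#' against the subjects-within-groups mean square; each within effect and
#' its interactions with between factors are tested against the
#' corresponding effect-by-subject(group) mean square. For a purely
#' between-subject 2 x 2 this reduces to the standard two-way ANOVA.
#'
#' Balanced between cells give the exact textbook decomposition. Unbalanced
#' between cells (as when some subjects are excluded from a pattern
#' analysis) are handled by the classical unweighted-means solution
#' (harmonic mean cell size), with a warning; denominator degrees of
#' freedom are unchanged (N - g for g between cells). Subjects missing any
#' within-subject cell are dropped with a warning.
#'
#' @param data data.frame in long format.
#' @param dv Name of the response column.
#' @param subject Name of the subject-id column.
#' @param between Character vector of between-subject factor columns.
#' @param within Character vector of within-subject factor columns.
#' @param gg Apply a Greenhouse-Geisser correction to within-effect p values
#'   (default FALSE; all designs in this package have few within levels).
#' @return data.frame with one row per effect: effect, df_num, df_den,
#'   ss_effect, ss_error, F, p.
#' @examples
#' d <- expand.grid(subject = 1:8, cond = c("within", "between"))
#' d$group <- rep(rep(c("typ", "poor"), each = 4), 2)
#' d$value <- rnorm(nrow(d))
#' mixed_anova(d, "value", "subject", between = "group", within = "cond")
#' @export
mixed_anova <- function(data, dv = "value", subject = "subject",
                        between = character(0), within = character(0),
                        gg = FALSE) {
  stopifnot(length(between) + length(within) >= 1)
  data <- as.data.frame(data)
  for (f in c(subject, between, within)) data[[f]] <- factor(data[[f]])
  data[[subject]] <- droplevels(data[[subject]])

  # within-cell layout
  wl <- lapply(within, function(f) levels(data[[f]]))
  names(wl) <- within
  m <- prod(vapply(wl, length, 1L))
  if (m == 1 && length(within)) stop("within factors need >= 2 levels")
  wcells <- if (length(within)) {
    do.call(expand.grid, c(wl, stringsAsFactors = FALSE))
  } else data.frame(row.names = 1)

  # subject x within-cell response matrix
  subj <- levels(data[[subject]])
  key_w <- if (length(within))
    interaction(data[, within, drop = FALSE], drop = FALSE) else factor(rep(1, nrow(data)))
  cell_key <- if (length(within))
    interaction(wcells, drop = FALSE) else factor(1)
  Y <- matrix(NA_real_, length(subj), m, dimnames = list(subj, as.character(cell_key)))
  agg <- tapply(data[[dv]], list(data[[subject]], key_w), mean)
  Y[rownames(agg), colnames(agg)] <- agg
  ok <- stats::complete.cases(Y)
  if (!all(ok)) {
    warning(sum(!ok), " subject(s) dropped: missing within-subject cells")
    Y <- Y[ok, , drop = FALSE]
    subj <- subj[ok]
  }
  N <- length(subj)

  # between-cell assignment per subject
  bmap <- unique(data[, c(subject, between), drop = FALSE])
  if (anyDuplicated(bmap[[subject]]))
    stop("subjects must have a single level of every between factor")
  rownames(bmap) <- as.character(bmap[[subject]])
  bmap <- bmap[subj, , drop = FALSE]
  bl <- lapply(between, function(f) levels(data[[f]]))
  names(bl) <- between
  g <- prod(vapply(bl, length, 1L))
  bcell <- if (length(between))
    interaction(lapply(between, function(f) bmap[[f]]), drop = FALSE) else factor(rep(1, N))
  n_c <- table(bcell)
  if (any(n_c == 0)) stop("empty between-subject cell")
  balanced <- length(unique(as.integer(n_c))) == 1L
  if (!balanced)
    warning("unbalanced between-subject cells: unweighted-means solution used")
  n_h <- 1 / mean(1 / as.numeric(n_c))   # harmonic mean cell size
  if (N - g <= 0) stop("no residual degrees of freedom")

  # per-between-cell index in level-array order
  bdims <- if (length(between)) vapply(bl, length, 1L) else 1L
  bindex <- if (length(between)) {
    idx <- vapply(seq_along(between), function(i)
      as.integer(factor(bmap[[between[i]]], levels = bl[[i]])), integer(N))
    if (N == 1) idx <- matrix(idx, 1)
    1L + as.integer((idx - 1L) %*% cumprod(c(1L, head(bdims, -1L))))
  } else rep(1L, N)

  subsets <- function(x) {
    out <- list(character(0))
    for (el in x) out <- c(out, lapply(out, c, el))
    out
  }
  wsub <- subsets(within)
  bsub <- subsets(between)

  res <- list()
  ss_floor <- 1e-12 * (sum(Y^2) + 1e-300)  # numerically-zero SS threshold
  for (W in wsub) {
    # orthonormal basis spanning the W-interaction subspace of R^m
    CW <- matrix(1, 1, 1)
    for (f in within) {
      l <- length(wl[[f]])
      Bf <- if (f %in% W) helmert_basis(l) else matrix(1 / sqrt(l), l, 1)
      CW <- kronecker(Bf, CW)   # matches expand.grid order (first factor fastest)
    }
    Z <- if (length(within)) Y %*% CW else Y
    dW <- ncol(Z)

    # stratum error: subject deviations from their between-cell mean
    cellmeans_obs <- apply(Z, 2, function(z) tapply(z, bcell, mean))
    cellmeans_obs <- matrix(cellmeans_obs, ncol = dW)
    ss_err <- sum((Z - cellmeans_obs[as.integer(bcell), , drop = FALSE])^2)
    if (ss_err < ss_floor) ss_err <- 0
    df_err <- (N - g) * dW

    for (B in bsub) {
      if (length(W) == 0 && length(B) == 0) next  # grand mean
      ss <- 0
      for (q in seq_len(dW)) {
        mu <- array(0, bdims)
        mu[seq_len(g)] <- vapply(seq_len(g), function(cix)
          mean(Z[bindex == cix, q]), 0)
        if (length(B) == 0) {
          ss <- ss + n_h * g * mean(mu)^2
        } else {
          e <- mu
          if (length(between)) for (i in seq_along(between)) {
            pm <- array_mean_along(e, i)
            e <- if (between[i] %in% B) e - pm else pm
          }
          ss <- ss + n_h * sum(e^2)
        }
      }
      if (ss < ss_floor) ss <- 0
      df_num <- dW * prod(vapply(B, function(f) length(bl[[f]]) - 1L, 1L))
      Fv <- (ss / df_num) / (ss_err / df_err)
      if (!is.finite(Fv)) Fv <- if (ss <= ss_err) 0 else Inf  # degenerate data
      df_den <- df_err
      p <- stats::pf(Fv, df_num, df_den, lower.tail = FALSE)
      if (gg && length(W) > 0 && dW > 1) {
        # Greenhouse-Geisser epsilon from the stratum residual covariance
        Rz <- Z - cellmeans_obs[as.integer(bcell), , drop = FALSE]
        S <- crossprod(Rz) / (N - g)
        eps <- sum(diag(S))^2 / (dW * sum(S^2))
        p <- stats::pf(Fv, df_num * eps, df_den * eps, lower.tail = FALSE)
      }
      res[[length(res) + 1L]] <- data.frame(
        effect = paste(c(B, W), collapse = ":"),
        df_num = df_num, df_den = df_den,
        ss_effect = ss, ss_error = ss_err, F = Fv, p = p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Pearson correlation with two-sided t-based p value
#'
#' Product-moment correlation computed from its covariance definition; the
#' p value uses the exact t transform with n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (n >= 3, finite).
#' @return List with \code{r}, \code{p}, \code{n}.
#' @export
pearson_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  n <- length(x)
  xc <- x - mean(x); yc <- y - mean(y)
  sx <- sqrt(sum(xc^2)); sy <- sqrt(sum(yc^2))
  if (sx == 0 || sy == 0) stop("zero variance in correlation input")
  r <- sum(xc * yc) / (sx * sy)
  r <- max(-1, min(1, r))
  tval <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tval), n - 2), n = n)
}

#' Fisher r-to-z transform
#'
#' atanh with inputs clipped to +/- (1 - 1e-7) so that perfectly correlated
#' patterns map to a large finite z instead of infinity.
#'
#' @param r Correlation coefficient(s), |r| <= 1.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12)) stop("|r| > 1")
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

#' Benjamini-Hochberg false discovery rate (step-up)
#'
#' Adjusted p values are \code{min over j >= i of m p_(j) / j}, capped at 1
#' and mapped back to input order; rejections at level \code{q} are
#' \code{p_adj <= q}.
#'
#' @param p Vector of raw p values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return List with \code{p}, \code{p_adj}, \code{reject}, \code{q}.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (length(p) == 0) stop("empty p-value list")
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("p values must be in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  adj <- numeric(m)
  adj[o] <- pmin(adj_sorted, 1)
  list(p = p, p_adj = adj, reject = adj <= q, q = q)
}
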