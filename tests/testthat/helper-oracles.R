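# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# all-voxel distance scan for sphere membership
oracle_sphere_linear <- function(grid, center_mm, radius_mm) {
  sh <- grid$shape
  ijk <- as.matrix(expand.grid(i = 0:(sh[1] - 1), j = 0:(sh[2] - 1),
                               k = 0:(sh[3] - 1)))
  mm <- sweep(ijk %*% t(grid$affine[1:3, 1:3]), 2, grid$affine[1:3, 4], "+")
  d2 <- rowSums(sweep(mm, 2, center_mm)^2)
  keep <- which(d2 <= radius_mm^2 + 1e-9)
  sort(as.integer(ijk[keep, 1] + sh[1] * (ijk[keep, 2] + sh[2] * ijk[keep, 3]) + 1))
}

# connected components via an igraph lattice adjacency (independent of the
# package's flood fill)
oracle_cc_sizes <- function(shape, supra_linear, connectivity) {
  if (length(supra_linear) == 0) return(integer(0))
  lin0 <- supra_linear - 1L
  ijk <- cbind(lin0 %% shape[1],
               (lin0 %/% shape[1]) %% shape[2],
               lin0 %/% (shape[1] * shape[2]))
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nn <- rowSums(abs(off))
  off <- off[switch(as.character(connectivity),
                    "6" = nn == 1, "18" = nn >= 1 & nn <= 2, "26" = nn >= 1), ,
             drop = FALSE]
  key <- function(m) m[, 1] + shape[1] * (m[, 2] + shape[2] * m[, 3])
  idx <- seq_along(supra_linear)
  names(idx) <- key(ijk)
  edges <- integer(0)
  for (o in seq_len(nrow(off))) {
    nb <- sweep(ijk, 2, off[o, ], "+")
    ok <- nb[, 1] >= 0 & nb[, 1] < shape[1] & nb[, 2] >= 0 &
      nb[, 2] < shape[2] & nb[, 3] >= 0 & nb[, 3] < shape[3]
    hit <- idx[as.character(key(nb[ok, , drop = FALSE]))]
    src <- which(ok)[!is.na(hit)]
    edges <- c(edges, rbind(src, hit[!is.na(hit)]))
  }
  g <- igraph::make_graph(edges = as.integer(edges),
                          n = length(supra_linear), directed = FALSE)
  sort(as.integer(table(igraph::components(g)$membership)), decreasing = TRUE)
}

# JZS Bayes factor via the normal-slash-inverse-gamma mixture representation
# (g integrated on a fine transformed grid), an independent route from the
# package's noncentral-t quadrature
oracle_jzs_bf <- function(tval, n1, n2, width = 0.707) {
  neff <- n1 * n2 / (n1 + n2)
  nu <- n1 + n2 - 2
  f <- function(g) (1 + neff * g)^(-0.5) *
    (1 + tval^2 / ((1 + neff * g) * nu))^(-(nu + 1) / 2) *
    (width^2 / 2)^(0.5) / gamma(0.5) * g^(-1.5) * exp(-width^2 / (2 * g))
  h0 <- (1 + tval^2 / nu)^(-(nu + 1) / 2)
  u <- seq(1e-8, 1 - 1e-8, length.out = 400001)   # g = u / (1 - u)
  vals <- f(u / (1 - u)) / (1 - u)^2
  num <- sum((vals[-1] + vals[-length(vals)]) / 2 * diff(u))
  num / h0
}

# Benjamini-Hochberg by definition: largest k with p_(k) <= k q / m
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ks <- which(p[o] <= seq_len(m) * q / m)
  rej <- logical(m)
  if (length(ks)) rej[o[seq_len(max(ks))]] <- TRUE
  rej
}

# tiny balanced mixed design generator for oracle comparisons
random_mixed_design <- function(n_between_levels = c(2, 2), n_within = 2,
                                n_per_cell = 4) {
  g <- expand.grid(A = paste0("a", seq_len(n_between_levels[1])),
                   B = paste0("b", seq_len(n_between_levels[2])))
  subj <- data.frame(
    subject = sprintf("s%03d", seq_len(nrow(g) * n_per_cell)),
    A = rep(g$A, each = n_per_cell), B = rep(g$B, each = n_per_cell))
  d <- merge(subj, data.frame(W = paste0("w", seq_len(n_within))))
  d$value <- rnorm(nrow(d))
  d
}
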