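#' @importFrom stats rnorm setNames
#' @importFrom utils write.table read.delim head
NULL

# ---------------------------------------------------------------------------
# Voxel grids
# ---------------------------------------------------------------------------

#' Construct a regular voxel grid in MNI millimetre space
#'
#' Defines an axis-aligned RAS+ grid whose voxel (0,0,0) centre sits at the
#' minimum corner of the bounding box, with isotropic or anisotropic voxel
#' spacing. The affine maps 0-based voxel indices to MNI mm coordinates.
#'
#' @param box_min,box_max Numeric length-3 vectors, mm bounds per axis
#'   (min strictly less than max on each axis).
#' @param voxel_size_mm Voxel edge length(s) in mm; scalar or length 3.
#' @return An object of class \code{vol_grid} with elements \code{shape}
#'   (integer voxel counts), \code{affine} (4x4 voxel-to-mm matrix) and
#'   \code{voxel_size_mm}.
#' @examples
#' g <- make_grid(c(-78, -112, -70), c(78, 76, 85), 3)
#' g$shape  # 53 63 52
#' @export
make_grid <- function(box_min, box_max, voxel_size_mm = 3) {
  box_min <- as.numeric(box_min); box_max <- as.numeric(box_max)
  vs <- rep(as.numeric(voxel_size_mm), length.out = 3L)
  if (length(box_min) != 3L || length(box_max) != 3L)
    stop("bounding box must have 3 coordinates per corner")
  if (any(!(box_min < box_max))) stop("degenerate bounding box: need min < max on every axis")
  if (any(vs <= 0)) stop("voxel size must be positive")
  shape <- as.integer(floor((box_max - box_min) / vs) + 1)
  affine <- diag(c(vs, 1))
  affine[1:3, 4] <- box_min
  structure(list(shape = shape, affine = affine, voxel_size_mm = vs),
            class = "vol_grid")
}

#' @export
print.vol_grid <- function(x, ...) {
  cat(sprintf("<vol_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  cat(sprintf("  origin (voxel 0,0,0 centre): %.1f %.1f %.1f mm\n",
              x$affine[1, 4], x$affine[2, 4], x$affine[3, 4]))
  invisible(x)
}

n_voxels <- function(grid) prod(grid$shape)

#' Map 0-based voxel indices to MNI mm coordinates
#'
#' @param grid A \code{vol_grid}.
#' @param ijk Integer vector of length 3 or an n x 3 matrix of 0-based indices.
#' @return A numeric vector or n x 3 matrix of mm coordinates.
#' @export
voxel_to_mm <- function(grid, ijk) {
  ijk <- rbind_coords(ijk)
  out <- ijk %*% t(grid$affine[1:3, 1:3]) +
    matrix(grid$affine[1:3, 4], nrow(ijk), 3, byrow = TRUE)
  drop_coords(out, ijk)
}

#' Map MNI mm coordinates to (fractional) 0-based voxel indices
#'
#' @param grid A \code{vol_grid}.
#' @param mm Numeric vector of length 3 or an n x 3 matrix of mm coordinates.
#' @return Fractional voxel indices; round to land on a voxel centre.
#' @export
mm_to_voxel <- function(grid, mm) {
  mm <- rbind_coords(mm)
  inv <- solve(grid$affine)
  out <- mm %*% t(inv[1:3, 1:3]) + matrix(inv[1:3, 4], nrow(mm), 3, byrow = TRUE)
  drop_coords(out, mm)
}

rbind_coords <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), 1L, 3L) else {
    storage.mode(x) <- "double"
    x
  }
}
drop_coords <- function(out, input) if (nrow(input) == 1L && is.null(attr(input, "keep"))) drop(out) else out

# Linear (1-based, column-major) index of 0-based voxel triples
ijk_to_linear <- function(grid, ijk) {
  ijk <- rbind_coords(ijk)
  as.integer(ijk[, 1] + grid$shape[1] * (ijk[, 2] + grid$shape[2] * ijk[, 3]) + 1)
}

linear_to_ijk <- function(grid, lin) {
  lin0 <- as.integer(lin) - 1L
  i <- lin0 %% grid$shape[1]
  j <- (lin0 %/% grid$shape[1]) %% grid$shape[2]
  k <- lin0 %/% (grid$shape[1] * grid$shape[2])
  cbind(i, j, k)
}

grids_equal <- function(a, b) {
  identical(a$shape, b$shape) && isTRUE(all.equal(a$affine, b$affine, tolerance = 1e-9))
}

# ---------------------------------------------------------------------------
# Voxel masks
# ---------------------------------------------------------------------------

new_mask <- function(grid, lin, name = NULL) {
  lin <- sort(unique(as.integer(lin)))
  structure(list(grid = grid, linear = lin, name = name), class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask>%s %d voxels (%.0f mm^3)\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              mask_size(x), mask_volume_mm3(x)))
  invisible(x)
}

#' Number of voxels in a mask
#' @param mask A \code{voxel_mask}.
#' @export
mask_size <- function(mask) length(mask$linear)

#' Mask volume in cubic millimetres
#' @param mask A \code{voxel_mask}.
#' @export
mask_volume_mm3 <- function(mask) mask_size(mask) * prod(mask$grid$voxel_size_mm)

#' 0-based voxel index triples of a mask
#' @param mask A \code{voxel_mask}.
#' @return n x 3 integer matrix.
#' @export
mask_ijk <- function(mask) linear_to_ijk(mask$grid, mask$linear)

#' mm coordinates of mask voxel centres
#' @param mask A \code{voxel_mask}.
#' @export
mask_mm <- function(mask) {
  ijk <- mask_ijk(mask); attr(ijk, "keep") <- TRUE
  voxel_to_mm(mask$grid, ijk)
}

#' Sphere region of interest on a voxel grid
#'
#' Returns the mask of voxels whose centres lie within Euclidean distance
#' \code{radius_mm} (inclusive boundary) of \code{center_mm}. The mask may be
#' empty if the centre lies far outside the grid.
#'
#' @param grid A \code{vol_grid}.
#' @param center_mm Sphere centre, MNI mm.
#' @param radius_mm Sphere radius in mm (> 0).
#' @param name Optional ROI name carried on the mask.
#' @export
sphere_mask <- function(grid, center_mm, radius_mm, name = NULL) {
  stopifnot(radius_mm > 0)
  ctr_vox <- mm_to_voxel(grid, as.numeric(center_mm))
  vs <- grid$voxel_size_mm
  lo <- pmax(ceiling(ctr_vox - radius_mm / vs - 1e-7), 0)
  hi <- pmin(floor(ctr_vox + radius_mm / vs + 1e-7), grid$shape - 1)
  if (any(lo > hi)) return(new_mask(grid, integer(0), name))
  ijk <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
  attr(ijk, "keep") <- TRUE
  mm <- voxel_to_mm(grid, ijk)
  d2 <- rowSums(sweep(mm, 2, as.numeric(center_mm))^2)
  new_mask(grid, ijk_to_linear(grid, ijk[d2 <= radius_mm^2 + 1e-9, , drop = FALSE]), name)
}

#' Intersection of two voxel masks
#' @param a,b Masks on the same grid.
#' @export
mask_intersect <- function(a, b) {
  if (!grids_equal(a$grid, b$grid)) stop("mask grids differ; cannot intersect")
  new_mask(a$grid, intersect(a$linear, b$linear), a$name)
}

#' Union of two voxel masks
#' @param a,b Masks on the same grid.
#' @export
mask_union <- function(a, b) {
  if (!grids_equal(a$grid, b$grid)) stop("mask grids differ; cannot union")
  new_mask(a$grid, union(a$linear, b$linear), a$name)
}

#' Build a mask from a logical/numeric volume
#' @param grid A \code{vol_grid}.
#' @param values Vector or 3D array over the grid.
#' @param threshold Keep voxels with value strictly greater than this.
#' @export
mask_from_values <- function(grid, values, threshold = 0) {
  v <- as.vector(values)
  stopifnot(length(v) == n_voxels(grid))
  new_mask(grid, which(v > threshold))
}

# ---------------------------------------------------------------------------
# Connected components
# ---------------------------------------------------------------------------

neighbour_offsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be one of 6, 18, 26")
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nn <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6"  = nn == 1,
                 "18" = nn >= 1 & nn <= 2,
                 "26" = nn >= 1)
  off[keep, , drop = FALSE]
}

#' Connected components of suprathreshold voxels
#'
#' Labels maximal connected sets of voxels with \code{values > threshold}
#' under face (6), face+edge (18) or face+edge+corner (26) connectivity.
#' Clusters are sorted by size (descending), ties by peak value (descending)
#' then by lexicographic peak voxel index.
#'
#' @param grid A \code{vol_grid}.
#' @param values Numeric vector or 3D array over the grid.
#' @param threshold Cluster-forming threshold (strict).
#' @param connectivity 6, 18 or 26 (default 18, the face+edge convention).
#' @return A list of clusters; each has \code{mask}, \code{size},
#'   \code{peak_ijk} (0-based), \code{peak_value}, \code{peak_mm}.
#' @export
connected_components <- function(grid, values, threshold, connectivity = 18L) {
  v <- as.vector(values)
  stopifnot(length(v) == n_voxels(grid))
  supra <- which(v > threshold)
  if (length(supra) == 0L) return(list())
  clusters <- lapply(cc_members(grid, supra, connectivity), function(members) {
    pk <- members[which.max(v[members])]
    list(mask = new_mask(grid, members),
         size = length(members),
         peak_ijk = drop(linear_to_ijk(grid, pk)),
         peak_value = v[pk],
         peak_mm = voxel_to_mm(grid, drop(linear_to_ijk(grid, pk))))
  })
  ord <- order(-vapply(clusters, `[[`, 1L, "size"),
               -vapply(clusters, `[[`, 0, "peak_value"),
               vapply(clusters, function(cl) ijk_to_linear(grid, cl$peak_ijk), 1L))
  clusters[ord]
}

# ---------------------------------------------------------------------------
# Gaussian smoothing (separable, edge-renormalised)
# ---------------------------------------------------------------------------

gaussian_kernel_matrix <- function(n, sd_vox) {
  if (sd_vox <= 0) return(diag(n))
  d <- outer(seq_len(n), seq_len(n), `-`)
  K <- exp(-d^2 / (2 * sd_vox^2))
  K[abs(d) > ceiling(4 * sd_vox)] <- 0
  K / rowSums(K)  # edge renormalisation: constants stay constant
}

#' Smooth one or many volumes with a Gaussian kernel
#'
#' Separable Gaussian smoothing with edge renormalisation (kernel weights are
#' rescaled to sum to one inside the grid, so constant fields are preserved).
#' Operating on a matrix smooths each column as an independent volume, which
#' is how whole simulated cohorts are smoothed in one pass.
#'
#' @param grid A \code{vol_grid}.
#' @param x Numeric vector/3D array (one volume) or nvox x m matrix.
#' @param fwhm_mm Full width at half maximum of the kernel, mm.
#' @return Same shape as the input.
#' @export
smooth_volume <- function(grid, x, fwhm_mm) {
  if (fwhm_mm <= 0) return(x)
  was_vec <- is.null(dim(x)) || length(dim(x)) == 3L
  X <- if (was_vec) as.vector(x) else x
  sh <- grid$shape
  m <- length(X) / n_voxels(grid)
  stopifnot(m == round(m))
  sds <- fwhm_mm / (2 * sqrt(2 * log(2))) / grid$voxel_size_mm
  K1 <- gaussian_kernel_matrix(sh[1], sds[1])
  K2 <- gaussian_kernel_matrix(sh[2], sds[2])
  K3t <- t(gaussian_kernel_matrix(sh[3], sds[3]))
  K3 <- t(K3t)
  # per-volume cyclic rotation keeps each working array cache-resident,
  # which beats one big pass over the stacked matrix by a wide margin
  smooth_one <- function(v) {
    dim(v) <- c(sh[1], sh[2] * sh[3]); v <- K1 %*% v
    dim(v) <- sh; v <- aperm(v, c(2, 3, 1))
    dim(v) <- c(sh[2], sh[3] * sh[1]); v <- K2 %*% v
    dim(v) <- sh[c(2, 3, 1)]; v <- aperm(v, c(2, 3, 1))
    dim(v) <- c(sh[3], sh[1] * sh[2]); v <- K3 %*% v
    dim(v) <- sh[c(3, 1, 2)]; v <- aperm(v, c(2, 3, 1))
    dim(v) <- NULL
    v
  }
  if (m == 1) {
    X <- smooth_one(as.vector(X))
  } else {
    dim(X) <- c(prod(sh), m)
    for (l in seq_len(m)) X[, l] <- smooth_one(X[, l])
  }
  if (was_vec) {
    dim(X) <- NULL
    if (length(dim(x)) == 3L) dim(X) <- dim(x)
  } else dim(X) <- c(prod(sh), m)
  X
}

# ---------------------------------------------------------------------------
# NIfTI I/O (via RNifti)
# ---------------------------------------------------------------------------

grid_to_nifti <- function(grid, values) {
  arr <- array(as.vector(values), grid$shape)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- grid$voxel_size_mm
  RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
}

#' Write a volume to NIfTI-1
#'
#' Scalar volumes are stored as float32, masks as uint8; the grid affine is
#' written to both sform and qform.
#'
#' @param grid A \code{vol_grid}.
#' @param values Numeric vector or 3D array over the grid.
#' @param path Output path (.nii or .nii.gz).
#' @export
write_volume <- function(grid, values, path) {
  img <- grid_to_nifti(grid, values)
  img <- RNifti::`qform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Write a voxel mask to NIfTI-1 (uint8)
#' @param mask A \code{voxel_mask}.
#' @param path Output path.
#' @export
write_mask <- function(mask, path) {
  v <- integer(n_voxels(mask$grid))
  v[mask$linear] <- 1L
  img <- grid_to_nifti(mask$grid, v)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read a NIfTI volume together with its grid
#'
#' @param path Path to a .nii/.nii.gz file with an axis-aligned RAS+ affine.
#' @return List with \code{grid} (a \code{vol_grid}) and \code{values}
#'   (numeric vector in voxel column-major order).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4, 4))
  sh <- dim(img)[1:3]
  rot <- aff[1:3, 1:3]
  if (any(abs(rot[upper.tri(rot) | lower.tri(rot)]) > 1e-6) || any(diag(rot) <= 0))
    stop("only axis-aligned RAS+ volumes are supported: ", path)
  grid <- structure(list(shape = as.integer(sh), affine = aff,
                         voxel_size_mm = diag(rot)), class = "vol_grid")
  list(grid = grid, values = as.vector(img))
}
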