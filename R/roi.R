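# ---------------------------------------------------------------------------
# Literature-driven ROI library: foci tables, merged sphere ROIs,
# anterior-posterior sphere chains, ROI extraction.
# ---------------------------------------------------------------------------

#' Read a literature foci table
#'
#' Expected columns: region, study, x, y, z, set (and optionally note).
#' The packaged default table (\code{foci_synthetic.tsv}) is a constructed
#' stand-in with the structure of published dyslexia / Chinese-reading
#' meta-analyses (10 alphabetic-dyslexia regions plus 3 Chinese-reading
#' regions); it is synthetic, not a transcription of any study.
#'
#' @param path Path to a TSV; default the packaged synthetic table.
#' @return data.frame of foci.
#' @export
read_foci <- function(path = system.file("extdata", "foci_synthetic.tsv",
                                         package = "readcircuit")) {
  foci <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("region", "study", "x", "y", "z", "set")
  if (!all(need %in% names(foci)))
    stop("foci table must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(as.matrix(foci[, c("x", "y", "z")]))))
    stop("non-finite coordinates in foci table")
  foci
}

#' Merge literature foci into sphere ROIs
#'
#' One ROI per distinct region label; the centre is the unweighted arithmetic
#' mean of the member foci coordinates (per axis), the standard construction
#' for literature-driven sphere ROIs.
#'
#' @param foci data.frame as from \code{read_foci()}.
#' @param radius_mm Sphere radius (default 6).
#' @return data.frame with one row per region: name, x, y, z, radius_mm,
#'   n_foci, set. Rows are sorted by region name so the result does not
#'   depend on foci order.
#' @export
merge_foci <- function(foci, radius_mm = 6) {
  if (is.null(foci) || nrow(foci) == 0L) stop("empty foci table")
  if (any(is.na(foci$region) | foci$region == ""))
    stop("every focus needs a region label")
  regions <- sort(unique(foci$region))
  out <- do.call(rbind, lapply(regions, function(rg) {
    fr <- foci[foci$region == rg, , drop = FALSE]
    data.frame(name = rg, x = mean(fr$x), y = mean(fr$y), z = mean(fr$z),
               radius_mm = radius_mm, n_foci = nrow(fr),
               set = fr$set[1], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fixed fusiform face-area sphere ROIs
#'
#' The bilateral FFA ROIs are fixed spheres at (-39, -45, -18) and
#' (39, -45, -18), not foci-averaged.
#' @param radius_mm Sphere radius (default 9, the pattern-analysis radius).
#' @export
ffa_rois <- function(radius_mm = 9) {
  data.frame(name = c("L_FFA", "R_FFA"), x = c(-39, 39), y = -45, z = -18,
             radius_mm = radius_mm, n_foci = 0L, set = "face_localizer",
             stringsAsFactors = FALSE)
}

#' Build sphere masks for an ROI table
#'
#' @param rois data.frame with name/x/y/z and (unless overridden) radius_mm.
#' @param grid A \code{vol_grid}.
#' @param radius_mm Optional radius override (e.g. 9 for pattern analyses,
#'   12 for individual-peak search spheres).
#' @return Named list of \code{voxel_mask} objects.
#' @export
roi_masks <- function(rois, grid, radius_mm = NULL) {
  out <- lapply(seq_len(nrow(rois)), function(i) {
    r <- if (is.null(radius_mm)) rois$radius_mm[i] else radius_mm
    sphere_mask(grid, c(rois$x[i], rois$y[i], rois$z[i]), r, rois$name[i])
  })
  names(out) <- rois$name
  out
}

#' Anterior-posterior sphere chain along the ventral temporal cortex
#'
#' Six 6-mm spheres regularly spaced along y at the category's privileged
#' lateral position (|x| = 48 for words, 39 for faces, 30 for houses) with
#' z fixed at -16, in both hemispheres.
#'
#' @param condition "words", "faces" or "houses".
#' @return List with \code{condition}, \code{x_abs}, \code{z}, \code{y}
#'   (increasing), \code{radius_mm}, \code{hemispheres}.
#' @export
build_ap_chain <- function(condition) {
  x_abs <- switch(condition, words = 48, faces = 39, houses = 30,
                  stop("unknown condition '", condition,
                       "'; expected words, faces or houses"))
  list(condition = condition, x_abs = x_abs, z = -16,
       y = c(-73, -64, -55, -46, -37, -28), radius_mm = 6,
       hemispheres = c("L", "R"))
}

#' Sphere masks for one hemisphere of an anterior-posterior chain
#'
#' @param chain As from \code{build_ap_chain()}.
#' @param grid A \code{vol_grid}.
#' @param hemisphere "L" or "R".
#' @return List of masks named by y centre.
#' @export
chain_masks <- function(chain, grid, hemisphere = c("L", "R")) {
  hemisphere <- match.arg(hemisphere)
  x <- if (hemisphere == "L") -chain$x_abs else chain$x_abs
  out <- lapply(chain$y, function(yy)
    sphere_mask(grid, c(x, yy, chain$z), chain$radius_mm,
                sprintf("%s_%s_y%+d", chain$condition, hemisphere, yy)))
  names(out) <- sprintf("y%+d", chain$y)
  out
}

#' Mean value of a volume inside an ROI mask
#'
#' Arithmetic mean over mask voxels; NaN voxels are excluded (with a
#' message naming the ROI). Errors on an empty mask.
#'
#' @param values Numeric vector or 3D array over the mask's grid.
#' @param mask A \code{voxel_mask}.
#' @export
extract_roi_mean <- function(values, mask) {
  if (mask_size(mask) == 0L)
    stop("empty ROI mask", if (!is.null(mask$name)) paste0(" '", mask$name, "'"))
  v <- as.vector(values)[mask$linear]
  bad <- !is.finite(v)
  if (any(bad)) {
    message(sum(bad), " non-finite voxel(s) excluded from ROI ",
            if (is.null(mask$name)) "<unnamed>" else mask$name)
    v <- v[!bad]
    if (!length(v)) stop("ROI has no finite voxels")
  }
  mean(v)
}

#' Export ROI definitions as JSON
#'
#' @param rois ROI data.frame.
#' @param path Output path.
#' @export
write_roi_json <- function(rois, path) {
  jsonlite::write_json(rois, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export ROI definitions as a NIfTI label volume
#'
#' Voxels of ROI i get label i (later ROIs overwrite earlier on overlap).
#' @param rois ROI data.frame.
#' @param grid A \code{vol_grid}.
#' @param path Output path.
#' @export
write_roi_labels <- function(rois, grid, path) {
  lab <- integer(n_voxels(grid))
  masks <- roi_masks(rois, grid)
  for (i in seq_along(masks)) lab[masks[[i]]$linear] <- i
  img <- grid_to_nifti(grid, lab)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}
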