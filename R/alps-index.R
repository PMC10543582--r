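#' Per-axis diffusivity maps on a common grid
#'
#' Container for the three directional diffusion-coefficient maps a DTI fit
#' produces: Dxx (right-left), Dyy (anterior-posterior) and Dzz
#' (inferior-superior), in mm^2/s, co-registered on one voxel grid.  The
#' world mapping is a simple axis-aligned affine: the center of voxel
#' (i, j, k) (1-based) sits at `origin_mm + (c(i, j, k) - 1) * voxel_mm`.
#'
#' @param dxx,dyy,dzz 3-D numeric arrays of identical dimension.
#' @param voxel_mm Voxel spacing in mm (length 3, positive).
#' @param origin_mm World coordinate of the first voxel center (length 3).
#' @return An object of class `diffusivity_maps`.
#' @export
diffusivity_maps <- function(dxx, dyy, dzz, voxel_mm, origin_mm = c(0, 0, 0)) {
  stopifnot(length(dim(dxx)) == 3)
  if (!identical(dim(dxx), dim(dyy)) || !identical(dim(dxx), dim(dzz)))
    stop("dxx, dyy and dzz must share the same grid dimensions")
  stopifnot(length(voxel_mm) == 3, all(voxel_mm > 0), length(origin_mm) == 3)
  for (nm in c("dxx", "dyy", "dzz")) {
    v <- get(nm)
    if (!all(is.finite(v)))
      stop("non-finite values in ", nm)
  }
  n_neg <- sum(dxx < 0) + sum(dyy < 0) + sum(dzz < 0)
  strip <- function(a) array(as.numeric(a), dim(a))
  structure(list(dxx = strip(dxx), dyy = strip(dyy), dzz = strip(dzz),
                 voxel_mm = as.numeric(voxel_mm),
                 origin_mm = as.numeric(origin_mm),
                 n_negative = n_neg),
            class = "diffusivity_maps")
}

#' Read diffusivity maps from NIfTI files
#'
#' @param dxx_file,dyy_file,dzz_file Paths to the per-axis NIfTI volumes.
#' @return A [diffusivity_maps()]; voxel spacing is taken from the Dxx
#'   header (all three must agree).
#' @export
read_diffusivity_maps <- function(dxx_file, dyy_file, dzz_file) {
  imgs <- lapply(c(dxx_file, dyy_file, dzz_file), RNifti::readNifti)
  vox <- lapply(imgs, function(i) RNifti::pixdim(i)[1:3])
  if (max(abs(vox[[1]] - vox[[2]])) > 1e-6 ||
      max(abs(vox[[1]] - vox[[3]])) > 1e-6)
    stop("voxel spacings of the three axis maps disagree")
  diffusivity_maps(as.array(imgs[[1]]), as.array(imgs[[2]]),
                   as.array(imgs[[3]]), voxel_mm = vox[[1]])
}

#' @export
print.diffusivity_maps <- function(x, ...) {
  cat("Diffusivity maps (Dxx, Dyy, Dzz): grid ",
      paste(dim(x$dxx), collapse = " x "), ", voxel ",
      paste(format(x$voxel_mm), collapse = " x "), " mm\n", sep = "")
  if (x$n_negative > 0)
    cat("  note: ", x$n_negative, " negative voxel value(s)\n", sep = "")
  invisible(x)
}

#' Projection / association ROI masks per hemisphere
#'
#' The four regions the ALPS index needs: projection and association area,
#' left and right.  Masks are logical arrays on the analysis grid.
#'
#' @param projection_left,projection_right,association_left,association_right
#'   Logical 3-D arrays (or 0/1 numeric), all of the same dimension,
#'   each selecting at least one voxel.
#' @param provenance Free-text note on how the masks were produced (mask
#'   file or center+size placement).
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(projection_left, projection_right,
                    association_left, association_right,
                    provenance = "unspecified") {
  masks <- list(projection_left = projection_left,
                projection_right = projection_right,
                association_left = association_left,
                association_right = association_right)
  masks <- lapply(masks, function(m) {
    stopifnot(length(dim(m)) == 3)
    array(as.logical(m), dim(m))
  })
  d <- dim(masks[[1]])
  for (nm in names(masks)) {
    if (!identical(dim(masks[[nm]]), d))
      stop("ROI masks must share one grid; '", nm, "' differs")
    if (!any(masks[[nm]]))
      stop("ROI mask '", nm, "' is empty")
  }
  if (any(masks$projection_left & masks$projection_right) ||
      any(masks$association_left & masks$association_right))
    stop("left and right masks of the same family must not overlap")
  structure(c(masks, list(provenance = provenance)), class = "roi_set")
}

#' Read an integer-label ROI NIfTI volume
#'
#' Labels: 1 = projection-left, 2 = projection-right, 3 = association-left,
#' 4 = association-right (the convention [write_volumes_nifti()] uses).
#'
#' @param file Path to the label volume.
#' @return A [roi_set()].
#' @export
read_roi_labels <- function(file) {
  lab <- as.array(RNifti::readNifti(file))
  roi_set(lab == 1, lab == 2, lab == 3, lab == 4,
          provenance = paste0("label file: ", file))
}

#' Build a square single-slice ROI from a world-coordinate center
#'
#' Realizes an in-plane square region (the field's "5 x 5 mm^2 ROI") as a
#' reproducible placement rule: the mask is one axial slice (the slice of
#' the voxel containing `center_mm`), and a voxel is included when its
#' center falls inside the half-open square
#' \eqn{[c - s/2, c + s/2) \times [c - s/2, c + s/2)} in x and y, centered
#' on the center of the voxel containing `center_mm`.
#'
#' @param center_mm World coordinate (mm, length 3) of the intended center.
#' @param size_mm In-plane edge length (mm, > 0).
#' @param geometry A [diffusivity_maps()] object, or a list with elements
#'   `dim`, `voxel_mm` and optionally `origin_mm`.
#' @return A logical 3-D mask.
#' @export
#' @examples
#' geom <- list(dim = c(20, 20, 10), voxel_mm = c(2, 2, 2))
#' m <- build_roi_from_center(c(20, 20, 10), 5, geom)
#' sum(m)  # 9 voxels: a 3 x 3 in-plane square
build_roi_from_center <- function(center_mm, size_mm, geometry) {
  if (inherits(geometry, "diffusivity_maps"))
    geometry <- list(dim = dim(geometry$dxx), voxel_mm = geometry$voxel_mm,
                     origin_mm = geometry$origin_mm)
  dim <- geometry$dim
  vox <- geometry$voxel_mm
  org <- if (is.null(geometry$origin_mm)) c(0, 0, 0) else geometry$origin_mm
  stopifnot(length(center_mm) == 3, length(size_mm) == 1, size_mm > 0)
  # voxel whose center is nearest in each axis = voxel containing center_mm
  idx0 <- round((center_mm - org) / vox) + 1
  if (any(idx0 < 1) || any(idx0 > dim))
    stop("ROI center (", paste(center_mm, collapse = ", "),
         ") mm lies outside the grid")
  c0 <- org + (idx0 - 1) * vox  # center of the containing voxel
  mask <- array(FALSE, dim)
  rng <- vector("list", 2)
  for (ax in 1:2) {
    centers <- org[ax] + (seq_len(dim[ax]) - 1) * vox[ax]
    inside <- centers >= c0[ax] - size_mm / 2 & centers < c0[ax] + size_mm / 2
    # spilling outside the grid: the half-open square extends past the
    # first/last voxel center row
    lo <- c0[ax] - size_mm / 2
    hi <- c0[ax] + size_mm / 2
    if (lo < centers[1] - vox[ax] / 2 || hi > centers[dim[ax]] + vox[ax] / 2)
      stop("ROI of size ", size_mm, " mm at (",
           paste(center_mm, collapse = ", "), ") spills outside the grid")
    rng[[ax]] <- which(inside)
  }
  mask[rng[[1]], rng[[2]], idx0[3]] <- TRUE
  mask
}

#' ROI means of the three axis maps
#'
#' Unweighted arithmetic mean of each diffusivity map over each of the four
#' ROI masks, with voxel counts.  Negative diffusivities (possible in DTI
#' fits) are included in the means but trigger a warning.
#'
#' @param maps A [diffusivity_maps()].
#' @param rois A [roi_set()] on the same grid.
#' @return Data frame with one row per ROI: `roi`, `n_voxels`, `dxx`,
#'   `dyy`, `dzz` (mm^2/s).
#' @export
extract_roi_means <- function(maps, rois) {
  stopifnot(inherits(maps, "diffusivity_maps"), inherits(rois, "roi_set"))
  roi_names <- c("projection_left", "projection_right",
                 "association_left", "association_right")
  if (!identical(dim(maps$dxx), dim(rois$projection_left)))
    stop("geometry mismatch: maps are ",
         paste(dim(maps$dxx), collapse = "x"), ", masks are ",
         paste(dim(rois$projection_left), collapse = "x"))
  out <- data.frame(roi = roi_names, n_voxels = NA_integer_,
                    dxx = NA_real_, dyy = NA_real_, dzz = NA_real_)
  any_neg <- FALSE
  for (i in seq_along(roi_names)) {
    m <- rois[[roi_names[i]]]
    if (!any(m)) stop("ROI mask '", roi_names[i], "' is empty")
    out$n_voxels[i] <- sum(m)
    vals <- cbind(maps$dxx[m], maps$dyy[m], maps$dzz[m])
    if (any(vals < 0)) any_neg <- TRUE
    out[i, c("dxx", "dyy", "dzz")] <- colMeans(vals)
  }
  if (any_neg)
    warning("negative diffusivity voxel(s) inside ROI; included in means")
  out
}

#' ALPS index from its four regional diffusivity means
#'
#' The index is the ratio of diffusivity along the perivascular-space
#' direction (x, read in both fiber areas) to diffusivity perpendicular to
#' both the dominant fibers and the perivascular space:
#'
#' \deqn{\mathrm{ALPS} = \frac{\mathrm{mean}(D_{xx,proj},\, D_{xx,assoc})}
#'                            {\mathrm{mean}(D_{yy,proj},\, D_{zz,assoc})}.}
#'
#' A value near 1.0 indicates minimal diffusivity along the perivascular
#' space; larger values indicate greater perivascular diffusivity.  All
#' arguments are vectorized.
#'
#' @param dxx_proj,dxx_assoc Mean x-axis diffusivity in the projection and
#'   association areas (mm^2/s).
#' @param dyy_proj Mean y-axis diffusivity in the projection area.
#' @param dzz_assoc Mean z-axis diffusivity in the association area.
#' @return Numeric ALPS index (dimensionless).
#' @export
#' @examples
#' compute_alps(1.2e-3, 1.0e-3, 0.7e-3, 0.8e-3)  # 1.1/0.75 = 1.4667
compute_alps <- function(dxx_proj, dxx_assoc, dyy_proj, dzz_assoc) {
  vals <- cbind(dxx_proj, dxx_assoc, dyy_proj, dzz_assoc)
  if (!all(is.finite(vals)))
    stop("all four regional means must be finite")
  denom <- (dyy_proj + dzz_assoc) / 2
  if (any(denom <= 0))
    stop("non-physical diffusivity: mean(dyy_proj, dzz_assoc) must be > 0")
  ((dxx_proj + dxx_assoc) / 2) / denom
}

#' Per-hemisphere ALPS measurement from maps and ROIs
#'
#' Extracts the four regional means per hemisphere and forms the ALPS
#' index, independently for left and right.
#'
#' @param maps A [diffusivity_maps()].
#' @param rois A [roi_set()] on the same grid.
#' @return Data frame with one row per hemisphere: the component means
#'   `dxx_proj`, `dxx_assoc`, `dyy_proj`, `dzz_assoc` (mm^2/s), voxel
#'   counts, and `alps_index`.
#' @export
alps_measurement <- function(maps, rois) {
  means <- extract_roi_means(maps, rois)
  rownames(means) <- means$roi
  out <- data.frame(hemisphere = c("left", "right"))
  for (i in 1:2) {
    h <- out$hemisphere[i]
    proj <- means[paste0("projection_", h), ]
    asso <- means[paste0("association_", h), ]
    out$dxx_proj[i] <- proj$dxx
    out$dxx_assoc[i] <- asso$dxx
    out$dyy_proj[i] <- proj$dyy
    out$dzz_assoc[i] <- asso$dzz
    out$n_voxels_proj[i] <- proj$n_voxels
    out$n_voxels_assoc[i] <- asso$n_voxels
  }
  out$alps_index <- compute_alps(out$dxx_proj, out$dxx_assoc,
                                 out$dyy_proj, out$dzz_assoc)
  out
}
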