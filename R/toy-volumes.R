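#' Specification for toy diffusivity volumes
#'
#' Describes a synthetic brain-free test phantom for the ALPS computation:
#' three co-registered per-axis diffusivity maps (Dxx, Dyy, Dzz, mm^2/s) on
#' one grid, with axis-aligned boxes standing in for the projection and
#' association white-matter areas of each hemisphere.  Inside projection
#' boxes the dominant fibers run along z, so Dzz is boosted there; inside
#' association boxes they run along y, so Dyy is boosted.  Dxx inside every
#' box is set to the perivascular signal level, which is what the ALPS index
#' reads out.  With zero noise the downstream index equals
#' `perivascular_dxx / baseline` exactly.
#'
#' Boxes are 1-based inclusive voxel index ranges, `list(x =, y =, z =)`.
#' They must lie inside the grid and must not overlap.
#'
#' @param dim Grid size in voxels (length 3).
#' @param voxel_mm Voxel spacing in mm (length 3).
#' @param boxes Named list of four boxes: `projection_left`,
#'   `projection_right`, `association_left`, `association_right`.
#' @param baseline Background diffusivity (mm^2/s); also the value of the
#'   non-dominant in-box axes (Dyy in projection, Dzz in association).
#' @param dominant_boost Added to the dominant-axis map inside each box
#'   (mm^2/s); 0 gives a fully isotropic phantom.
#' @param perivascular_dxx Dxx value inside all four boxes (mm^2/s).
#' @param noise_sd Gaussian noise sd added voxelwise to all maps (mm^2/s);
#'   values are clipped at 0 afterwards.
#' @param seed Integer seed.
#' @return An object of class `toy_volume_spec`.
#' @seealso [generate_diffusivity_volumes()]
#' @export
toy_volume_spec <- function(dim = c(48, 48, 24),
                            voxel_mm = c(2, 2, 2),
                            boxes = list(
                              projection_left   = list(x = c(10, 14), y = c(18, 22), z = c(10, 14)),
                              projection_right  = list(x = c(34, 38), y = c(18, 22), z = c(10, 14)),
                              association_left  = list(x = c(10, 14), y = c(28, 32), z = c(10, 14)),
                              association_right = list(x = c(34, 38), y = c(28, 32), z = c(10, 14))),
                            baseline = 0.8e-3,
                            dominant_boost = 1.0e-3,
                            perivascular_dxx = 1.2e-3,
                            noise_sd = 0,
                            seed = 1L) {
  stopifnot(length(dim) == 3, length(voxel_mm) == 3, all(voxel_mm > 0),
            all(dim >= 1))
  need <- c("projection_left", "projection_right",
            "association_left", "association_right")
  if (!all(need %in% names(boxes)))
    stop("boxes must name: ", paste(need, collapse = ", "))
  boxes <- boxes[need]
  occupied <- array(FALSE, dim)
  for (nm in need) {
    b <- boxes[[nm]]
    for (ax in 1:3) {
      rng <- b[[c("x", "y", "z")[ax]]]
      if (length(rng) != 2 || rng[1] > rng[2] || rng[1] < 1 || rng[2] > dim[ax])
        stop("box '", nm, "' lies outside the grid on the ",
             c("x", "y", "z")[ax], " axis")
    }
    idx <- list(b$x[1]:b$x[2], b$y[1]:b$y[2], b$z[1]:b$z[2])
    if (any(occupied[idx[[1]], idx[[2]], idx[[3]]]))
      stop("box '", nm, "' overlaps a previously placed box")
    occupied[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  }
  stopifnot(baseline >= 0, perivascular_dxx >= 0, dominant_boost >= 0,
            noise_sd >= 0)
  structure(list(dim = as.integer(dim), voxel_mm = as.numeric(voxel_mm),
                 boxes = boxes, baseline = baseline,
                 dominant_boost = dominant_boost,
                 perivascular_dxx = perivascular_dxx,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "toy_volume_spec")
}

#' Generate toy diffusivity volumes and matching ROIs
#'
#' Builds the phantom described by a [toy_volume_spec()]: Dzz boosted in the
#' projection boxes, Dyy boosted in the association boxes, Dxx set to the
#' perivascular level inside all boxes, i.i.d. Gaussian noise added to every
#' voxel of every map, and values clipped at zero (diffusivities are
#' non-negative).  The returned ROI set marks the boxes themselves, so the
#' generator is its own ground truth for ROI means.
#'
#' @param spec A [toy_volume_spec()].
#' @return A list with elements `maps` (a [diffusivity_maps()]) and `rois`
#'   (a [roi_set()]).
#' @export
generate_diffusivity_volumes <- function(spec) {
  stopifnot(inherits(spec, "toy_volume_spec"))
  set.seed(spec$seed)
  d <- spec$dim
  dxx <- array(spec$baseline, d)
  dyy <- array(spec$baseline, d)
  dzz <- array(spec$baseline, d)
  masks <- list()
  for (nm in names(spec$boxes)) {
    b <- spec$boxes[[nm]]
    ix <- b$x[1]:b$x[2]; iy <- b$y[1]:b$y[2]; iz <- b$z[1]:b$z[2]
    m <- array(FALSE, d)
    m[ix, iy, iz] <- TRUE
    masks[[nm]] <- m
    dxx[m] <- spec$perivascular_dxx
    if (startsWith(nm, "projection")) {
      dzz[m] <- spec$baseline + spec$dominant_boost
    } else {
      dyy[m] <- spec$baseline + spec$dominant_boost
    }
  }
  if (spec$noise_sd > 0) {
    nv <- prod(d)
    dxx <- dxx + stats::rnorm(nv, 0, spec$noise_sd)
    dyy <- dyy + stats::rnorm(nv, 0, spec$noise_sd)
    dzz <- dzz + stats::rnorm(nv, 0, spec$noise_sd)
    dxx[dxx < 0] <- 0; dyy[dyy < 0] <- 0; dzz[dzz < 0] <- 0
  }
  maps <- diffusivity_maps(dxx, dyy, dzz, voxel_mm = spec$voxel_mm)
  rois <- roi_set(masks$projection_left, masks$projection_right,
                  masks$association_left, masks$association_right,
                  provenance = "toy_volume_spec")
  list(maps = maps, rois = rois)
}

#' Write diffusivity maps and ROI masks as NIfTI
#'
#' One file per axis map (`dxx.nii.gz`, `dyy.nii.gz`, `dzz.nii.gz`) plus a
#' single integer-label ROI volume (`rois.nii.gz`; 1 = projection-left,
#' 2 = projection-right, 3 = association-left, 4 = association-right), all
#' carrying the mm voxel spacing.
#'
#' @param maps A [diffusivity_maps()].
#' @param rois A [roi_set()] or `NULL`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
write_volumes_nifti <- function(maps, rois = NULL, dir) {
  stopifnot(inherits(maps, "diffusivity_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c()
  for (nm in c("dxx", "dyy", "dzz")) {
    img <- RNifti::asNifti(maps[[nm]])
    RNifti::pixdim(img) <- maps$voxel_mm
    f <- file.path(dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(img, f)
    files[nm] <- f
  }
  if (!is.null(rois)) {
    stopifnot(inherits(rois, "roi_set"))
    lab <- array(0L, dim(maps$dxx))
    roi_names <- c("projection_left", "projection_right",
                   "association_left", "association_right")
    for (i in seq_along(roi_names)) lab[rois[[roi_names[i]]]] <- i
    img <- RNifti::asNifti(lab)
    RNifti::pixdim(img) <- maps$voxel_mm
    f <- file.path(dir, "rois.nii.gz")
    RNifti::writeNifti(img, f)
    files["rois"] <- f
  }
  files
}
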