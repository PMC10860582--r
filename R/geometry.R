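#' Spherical region-of-interest mask
#'
#' Builds a 3D logical mask of voxels whose centres lie within `radius_mm`
#' of `center_mm` (millimetre coordinates; voxel i sits at
#' `(i - 1) * spacing`).
#'
#' @param dim Integer grid dimensions (length 3).
#' @param spacing Voxel spacing in mm (length 3, > 0).
#' @param center_mm Sphere centre in mm (length 3).
#' @param radius_mm Sphere radius in mm (> 0).
#' @return A logical array of dimension `dim`.
#' @export
sphere_mask <- function(dim, spacing, center_mm, radius_mm) {
  stopifnot(length(dim) == 3, length(spacing) == 3, all(spacing > 0),
            radius_mm > 0)
  cx <- (seq_len(dim[1]) - 1) * spacing[1]
  cy <- (seq_len(dim[2]) - 1) * spacing[2]
  cz <- (seq_len(dim[3]) - 1) * spacing[3]
  dx2 <- (cx - center_mm[1])^2
  dy2 <- (cy - center_mm[2])^2
  dz2 <- (cz - center_mm[3])^2
  arr <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  array(arr <= radius_mm^2, dim = dim)
}

#' Phantom grid geometry
#'
#' Defines the digital phantom every simulator shares: grid dimensions,
#' voxel spacing, and disjoint arterial and venous ROI masks (spheres by
#' default). Background voxels are everything outside both ROIs.
#'
#' @param dim Grid dimensions; default `c(24, 24, 10)`.
#' @param spacing Voxel spacing in mm; default 1 mm isotropic.
#' @param arterial_center,venous_center Sphere centres in mm.
#' @param roi_radius_mm Sphere radius in mm; the default gives ROIs of
#'   30+ voxels on the default grid.
#' @return A list of class `phantom_geometry` with elements `dim`, `spacing`,
#'   `arterial`, `venous` (logical masks).
#' @export
phantom_geometry <- function(dim = c(24L, 24L, 10L), spacing = c(1, 1, 1),
                             arterial_center = c(6, 6, 4.5),
                             venous_center = c(17, 17, 4.5),
                             roi_radius_mm = 2.1) {
  art <- sphere_mask(dim, spacing, arterial_center, roi_radius_mm)
  ven <- sphere_mask(dim, spacing, venous_center, roi_radius_mm)
  if (any(art & ven))
    stop("phantom_geometry: arterial and venous ROIs overlap", call. = FALSE)
  if (!any(art) || !any(ven))
    stop("phantom_geometry: empty ROI", call. = FALSE)
  structure(list(dim = as.integer(dim), spacing = as.numeric(spacing),
                 arterial = art, venous = ven),
            class = "phantom_geometry")
}
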