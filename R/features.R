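# Per-case morphology covariates: the clinical ellipsoid volume estimate
# and the squared transition-to-peripheral-zone signal-intensity contrast.

#' Ellipsoid prostate volume estimate
#'
#' The clinical formula `V = length * width * height * 0.52`, dimensions in
#' cm, result in cm^3.
#'
#' @param length_cm,width_cm,height_cm gland diameters in cm, all positive
#' @return estimated volume in cm^3
#' @examples
#' ellipsoid_volume(5, 4, 3) # 31.2
#' @export
ellipsoid_volume <- function(length_cm, width_cm, height_cm) {
  if (any(c(length_cm, width_cm, height_cm) <= 0) ||
      any(!is.finite(c(length_cm, width_cm, height_cm))))
    stop("all dimensions must be positive and finite", call. = FALSE)
  length_cm * width_cm * height_cm * 0.52
}

#' Squared TZ-to-PZ signal contrast
#'
#' `((SI_TZ - SI_PZ) / (SI_TZ + SI_PZ))^2`, a scale-invariant index of
#' zonal differentiation in `[0, 1]`: 0 when the zones are isointense, 1
#' when one zone has no signal.
#'
#' @param si_tz,si_pz nonnegative mean signal intensities; their sum must
#'   be positive
#' @return squared contrast in `[0, 1]`
#' @examples
#' squared_contrast(300, 100) # 0.25
#' @export
squared_contrast <- function(si_tz, si_pz) {
  if (any(c(si_tz, si_pz) < 0) || any(!is.finite(c(si_tz, si_pz))))
    stop("signal intensities must be nonnegative and finite", call. = FALSE)
  if (si_tz + si_pz <= 0)
    stop("squared contrast undefined: both signal intensities are zero",
         call. = FALSE)
  ((si_tz - si_pz) / (si_tz + si_pz))^2
}

#' Mean signal over a spherical ROI
#'
#' Averages the intensity over voxels whose centres lie within
#' `roi_radius_mm` of the centre voxel's centre (distances in mm using the
#' volume's spacing). A radius smaller than any voxel step degenerates to
#' the centre voxel's value.
#'
#' @param intensity an [intensity_volume()]
#' @param roi_center integer voxel index (1-based, length 3)
#' @param roi_radius_mm sphere radius in mm
#' @return mean intensity over the ROI
#' @export
roi_signal <- function(intensity, roi_center, roi_radius_mm = 3) {
  stopifnot(inherits(intensity, "intensity_volume"),
            length(roi_center) == 3, roi_radius_mm >= 0)
  d <- dim(intensity$voxels)
  if (any(roi_center < 1) || any(roi_center > d))
    stop("ROI centre outside the volume", call. = FALSE)
  sp <- intensity$spacing
  half <- pmin(ceiling(roi_radius_mm / sp), d - 1)
  lo <- roi_center - half; hi <- roi_center + half
  if (any(lo < 1) || any(hi > d))
    stop("ROI extends outside the volume", call. = FALSE)
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  dx <- (ii - roi_center[1]) * sp[1]
  dy <- (jj - roi_center[2]) * sp[2]
  dz <- (kk - roi_center[3]) * sp[3]
  d2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
  inside <- d2 <= roi_radius_mm^2
  inside[half[1] + 1, half[2] + 1, half[3] + 1] <- TRUE # centre voxel always in
  mean(intensity$voxels[ii, jj, kk][inside])
}

#' Deepest interior points of the TZ and PZ
#'
#' Convenience for automated ROI placement: returns, for the transition
#' zone and the peripheral zone (WG minus TZ), the voxel maximising the
#' distance to the zone's complement — the point where a spherical ROI has
#' the most room.
#'
#' @param wg,tz whole-gland and transition-zone [label_volume()]s
#' @return list with integer voxel indices `tz` and `pz` and their
#'   clearance radii in mm (`tz_clearance_mm`, `pz_clearance_mm`)
#' @export
suggest_roi_centers <- function(wg, tz) {
  pz <- derive_pz(wg, tz, tolerance = 1) # nesting enforced upstream
  deepest <- function(vol) {
    if (n_foreground(vol) == 0)
      stop("cannot place an ROI in an empty zone", call. = FALSE)
    d2 <- .edt_squared(as.vector(vol$voxels == 0L), dim(vol$voxels),
                       vol$spacing)
    k <- which.max(replace(d2, vol$voxels == 0L, -1))
    list(idx = as.integer(arrayInd(k, dim(vol$voxels))),
         clearance = sqrt(d2[k]))
  }
  t_ <- deepest(tz); p_ <- deepest(pz)
  list(tz = t_$idx, pz = p_$idx,
       tz_clearance_mm = t_$clearance, pz_clearance_mm = p_$clearance)
}

#' Gland extents along principal axes
#'
#' Mask-derived convenience for feeding [ellipsoid_volume()]: projects
#' foreground voxel centres (mm) onto the mask's principal axes and
#' returns the three extents in cm, longest first. This is a geometric
#' surrogate for calliper measurements, not a clinical protocol.
#'
#' @param vol a [label_volume()]
#' @return numeric length-3, extents in cm (decreasing)
#' @export
mask_principal_extents_cm <- function(vol) {
  stopifnot(is_label_volume(vol))
  idx <- which(vol$voxels == 1L, arr.ind = TRUE)
  if (nrow(idx) < 4) stop("mask too small for principal axes", call. = FALSE)
  xyz <- sweep(idx, 2, vol$spacing, `*`)
  pc <- stats::prcomp(xyz, center = TRUE, scale. = FALSE)
  ext <- apply(pc$x, 2, function(u) diff(range(u)))
  sort(ext, decreasing = TRUE) / 10
}
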