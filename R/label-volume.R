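#' Binary label volume
#'
#' Container for a 3D binary segmentation mask with physical voxel spacing.
#' The array uses the package's canonical axis order (x, y, z) with the
#' third axis cranio-caudal: slice index increases from the apex (caudal)
#' towards the base (cranial). Readers normalise to this convention.
#'
#' @param voxels 3D array; any nonzero value is treated as foreground.
#' @param spacing numeric length-3, physical voxel size per axis in mm.
#' @return An object of class `label_volume`: a list with integer array
#'   `voxels` (values 0/1) and numeric `spacing`.
#' @examples
#' v <- label_volume(array(c(0, 1), dim = c(4, 4, 2)), spacing = c(0.5, 0.5, 1))
#' sum(v$voxels)
#' @export
label_volume <- function(voxels, spacing) {
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array", call. = FALSE)
  if (!is.numeric(spacing) || length(spacing) != 3L || any(!is.finite(spacing)) ||
      any(spacing <= 0))
    stop("spacing must be 3 strictly positive finite values (mm)", call. = FALSE)
  v <- as.vector(voxels)
  if (anyNA(v)) stop("voxels contain NA", call. = FALSE)
  vox <- array(as.integer(v != 0), dim = dim(voxels))
  structure(list(voxels = vox, spacing = as.numeric(spacing)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<label_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, |FG| = %d\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              sum(x$voxels)))
  invisible(x)
}

is_label_volume <- function(x) inherits(x, "label_volume")

#' Scalar intensity volume
#'
#' 3D scalar image (e.g. a T2-weighted MRI) sharing geometry with the
#' case's label volumes.
#'
#' @param voxels 3D numeric array of finite signal intensities.
#' @param spacing numeric length-3 voxel size in mm.
#' @return An object of class `intensity_volume`.
#' @export
intensity_volume <- function(voxels, spacing) {
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array", call. = FALSE)
  if (!is.numeric(spacing) || length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm)", call. = FALSE)
  if (any(!is.finite(voxels)))
    stop("intensity voxels must all be finite", call. = FALSE)
  structure(list(voxels = array(as.double(voxels), dim = dim(voxels)),
                 spacing = as.numeric(spacing)),
            class = "intensity_volume")
}

#' @export
print.intensity_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<intensity_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, range [%.3g, %.3g]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

voxel_volume_mm3 <- function(vol) prod(vol$spacing)

n_foreground <- function(vol) sum(vol$voxels)

#' Mask volume in cubic centimetres
#'
#' Foreground voxel count times physical voxel volume.
#'
#' @param vol a [label_volume()]
#' @return volume in cm^3
#' @export
mask_volume_cm3 <- function(vol) {
  stopifnot(is_label_volume(vol))
  n_foreground(vol) * voxel_volume_mm3(vol) / 1000
}

check_same_geometry <- function(a, b, what = "volumes") {
  if (!identical(dim(a$voxels), dim(b$voxels)))
    stop(sprintf("%s have different array dimensions (%s vs %s)",
                 what, paste(dim(a$voxels), collapse = "x"),
                 paste(dim(b$voxels), collapse = "x")), call. = FALSE)
  if (max(abs(a$spacing - b$spacing)) > 1e-6)
    stop(sprintf("%s have different voxel spacing", what), call. = FALSE)
  invisible(TRUE)
}

#' Peripheral zone by subtraction
#'
#' The peripheral zone (with the central zone folded in) is defined as the
#' whole gland minus the transition zone: PZ = WG AND NOT TZ. The transition
#' zone is expected to be nested inside the whole gland; voxels of TZ falling
#' outside WG beyond `tolerance` (as a fraction of the TZ voxel count) raise
#' an error reporting the violation size.
#'
#' @param wg whole-gland [label_volume()]
#' @param tz transition-zone [label_volume()], same geometry
#' @param tolerance maximum tolerated fraction of TZ voxels outside WG
#'   (default 0, i.e. strict nesting)
#' @return a [label_volume()] with `|PZ| + |TZ intersect WG| = |WG|`
#' @examples
#' wg <- label_volume(array(1, c(4, 4, 4)), c(1, 1, 1))
#' tz <- label_volume(array(rep(c(1, 0), each = 32), c(4, 4, 4)), c(1, 1, 1))
#' mask_volume_cm3(derive_pz(wg, tz))
#' @export
derive_pz <- function(wg, tz, tolerance = 0) {
  stopifnot(is_label_volume(wg), is_label_volume(tz))
  check_same_geometry(wg, tz, "WG and TZ")
  outside <- sum(tz$voxels == 1L & wg$voxels == 0L)
  ntz <- n_foreground(tz)
  if (ntz > 0 && outside / ntz > tolerance)
    stop(sprintf("TZ is not nested in WG: %d TZ voxel(s) outside WG (%.2f%% > tolerance %.2f%%)",
                 outside, 100 * outside / ntz, 100 * tolerance), call. = FALSE)
  label_volume(array(as.integer(wg$voxels == 1L & tz$voxels == 0L),
                     dim = dim(wg$voxels)),
               wg$spacing)
}
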