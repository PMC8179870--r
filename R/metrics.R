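# Overlap and surface-distance metrics.
#
# Distances are supported on boundary voxels: a foreground voxel with at
# least one background face-neighbour (6-connectivity), voxels outside the
# array counting as background. "voxels" units measure Euclidean distance in
# index space (spacing ignored, as agreement tables on anisotropic MRI are
# conventionally reported); "mm" units scale each axis by its spacing.

#' Boundary voxels of a binary mask
#'
#' A voxel is boundary if it is foreground and at least one of its six
#' face neighbours is background (or outside the array).
#'
#' @param vol a [label_volume()]
#' @return logical 3D array marking boundary voxels
#' @export
boundary_mask <- function(vol) {
  v <- if (is_label_volume(vol)) vol$voxels else vol
  d <- dim(v)
  fg <- v == 1L
  has_bg <- array(FALSE, d)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  # an axis of extent 1 (a single 2D slice) contributes no neighbours, so
  # slicewise calls see the in-plane boundary
  if (nx > 1) {
    has_bg[1, , ] <- TRUE
    has_bg[nx, , ] <- TRUE
    has_bg[-nx, , ] <- has_bg[-nx, , ] | !fg[-1, , ]
    has_bg[-1, , ]  <- has_bg[-1, , ]  | !fg[-nx, , ]
  }
  if (ny > 1) {
    has_bg[, 1, ] <- TRUE
    has_bg[, ny, ] <- TRUE
    has_bg[, -ny, ] <- has_bg[, -ny, ] | !fg[, -1, ]
    has_bg[, -1, ]  <- has_bg[, -1, ]  | !fg[, -ny, ]
  }
  if (nz > 1) {
    has_bg[, , 1] <- TRUE
    has_bg[, , nz] <- TRUE
    has_bg[, , -nz] <- has_bg[, , -nz] | !fg[, , -1]
    has_bg[, , -1]  <- has_bg[, , -1]  | !fg[, , -nz]
  }
  fg & has_bg
}

metric_spacing <- function(vol, units) {
  units <- match.arg(units, c("voxels", "mm"))
  if (units == "mm") vol$spacing else c(1, 1, 1)
}

distance_support <- function(vol, support) {
  support <- match.arg(support, c("boundary", "all"))
  if (support == "boundary") boundary_mask(vol) else vol$voxels == 1L
}

#' Dice similarity coefficient
#'
#' `2|A intersect B| / (|A| + |B|)`, the standard volumetric overlap
#' agreement in `[0, 1]`.
#'
#' @param a,b [label_volume()]s with identical geometry
#' @return Dice score; errors when both masks are empty (undefined)
#' @examples
#' a <- label_volume(array(c(1, 1, 0, 0), c(4, 1, 1)), c(1, 1, 1))
#' b <- label_volume(array(c(0, 1, 1, 0), c(4, 1, 1)), c(1, 1, 1))
#' dice(a, b)
#' @export
dice <- function(a, b) {
  stopifnot(is_label_volume(a), is_label_volume(b))
  check_same_geometry(a, b, "masks")
  na <- n_foreground(a); nb <- n_foreground(b)
  if (na == 0 && nb == 0)
    stop("Dice undefined: both masks are empty", call. = FALSE)
  2 * sum(a$voxels == 1L & b$voxels == 1L) / (na + nb)
}

directed_distances <- function(a, b, units, support) {
  sup_a <- distance_support(a, support)
  sup_b <- distance_support(b, support)
  sp <- metric_spacing(a, units)
  d2 <- .edt_squared(as.vector(sup_b), dim(a$voxels), sp)
  sqrt(d2[as.vector(sup_a)])
}

check_nonempty_pair <- function(a, b, metric) {
  check_same_geometry(a, b, "masks")
  if (n_foreground(a) == 0 || n_foreground(b) == 0)
    stop(sprintf("%s undefined for an empty mask", metric), call. = FALSE)
}

#' Hausdorff distance
#'
#' Maximum of the two directed maximum distances between the masks'
#' support voxels (boundary voxels by default). `percentile < 1` gives the
#' corresponding percentile Hausdorff distance (e.g. 0.95 for HD95).
#'
#' @param a,b [label_volume()]s, both nonempty, identical geometry
#' @param units `"voxels"` (index-space distances) or `"mm"`
#' @param percentile quantile of directed distances, default 1 (exact HD)
#' @param support `"boundary"` (default) or `"all"` foreground voxels
#' @return Hausdorff distance in the requested units
#' @export
hausdorff <- function(a, b, units = c("voxels", "mm"), percentile = 1,
                      support = c("boundary", "all")) {
  units <- match.arg(units); support <- match.arg(support)
  check_nonempty_pair(a, b, "Hausdorff distance")
  stopifnot(percentile > 0, percentile <= 1)
  dab <- directed_distances(a, b, units, support)
  dba <- directed_distances(b, a, units, support)
  if (percentile >= 1) max(max(dab), max(dba))
  else max(stats::quantile(dab, percentile, names = FALSE),
           stats::quantile(dba, percentile, names = FALSE))
}

#' Average Hausdorff (mean surface) distance
#'
#' Directed mean distances `d(A,B)` (mean over A's support voxels of the
#' distance to B's support) are combined as their maximum by default,
#' matching common segmentation-evaluation tooling; `combine = "mean"`
#' gives the symmetric-mean variant.
#'
#' @inheritParams hausdorff
#' @param combine `"max"` (default) or `"mean"` of the two directed means
#' @return average Hausdorff distance in the requested units
#' @export
average_hausdorff <- function(a, b, units = c("voxels", "mm"),
                              combine = c("max", "mean"),
                              support = c("boundary", "all")) {
  units <- match.arg(units); combine <- match.arg(combine)
  support <- match.arg(support)
  check_nonempty_pair(a, b, "average Hausdorff distance")
  dab <- mean(directed_distances(a, b, units, support))
  dba <- mean(directed_distances(b, a, units, support))
  if (combine == "max") max(dab, dba) else (dab + dba) / 2
}

slice_volume <- function(vol, k) {
  d <- dim(vol$voxels)
  label_volume(array(vol$voxels[, , k], dim = c(d[1], d[2], 1L)), vol$spacing)
}

#' Slicewise (2D) agreement
#'
#' Computes the 2D metric per axial slice and averages over contributing
#' slices: for DSC, slices where both masks are nonempty contribute their
#' 2D Dice and slices where exactly one is nonempty contribute 0; for HD,
#' only slices where both are nonempty contribute. Slices empty in both
#' masks are excluded throughout.
#'
#' @param a,b [label_volume()]s with identical geometry
#' @param metric `"DSC"` or `"HD"`
#' @param units `"voxels"` or `"mm"` (in-plane spacing; HD only)
#' @param percentile,support passed to [hausdorff()]
#' @return mean per-slice metric; errors when no slice has both masks
#'   nonempty
#' @export
slicewise_metric <- function(a, b, metric = c("DSC", "HD"),
                             units = c("voxels", "mm"), percentile = 1,
                             support = c("boundary", "all")) {
  metric <- match.arg(metric); units <- match.arg(units)
  support <- match.arg(support)
  check_same_geometry(a, b, "masks")
  nz <- dim(a$voxels)[3]
  ca <- apply(a$voxels, 3, sum)
  cb <- apply(b$voxels, 3, sum)
  both <- ca > 0 & cb > 0
  one <- xor(ca > 0, cb > 0)
  if (!any(both))
    stop("no axial slice where both masks are nonempty", call. = FALSE)
  vals <- numeric(0)
  for (k in seq_len(nz)[both]) {
    sa <- slice_volume(a, k); sb <- slice_volume(b, k)
    vals <- c(vals, if (metric == "DSC") dice(sa, sb)
              else hausdorff(sa, sb, units, percentile, support))
  }
  if (metric == "DSC") vals <- c(vals, rep(0, sum(one)))
  mean(vals)
}
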