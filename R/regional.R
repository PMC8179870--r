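# Cranio-caudal regional decomposition into apex / mid-gland / base thirds.
#
# Slice index increases from apex (caudal) to base (cranial) under the
# package's axis convention, so the apex third is the low-index end of the
# extent. Slice ranges are 1-based inclusive (the R convention).

z_extent <- function(vol) {
  prof <- apply(vol$voxels, 3, sum) > 0
  if (!any(prof)) return(NULL)
  range(which(prof))
}

#' Split a comparison extent into base / mid-gland / apex thirds
#'
#' The cranio-caudal extent is the slice range containing foreground of
#' either the union (`pair_extent = "union"`, default) or the intersection
#' of the pair of masks (`limits_source = "pairwise-union"`), or of the
#' consensus mask (`limits_source = "consensus"`). An extent of `L` slices
#' is split into thirds of `floor(L/3)`, `L - 2*floor(L/3)`, `floor(L/3)`
#' slices in apex / mid-gland / base order, remainder slices going to the
#' mid-gland so the extreme regions stay equal-sized.
#'
#' @param masks list of [label_volume()]s being compared (typically a pair)
#' @param limits_source `"pairwise-union"` or `"consensus"`
#' @param reference consensus [label_volume()] (or `staple_result`),
#'   required when `limits_source = "consensus"`
#' @param pair_extent `"union"` (default) or `"intersection"` of the masks'
#'   individual extents
#' @return object of class `regional_decomposition` with the overall
#'   `extent` and 1-based inclusive slice ranges `regions$apex`,
#'   `regions$mid`, `regions$base`
#' @export
decompose <- function(masks, limits_source = c("pairwise-union", "consensus"),
                      reference = NULL, pair_extent = c("union", "intersection")) {
  limits_source <- match.arg(limits_source)
  pair_extent <- match.arg(pair_extent)
  if (limits_source == "consensus") {
    if (inherits(reference, "staple_result")) reference <- reference$consensus
    if (!is_label_volume(reference))
      stop("limits_source = 'consensus' requires a consensus reference mask",
           call. = FALSE)
    ext <- z_extent(reference)
    if (is.null(ext)) stop("consensus mask is empty", call. = FALSE)
  } else {
    exts <- lapply(masks, z_extent)
    if (any(vapply(exts, is.null, logical(1))))
      stop("cannot decompose: an input mask is empty", call. = FALSE)
    ext <- if (pair_extent == "union") {
      c(min(vapply(exts, `[`, numeric(1), 1)),
        max(vapply(exts, `[`, numeric(1), 2)))
    } else {
      c(max(vapply(exts, `[`, numeric(1), 1)),
        min(vapply(exts, `[`, numeric(1), 2)))
    }
    if (ext[1] > ext[2])
      stop("mask extents do not overlap; intersection extent is empty",
           call. = FALSE)
  }
  L <- ext[2] - ext[1] + 1
  if (L < 3)
    stop(sprintf("cranio-caudal extent of %d slice(s) is too short to split into thirds", L),
         call. = FALSE)
  n3 <- L %/% 3
  apex <- c(ext[1], ext[1] + n3 - 1)
  mid <- c(ext[1] + n3, ext[2] - n3)
  base <- c(ext[2] - n3 + 1, ext[2])
  structure(list(limits_source = limits_source, extent = ext,
                 regions = list(apex = apex, mid = mid, base = base)),
            class = "regional_decomposition")
}

#' @export
print.regional_decomposition <- function(x, ...) {
  cat(sprintf("<regional_decomposition> (%s) slices %d..%d: apex %d..%d | mid %d..%d | base %d..%d\n",
              x$limits_source, x$extent[1], x$extent[2],
              x$regions$apex[1], x$regions$apex[2],
              x$regions$mid[1], x$regions$mid[2],
              x$regions$base[1], x$regions$base[2]))
  invisible(x)
}

#' Restrict a mask to a regional slice range
#'
#' @param vol a [label_volume()]
#' @param region length-2 inclusive slice range (as in
#'   [decompose()]`$regions`)
#' @return a [label_volume()] containing only those slices
#' @export
region_submask <- function(vol, region) {
  d <- dim(vol$voxels)
  ks <- region[1]:region[2]
  label_volume(array(vol$voxels[, , ks, drop = FALSE],
                     dim = c(d[1], d[2], length(ks))), vol$spacing)
}

#' Per-region agreement metrics
#'
#' Computes the requested metric within each third. Empty-region policy:
#' when both sub-masks are empty the record is skipped (`value = NA`,
#' `reason` set); when exactly one is empty, DSC is 0 and distance metrics
#' are skipped (undefined for an empty mask).
#'
#' @param a,b [label_volume()]s
#' @param decomposition a [decompose()] result from the same comparison
#' @param metric `"DSC"`, `"HD"` or `"AHD"`
#' @param units `"voxels"` or `"mm"`
#' @param ... passed to the distance metrics
#' @return data.frame with one row per region: `region`, `value`, `reason`
#' @export
regional_metrics <- function(a, b, decomposition,
                             metric = c("DSC", "HD", "AHD"),
                             units = c("voxels", "mm"), ...) {
  metric <- match.arg(metric); units <- match.arg(units)
  stopifnot(inherits(decomposition, "regional_decomposition"))
  out <- data.frame(region = c("apex", "mid", "base"), value = NA_real_,
                    reason = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(3)) {
    rg <- decomposition$regions[[out$region[i]]]
    sa <- region_submask(a, rg); sb <- region_submask(b, rg)
    ea <- n_foreground(sa) == 0; eb <- n_foreground(sb) == 0
    if (ea && eb) {
      out$reason[i] <- "both sub-masks empty"
    } else if (ea || eb) {
      if (metric == "DSC") out$value[i] <- 0
      else out$reason[i] <- "one sub-mask empty; distance undefined"
    } else {
      out$value[i] <- switch(metric,
                             DSC = dice(sa, sb),
                             HD = hausdorff(sa, sb, units, ...),
                             AHD = average_hausdorff(sa, sb, units, ...))
    }
  }
  out
}
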