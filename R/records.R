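# MetricRecord assembly: one row per (case, structure, region, frame,
# metric) measurement, the long-format currency passed to the statistical
# layer and written to metrics.csv.

metric_record <- function(case_id, structure, region, frame, rater_a,
                          rater_b, metric, mode, units, value) {
  data.frame(case_id = case_id, structure = structure, region = region,
             frame = frame, rater_a = rater_a, rater_b = rater_b,
             metric = metric, mode = mode, units = units, value = value,
             stringsAsFactors = FALSE)
}

value_or_na <- function(expr) tryCatch(expr, error = function(e) NA_real_)

#' Agreement records for one case and structure
#'
#' Computes whole-structure 3D metrics, regional (base/mid-gland/apex)
#' metrics, and optionally slicewise metrics, for all rater pairs
#' (`frame = "pairwise"`, regional limits from the pair's union extent)
#' and, when a consensus is supplied, for each rater against the consensus
#' mask (`frame = "consensus"`, regional limits from the consensus
#' extent). DSC is 0 when exactly one regional sub-mask is empty; records
#' whose metric is undefined (both empty, or a distance with an empty
#' side) carry `NA`.
#'
#' @param masks named list of [label_volume()]s, one per rater
#' @param case_id case label
#' @param structure `"WG"` or `"TZ"`
#' @param consensus optional `staple_result` (or consensus
#'   [label_volume()])
#' @param metrics whole-structure metrics to compute
#' @param regional_metrics_set regional metrics to compute (empty vector to
#'   skip regions)
#' @param units `"voxels"` or `"mm"`
#' @param slicewise also compute slicewise DSC/HD (whole + regions)
#' @param hd_percentile,ahd_combine,support,pair_extent metric options
#' @return data.frame of metric records
#' @export
case_metric_records <- function(masks, case_id, structure,
                                consensus = NULL,
                                metrics = c("DSC", "HD", "AHD"),
                                regional_metrics_set = c("DSC", "HD"),
                                units = "voxels", slicewise = FALSE,
                                hd_percentile = 1, ahd_combine = "max",
                                support = "boundary",
                                pair_extent = "union") {
  rater_ids <- names(masks)
  stopifnot(!is.null(rater_ids), length(masks) >= 2)
  rows <- list()
  add <- function(df) rows[[length(rows) + 1]] <<- df

  whole_metric <- function(a, b, metric) {
    value_or_na(switch(metric,
      DSC = dice(a, b),
      HD = hausdorff(a, b, units, hd_percentile, support),
      AHD = average_hausdorff(a, b, units, ahd_combine, support)))
  }
  metric_units <- function(metric) if (metric == "DSC") "dimensionless" else units

  emit_frame <- function(a, b, frame, ra, rb, limits_source, reference) {
    for (m in metrics)
      add(metric_record(case_id, structure, "whole", frame, ra, rb, m,
                        "3D", metric_units(m), whole_metric(a, b, m)))
    if (length(regional_metrics_set)) {
      dec <- tryCatch(
        decompose(list(a, b), limits_source, reference, pair_extent),
        error = function(e) NULL)
      if (!is.null(dec)) {
        for (m in regional_metrics_set) {
          rg <- regional_metrics(a, b, dec, m, units,
                                 percentile = hd_percentile,
                                 support = support)
          for (i in seq_len(nrow(rg)))
            add(metric_record(case_id, structure, rg$region[i], frame,
                              ra, rb, m, "3D", metric_units(m), rg$value[i]))
        }
      }
    }
    if (slicewise) {
      for (m in intersect(c("DSC", "HD"), metrics)) {
        add(metric_record(case_id, structure, "whole", frame, ra, rb, m,
                          "slicewise", metric_units(m),
                          value_or_na(slicewise_metric(a, b, m, units,
                                                       hd_percentile,
                                                       support))))
      }
      dec <- tryCatch(
        decompose(list(a, b), limits_source, reference, pair_extent),
        error = function(e) NULL)
      if (!is.null(dec)) {
        for (regname in c("apex", "mid", "base")) {
          rg <- dec$regions[[regname]]
          sa <- region_submask(a, rg); sb <- region_submask(b, rg)
          for (m in intersect(c("DSC", "HD"), regional_metrics_set))
            add(metric_record(case_id, structure, regname, frame, ra, rb,
                              m, "slicewise", metric_units(m),
                              value_or_na(slicewise_metric(sa, sb, m, units,
                                                           hd_percentile,
                                                           support))))
        }
      }
    }
  }

  for (i in seq_along(masks)) {
    for (j in seq_along(masks)) {
      if (j <= i) next
      emit_frame(masks[[i]], masks[[j]], "pairwise",
                 rater_ids[i], rater_ids[j], "pairwise-union", NULL)
    }
  }
  if (!is.null(consensus)) {
    ref <- if (inherits(consensus, "staple_result")) consensus$consensus
           else consensus
    for (i in seq_along(masks))
      emit_frame(masks[[i]], ref, "consensus", rater_ids[i], "consensus",
                 "consensus", ref)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Agreement records and consensus results for a whole cohort
#'
#' Runs STAPLE per (case, structure) and assembles the full metric-record
#' table for both comparison frames.
#'
#' @param cohort a `synthetic_cohort` (from [simulate_cohort()]) or
#'   `rater_cohort` (from [load_cohort()], volumes loaded)
#' @param structures structures to process
#' @param staple_options list of arguments for [staple()]
#' @param ... passed to [case_metric_records()]
#' @param run_staple compute the consensus frame (default TRUE)
#' @return list with `records` (data.frame) and `consensus`
#'   (`consensus[[case_id]][[structure]]`, `staple_result`s)
#' @export
cohort_metrics <- function(cohort, structures = c("WG", "TZ"),
                           staple_options = list(), run_staple = TRUE, ...) {
  case_masks <- cohort_case_masks(cohort)
  records <- list()
  consensus <- list()
  for (cid in names(case_masks)) {
    consensus[[cid]] <- list()
    for (st in structures) {
      masks <- case_masks[[cid]][[st]]
      cons <- NULL
      if (run_staple) {
        cons <- do.call(staple, c(list(masks = masks), staple_options))
        consensus[[cid]][[st]] <- cons
      }
      records[[length(records) + 1]] <-
        case_metric_records(masks, cid, st, consensus = cons, ...)
    }
  }
  list(records = do.call(rbind, records), consensus = consensus)
}

# normalise either cohort flavour to case -> structure -> rater -> mask
cohort_case_masks <- function(cohort) {
  if (inherits(cohort, "synthetic_cohort")) {
    lapply(cohort$cases, function(cs) {
      list(WG = lapply(cs$raters, `[[`, "WG"),
           TZ = lapply(cs$raters, `[[`, "TZ"))
    })
  } else if (inherits(cohort, "rater_cohort")) {
    if (is.null(cohort$volumes))
      stop("rater_cohort was loaded without volumes", call. = FALSE)
    cohort$volumes
  } else stop("unsupported cohort object", call. = FALSE)
}

cohort_rater_groups <- function(cohort) {
  if (inherits(cohort, "synthetic_cohort")) {
    stats::setNames(cohort$spec$raters$group, cohort$spec$raters$rater_id)
  } else {
    gr <- cohort$rater_groups
    stats::setNames(as.character(gr), names(gr))
  }
}

#' Per-case morphology features of a synthetic cohort
#'
#' Computes, per case: each rater's voxel-counted mask volume, the mean
#' and median volume summaries, the ellipsoid volume estimate from the
#' truth mask's principal extents, ROI-based TZ and PZ signal intensities
#' (spherical ROIs at the zones' deepest points) and their squared
#' contrast, plus the latent true volume and contrast.
#'
#' @param cohort a `synthetic_cohort`
#' @param roi_radius_mm ROI radius in mm (shrunk per-zone when the zone is
#'   too thin)
#' @return data.frame, one row per case
#' @export
cohort_features <- function(cohort, roi_radius_mm = 3) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  rows <- lapply(names(cohort$cases), function(cid) {
    cs <- cohort$cases[[cid]]
    truth <- cs$truth
    vols <- vapply(cs$raters, function(r) mask_volume_cm3(r$WG), numeric(1))
    ext <- mask_principal_extents_cm(truth$true_wg)
    centers <- suggest_roi_centers(truth$true_wg, truth$true_tz)
    si_tz <- roi_signal(truth$intensity, centers$tz,
                        min(roi_radius_mm, centers$tz_clearance_mm))
    si_pz <- roi_signal(truth$intensity, centers$pz,
                        min(roi_radius_mm, centers$pz_clearance_mm))
    data.frame(case_id = cid,
               volume_cm3_mean = mean(vols),
               volume_cm3_median = stats::median(vols),
               volume_cm3_ellipsoid = ellipsoid_volume(ext[1], ext[2], ext[3]),
               si_tz = si_tz, si_pz = si_pz,
               squared_contrast = squared_contrast(si_tz, si_pz),
               true_volume_cm3 = truth$true_volume_cm3,
               true_contrast = truth$true_contrast,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
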