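# End-to-end study pipeline: simulate (or load) -> consensus -> metrics ->
# regional -> features -> statistics, under one reproducibility seed, with
# all tabular outputs written to an output directory.

#' Build a run configuration
#'
#' Collects every knob of the pipeline with its default. `cohort` may be a
#' [cohort_spec()] (synthetic study) or a manifest path (clinical-style
#' study). A YAML file with the same field names can be loaded with
#' [read_run_config()].
#'
#' @param cohort [cohort_spec()] or manifest file path
#' @param out_dir output directory (required by [run_study()])
#' @param seed overrides the cohort spec's seed when not `NULL`
#' @param units `"voxels"` or `"mm"` for distance metrics
#' @param hd_percentile 1 for exact HD, e.g. 0.95 for HD95
#' @param ahd_combine `"max"` or `"mean"` of directed mean distances
#' @param support `"boundary"` or `"all"` distance support
#' @param pair_extent `"union"` or `"intersection"` pairwise regional limits
#' @param staple_prior,staple_tol,staple_threshold,staple_margin STAPLE
#'   options (see [staple()])
#' @param include_2d_arm also simulate a thick-slice 2D-sequence arm on a
#'   case subset and compare 2D vs 3D (synthetic cohorts only)
#' @param n_2d cases in the 2D arm
#' @param spacing_2d voxel spacing of the 2D-sequence arm, mm
#' @param write_volumes write consensus masks as NIfTI
#' @return list of class `run_config`
#' @export
run_config <- function(cohort = cohort_spec(), out_dir = NULL, seed = NULL,
                       units = "voxels", hd_percentile = 1,
                       ahd_combine = "max", support = "boundary",
                       pair_extent = "union",
                       staple_prior = "sample-mean", staple_tol = 1e-7,
                       staple_threshold = 0.5, staple_margin = 10L,
                       include_2d_arm = FALSE, n_2d = 12,
                       spacing_2d = c(0.6, 0.6, 3.0),
                       write_volumes = FALSE) {
  cfg <- list(cohort = cohort, out_dir = out_dir, seed = seed, units = units,
              hd_percentile = hd_percentile, ahd_combine = ahd_combine,
              support = support, pair_extent = pair_extent,
              staple_prior = staple_prior, staple_tol = staple_tol,
              staple_threshold = staple_threshold,
              staple_margin = staple_margin,
              include_2d_arm = include_2d_arm, n_2d = n_2d,
              spacing_2d = spacing_2d, write_volumes = write_volumes)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Scalar pipeline fields override [run_config()] defaults; a `cohort`
#' block is passed to [cohort_spec()] (a `raters` sub-block becomes the
#' roster data.frame).
#'
#' @param path YAML file
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- if (!is.null(y$manifest)) y$manifest else {
    args <- y$cohort %||% list()
    if (!is.null(args$raters))
      args$raters <- do.call(rbind.data.frame, lapply(args$raters, as.data.frame))
    do.call(cohort_spec, args)
  }
  y$cohort <- NULL; y$manifest <- NULL
  do.call(run_config, c(list(cohort = cohort), y))
}

#' Run the full variability study
#'
#' Simulates (or loads) the cohort, estimates a STAPLE consensus per case
#' and structure, computes pairwise and consensus-frame metrics in 3D and
#' per region, derives per-case morphology features, runs the
#' nonparametric statistical layer with Holm correction per analysis
#' family, and writes `metrics.csv`, `features.csv`, `stats.csv`,
#' `report.json`, `summary.txt`, `config.json` and `run.log` to
#' `out_dir`. A run is a pure function of the configuration.
#'
#' @param config a [run_config()]
#' @param out_dir overrides `config$out_dir`
#' @return (invisibly) list with `records`, `features`, `stats`,
#'   `consensus`, `summary`, and `records_2d` when the 2D arm is enabled
#' @export
run_study <- function(config = run_config(), out_dir = config$out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(out_dir)) stop("out_dir is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  cat("", file = logf)
  log_line <- function(fmt, ...) {
    cat(sprintf(paste0(fmt, "\n"), ...), file = logf, append = TRUE)
  }

  synthetic <- inherits(config$cohort, "cohort_spec")
  cohort <- if (synthetic) {
    spec <- config$cohort
    if (!is.null(config$seed)) spec$seed <- as.integer(config$seed)
    log_line("stage=simulate n_cases=%d raters=%d seed=%d", spec$n_cases,
             nrow(spec$raters), spec$seed)
    simulate_cohort(spec)
  } else {
    log_line("stage=load manifest=%s", config$cohort)
    load_cohort(config$cohort)
  }

  staple_options <- list(prior = config$staple_prior, tol = config$staple_tol,
                         threshold = config$staple_threshold,
                         margin = config$staple_margin)
  cm <- cohort_metrics(cohort, staple_options = staple_options,
                       units = config$units,
                       hd_percentile = config$hd_percentile,
                       ahd_combine = config$ahd_combine,
                       support = config$support,
                       pair_extent = config$pair_extent)
  records <- cm$records
  for (cid in names(cm$consensus))
    for (st in names(cm$consensus[[cid]]))
      log_line("stage=consensus case=%s structure=%s iters=%d converged=%s",
               cid, st, cm$consensus[[cid]][[st]]$n_iterations,
               cm$consensus[[cid]][[st]]$converged)
  log_line("stage=metrics records=%d", nrow(records))

  features <- if (synthetic) cohort_features(cohort) else NULL
  if (!is.null(features)) log_line("stage=features cases=%d", nrow(features))

  records_2d <- NULL
  if (config$include_2d_arm) {
    if (!synthetic)
      stop("the 2D arm requires a synthetic cohort spec", call. = FALSE)
    spec2 <- cohort$spec
    spec2$n_cases <- min(config$n_2d, spec2$n_cases)
    spec2$spacing_mm <- config$spacing_2d
    spec2$sequence_type <- "2D_T2W"
    log_line("stage=simulate-2d n_cases=%d spacing=%s", spec2$n_cases,
             paste(spec2$spacing_mm, collapse = "x"))
    cohort2d <- simulate_cohort(spec2)
    records_2d <- cohort_metrics(cohort2d, staple_options = staple_options,
                                 units = config$units,
                                 hd_percentile = config$hd_percentile,
                                 ahd_combine = config$ahd_combine,
                                 support = config$support,
                                 pair_extent = config$pair_extent,
                                 slicewise = TRUE)$records
    # matching slicewise records for the 3D arm's shared cases
    sub <- cohort
    sub$cases <- sub$cases[seq_len(spec2$n_cases)]
    rec3_sw <- cohort_metrics(sub, run_staple = FALSE,
                              units = config$units,
                              hd_percentile = config$hd_percentile,
                              ahd_combine = config$ahd_combine,
                              support = config$support,
                              pair_extent = config$pair_extent,
                              slicewise = TRUE)$records
    records <- rbind(records,
                     rec3_sw[rec3_sw$mode == "slicewise", ])
  }

  stats_tab <- study_statistics(records, features,
                                cohort_rater_groups(cohort), records_2d)
  log_line("stage=stats rows=%d", nrow(stats_tab))

  summary_tab <- study_summary(records)

  utils::write.csv(records, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  if (!is.null(features))
    utils::write.csv(features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
  if (!is.null(records_2d))
    utils::write.csv(records_2d, file.path(out_dir, "metrics_2d.csv"),
                     row.names = FALSE)
  utils::write.csv(stats_tab, file.path(out_dir, "stats.csv"),
                   row.names = FALSE)
  report <- list(summary = summary_tab, stats = stats_tab)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  cfg_out <- config
  cfg_out$cohort <- if (synthetic) unclass(cohort$spec) else config$cohort
  jsonlite::write_json(unclass(cfg_out), file.path(out_dir, "config.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  write_summary_text(summary_tab, stats_tab, file.path(out_dir, "summary.txt"))

  if (config$write_volumes && length(cm$consensus)) {
    cdir <- file.path(out_dir, "consensus")
    dir.create(cdir, showWarnings = FALSE)
    for (cid in names(cm$consensus))
      for (st in names(cm$consensus[[cid]]))
        write_volume(cm$consensus[[cid]][[st]]$consensus,
                     file.path(cdir, sprintf("%s_%s.nii.gz", cid, st)))
  }
  log_line("stage=done")
  invisible(list(records = records, features = features, stats = stats_tab,
                 consensus = cm$consensus, summary = summary_tab,
                 records_2d = records_2d))
}

# grand mean +/- SD per (structure, region, frame, metric), case-mean first
study_summary <- function(records) {
  r <- records[!is.na(records$value) & records$mode == "3D", ]
  keys <- unique(r[, c("structure", "region", "frame", "metric", "units")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    s <- r[r$structure == k$structure & r$region == k$region &
             r$frame == k$frame & r$metric == k$metric, ]
    cmeans <- tapply(s$value, s$case_id, mean)
    data.frame(structure = k$structure, region = k$region, frame = k$frame,
               metric = k$metric, units = k$units,
               mean = mean(cmeans), sd = stats::sd(cmeans),
               n_cases = length(cmeans), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# the default analysis families, each Holm-corrected as one block
study_statistics <- function(records, features, rater_groups,
                             records_2d = NULL) {
  out <- list()
  metrics3 <- intersect(c("DSC", "HD", "AHD"), unique(records$metric))
  has_tz <- all(c("WG", "TZ") %in% records$structure)

  # WG vs TZ per frame, family = the metrics
  for (fr in intersect(c("pairwise", "consensus"), unique(records$frame))) {
    if (!has_tz) break
    fam <- do.call(rbind, lapply(metrics3, function(m)
      value_or_null(compare_structures(records, "WG", "TZ", fr, m))))
    out[[length(out) + 1]] <- holm_family(fam)
  }

  # regional contrasts on WG per frame, family = the 3 region pairs
  regional_metrics_present <-
    intersect(c("DSC", "HD"), unique(records$metric[records$region != "whole"]))
  for (fr in intersect(c("pairwise", "consensus"), unique(records$frame))) {
    for (m in regional_metrics_present) {
      fam <- do.call(rbind, lapply(
        list(c("base", "mid"), c("base", "apex"), c("mid", "apex")),
        function(pr) value_or_null(
          compare_regions(records, pr[1], pr[2], "WG", fr, m))))
      out[[length(out) + 1]] <- holm_family(fam)
    }
  }

  # experience groups vs consensus, family = 3 contrasts per metric
  if ("consensus" %in% records$frame && length(unique(rater_groups)) == 3) {
    for (st in intersect(c("WG", "TZ"), unique(records$structure)))
      for (m in metrics3)
        out[[length(out) + 1]] <- value_or_null(
          compare_groups_to_consensus(records, rater_groups, st, m))
  }

  # covariate correlations, family = the metrics per covariate and frame
  if (!is.null(features)) {
    for (fr in intersect(c("pairwise", "consensus"), unique(records$frame))) {
      for (feat in intersect(c("volume_cm3_mean", "squared_contrast"),
                             names(features))) {
        fam <- do.call(rbind, lapply(metrics3, function(m)
          value_or_null(
            correlate_with_feature(records, features, feat, fr, "WG", m))))
        out[[length(out) + 1]] <- holm_family(fam)
      }
      for (feat in intersect(c("lesion_flag", "median_lobe_flag"),
                             names(features))) {
        fam <- do.call(rbind, lapply(metrics3, function(m)
          value_or_null(
            compare_binary_factor(records, features, feat, fr, "WG", m))))
        out[[length(out) + 1]] <- holm_family(fam)
      }
    }
  }

  # 2D vs 3D arm: whole zones in 3D mode, regions slicewise
  if (!is.null(records_2d)) {
    fam <- do.call(rbind, c(
      lapply(intersect(c("WG", "TZ"), unique(records_2d$structure)),
             function(st) value_or_null(
               compare_2d_3d(records_2d, records, st, "pairwise", "DSC",
                             "whole", "3D"))),
      lapply(c("base", "mid", "apex"), function(rg) value_or_null(
        compare_2d_3d(records_2d, records, "WG", "pairwise", "DSC", rg,
                      "slicewise")))))
    out[[length(out) + 1]] <- holm_family(fam)
  }

  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

holm_family <- function(fam) {
  if (is.null(fam) || nrow(fam) == 0) return(NULL)
  fam$p_holm <- holm_adjust(fam$p_raw)
  fam
}

value_or_null <- function(expr) tryCatch(expr, error = function(e) NULL)

write_summary_text <- function(summary_tab, stats_tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("Agreement summary (case-mean first; mean +/- SD across cases)", con)
  writeLines(utils::capture.output(print(
    transform(summary_tab, mean = round(mean, 4), sd = round(sd, 4)),
    row.names = FALSE)), con)
  writeLines("", con)
  writeLines("Statistical tests (two-sided; Holm-corrected per family)", con)
  writeLines(utils::capture.output(print(
    transform(stats_tab,
              statistic = signif(statistic, 6), effect = signif(effect, 4),
              p_raw = signif(p_raw, 4), p_holm = signif(p_holm, 4)),
    row.names = FALSE)), con)
}
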