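# Nonparametric statistical layer.
#
# Aggregation unit is the case: per-case means over rater pairs (or over a
# group's raters) are formed before any test, so cases -- not pairs -- are
# the statistical samples. All tests are two-sided; families of related
# contrasts are corrected with the Holm-Bonferroni step-down method.

#' Holm-Bonferroni step-down adjustment
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "holm"` (step-down
#' multipliers m, m-1, ..., 1 with monotonicity enforcement, capped at 1).
#'
#' @param pvalues numeric vector of raw p-values in `[0, 1]`
#' @return adjusted p-values, same order as the input
#' @examples
#' holm_adjust(c(0.01, 0.04)) # 0.02, 0.04
#' @export
holm_adjust <- function(pvalues) {
  stopifnot(is.numeric(pvalues), all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "holm")
}

#' Wilcoxon signed-rank test with Pratt zero handling
#'
#' Two-sided paired test. Zero differences are ranked with the rest and
#' then discarded from the statistic (Pratt's method), instead of being
#' dropped before ranking. With no zeros and no ties and `n <= 25` the
#' exact null distribution is used; otherwise a normal approximation with
#' continuity correction and zero/tie variance corrections.
#'
#' @param x,y paired numeric vectors (or `y = NULL` for differences in `x`)
#' @return list with `statistic` (V, sum of positive-difference ranks),
#'   `p_value`, `n` (nonzero pairs), `method`
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else {
    stopifnot(length(x) == length(y))
    x - y
  }
  d <- d[is.finite(d)]
  if (length(d) == 0) stop("no finite differences", call. = FALSE)
  if (all(d == 0))
    return(list(statistic = 0, p_value = 1, n = 0,
                method = "degenerate (all differences zero)"))
  r <- rank(abs(d))            # zeros ranked too (Pratt)
  nonzero <- d != 0
  V <- sum(r[d > 0])
  n <- length(d)
  n0 <- sum(!nonzero)
  ties <- any(duplicated(r[nonzero])) || n0 > 0
  if (!ties && n <= 25) {
    # no zeros here (n0 == 0), classic exact distribution
    p <- min(1, 2 * min(stats::psignrank(V, n),
                        stats::psignrank(V - 1, n, lower.tail = FALSE)))
    return(list(statistic = V, p_value = p, n = n, method = "exact"))
  }
  mu <- n * (n + 1) / 4 - n0 * (n0 + 1) / 4
  tie_tab <- table(r[nonzero])
  sigma2 <- (n * (n + 1) * (2 * n + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = V, p_value = p, n = sum(nonzero),
       method = "normal approximation (Pratt, continuity-corrected)")
}

#' Spearman correlation with Fisher-z confidence interval
#'
#' Rank correlation with average ranks for ties, two-sided p from the
#' t-approximation, and a 95% CI from the Fisher transform with standard
#' error `1/sqrt(n - 3)`.
#'
#' @param x,y numeric vectors
#' @return list with `rho`, `ci95` (length 2), `p_value`, `n`
#' @export
spearman_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  zr <- atanh(max(min(rho, 1 - 1e-12), -1 + 1e-12))
  hw <- stats::qnorm(0.975) / sqrt(n - 3)
  list(rho = rho, ci95 = tanh(c(zr - hw, zr + hw)), p_value = p, n = n)
}

stat_report_row <- function(test, comparison, statistic, effect,
                            ci_lo = NA_real_, ci_hi = NA_real_,
                            p_raw, n) {
  data.frame(test = test, comparison = comparison, statistic = statistic,
             effect = effect, ci_lo = ci_lo, ci_hi = ci_hi,
             p_raw = p_raw, p_holm = NA_real_, n = n,
             stringsAsFactors = FALSE)
}

# ---- record helpers ----------------------------------------------------

filter_records <- function(records, structure = NULL, region = "whole",
                           frame = NULL, metric = NULL, mode = NULL) {
  r <- records
  if (!is.null(structure)) r <- r[r$structure %in% structure, ]
  if (!is.null(region)) r <- r[r$region %in% region, ]
  if (!is.null(frame)) r <- r[r$frame %in% frame, ]
  if (!is.null(metric)) r <- r[r$metric %in% metric, ]
  if (!is.null(mode)) r <- r[r$mode %in% mode, ]
  r
}

case_means <- function(records) {
  r <- records[!is.na(records$value), ]
  tapply(r$value, r$case_id, mean)
}

#' Pairwise agreement summary
#'
#' Case-level mean and SD over all rater pairs first, then the grand mean
#' and SD across cases. Errors when any case lacks pairs (all `choose(J, 2)`
#' pairs are required when `n_raters` is given).
#'
#' @param records a metric-record data.frame (see [pairwise_records()])
#' @param structure,region,metric,mode filters applied before summarising
#' @param n_raters when given, each case must carry exactly
#'   `choose(n_raters, 2)` pair records
#' @return list with `per_case` (data.frame `case_id`, `mean`, `sd`,
#'   `n_pairs`), `grand_mean`, `grand_sd`, `n_cases`
#' @export
pairwise_summary <- function(records, structure = NULL, region = "whole",
                             metric = "DSC", mode = "3D", n_raters = NULL) {
  r <- filter_records(records, structure, region, "pairwise", metric, mode)
  r <- r[!is.na(r$value), ]
  if (nrow(r) == 0) stop("no pairwise records after filtering", call. = FALSE)
  per <- do.call(rbind, lapply(split(r, r$case_id), function(s) {
    data.frame(case_id = s$case_id[1], mean = mean(s$value),
               sd = stats::sd(s$value), n_pairs = nrow(s),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  if (!is.null(n_raters)) {
    want <- choose(n_raters, 2)
    bad <- per$case_id[per$n_pairs != want]
    if (length(bad))
      stop(sprintf("incomplete pairwise records (expected %d pairs/case): %s",
                   want, paste(bad, collapse = ", ")), call. = FALSE)
  }
  list(per_case = per, grand_mean = mean(per$mean),
       grand_sd = stats::sd(per$mean), n_cases = nrow(per))
}

#' Compare agreement between two structures
#'
#' Paired two-sided Wilcoxon signed-rank test (Pratt zeros) on per-case
#' mean metric values of `structure_a` vs `structure_b` over the common
#' cases. The effect is the mean of the per-case differences (a - b).
#'
#' @param records metric-record data.frame
#' @param structure_a,structure_b e.g. `"WG"`, `"TZ"`
#' @param frame `"pairwise"` or `"consensus"`
#' @param metric,region,mode filters
#' @return one-row StatReport data.frame
#' @export
compare_structures <- function(records, structure_a, structure_b,
                               frame = "pairwise", metric = "DSC",
                               region = "whole", mode = "3D") {
  ma <- case_means(filter_records(records, structure_a, region, frame, metric, mode))
  mb <- case_means(filter_records(records, structure_b, region, frame, metric, mode))
  common <- intersect(names(ma), names(mb))
  if (length(common) < 3)
    stop("fewer than 3 common cases between structures", call. = FALSE)
  w <- wilcoxon_signed_rank(ma[common], mb[common])
  stat_report_row("wilcoxon-signed-rank",
                  sprintf("%s vs %s (%s %s)", structure_a, structure_b,
                          frame, metric),
                  w$statistic, mean(ma[common] - mb[common]),
                  p_raw = w$p_value, n = length(common))
}

#' Compare agreement between two regions
#'
#' Paired Wilcoxon on per-case mean regional metric values.
#'
#' @param records metric-record data.frame
#' @param region_a,region_b e.g. `"base"`, `"mid"`, `"apex"`
#' @param structure,frame,metric,mode filters
#' @return one-row StatReport data.frame
#' @export
compare_regions <- function(records, region_a, region_b, structure = "WG",
                            frame = "pairwise", metric = "DSC", mode = "3D") {
  ma <- case_means(filter_records(records, structure, region_a, frame, metric, mode))
  mb <- case_means(filter_records(records, structure, region_b, frame, metric, mode))
  common <- intersect(names(ma), names(mb))
  if (length(common) < 3)
    stop("fewer than 3 common cases between regions", call. = FALSE)
  w <- wilcoxon_signed_rank(ma[common], mb[common])
  stat_report_row("wilcoxon-signed-rank",
                  sprintf("%s vs %s (%s %s %s)", region_a, region_b,
                          structure, frame, metric),
                  w$statistic, mean(ma[common] - mb[common]),
                  p_raw = w$p_value, n = length(common))
}

#' Correlate agreement with a per-case covariate
#'
#' Spearman rank correlation between per-case mean metric values and a
#' feature column, with a Fisher-z 95% CI.
#'
#' @param records metric-record data.frame
#' @param features data.frame with `case_id` and the feature column
#' @param feature_name column of `features`
#' @param frame,structure,metric,region,mode filters
#' @return one-row StatReport data.frame (`effect` is rho)
#' @export
correlate_with_feature <- function(records, features, feature_name,
                                   frame = "pairwise", structure = "WG",
                                   metric = "DSC", region = "whole",
                                   mode = "3D") {
  stopifnot(feature_name %in% names(features), "case_id" %in% names(features))
  m <- case_means(filter_records(records, structure, region, frame, metric, mode))
  f <- features[[feature_name]][match(names(m), features$case_id)]
  sp <- spearman_test(f, as.numeric(m))
  stat_report_row("spearman",
                  sprintf("%s vs %s (%s %s)", feature_name, metric, frame,
                          structure),
                  sp$rho, sp$rho, sp$ci95[1], sp$ci95[2], sp$p_value, sp$n)
}

#' Compare experience groups against the consensus
#'
#' For each case and group, the group's mean consensus-frame metric; the
#' three pairwise group contrasts are tested with paired Wilcoxon tests
#' and Holm-corrected as one family (per metric).
#'
#' @param records metric-record data.frame with consensus-frame rows
#'   carrying `rater` ids
#' @param rater_groups named character vector mapping rater_id to group
#' @param structure,metric,region,mode filters
#' @return three-row StatReport data.frame with `p_holm` filled
#' @export
compare_groups_to_consensus <- function(records, rater_groups,
                                        structure = "WG", metric = "DSC",
                                        region = "whole", mode = "3D") {
  r <- filter_records(records, structure, region, "consensus", metric, mode)
  r <- r[!is.na(r$value), ]
  if (nrow(r) == 0) stop("no consensus-frame records", call. = FALSE)
  r$group <- rater_groups[r$rater_a]
  if (anyNA(r$group))
    stop("rater(s) missing from rater_groups", call. = FALSE)
  gm <- tapply(r$value, list(r$case_id, r$group), mean)
  pairs <- list(c("expert", "senior"), c("expert", "junior"),
                c("senior", "junior"))
  rows <- lapply(pairs, function(pr) {
    a <- gm[, pr[1]]; b <- gm[, pr[2]]
    ok <- is.finite(a) & is.finite(b)
    w <- wilcoxon_signed_rank(a[ok], b[ok])
    stat_report_row("wilcoxon-signed-rank",
                    sprintf("%s vs %s (consensus %s %s)", pr[1], pr[2],
                            structure, metric),
                    w$statistic, mean(a[ok] - b[ok]),
                    p_raw = w$p_value, n = sum(ok))
  })
  out <- do.call(rbind, rows)
  out$p_holm <- holm_adjust(out$p_raw)
  out
}

#' Mann-Whitney U test of a binary per-case factor
#'
#' Two-sided Mann-Whitney U (via [stats::wilcox.test()]) on per-case mean
#' metric values split by a logical feature column.
#'
#' @param records metric-record data.frame
#' @param features data.frame with `case_id` and the factor column
#' @param factor_name logical column of `features`
#' @param frame,structure,metric,region,mode filters
#' @return one-row StatReport data.frame (`effect` is the difference of
#'   group medians, TRUE minus FALSE)
#' @export
compare_binary_factor <- function(records, features, factor_name,
                                  frame = "pairwise", structure = "WG",
                                  metric = "DSC", region = "whole",
                                  mode = "3D") {
  stopifnot(factor_name %in% names(features))
  m <- case_means(filter_records(records, structure, region, frame, metric, mode))
  f <- as.logical(features[[factor_name]][match(names(m), features$case_id)])
  if (length(unique(f[!is.na(f)])) < 2)
    stop(sprintf("factor '%s' has fewer than 2 levels among scored cases",
                 factor_name), call. = FALSE)
  wt <- stats::wilcox.test(as.numeric(m)[f], as.numeric(m)[!f],
                           exact = FALSE, correct = TRUE)
  stat_report_row("mann-whitney-u",
                  sprintf("%s (%s %s %s)", factor_name, frame, structure,
                          metric),
                  unname(wt$statistic),
                  stats::median(m[f], na.rm = TRUE) -
                    stats::median(m[!f], na.rm = TRUE),
                  p_raw = wt$p.value, n = sum(!is.na(f)))
}

#' Compare 2D versus 3D acquisition agreement
#'
#' Paired Wilcoxon on per-case mean metric values matched by case id
#' between a 2D-sequence and a 3D-sequence set of records.
#'
#' @param records_2d,records_3d metric-record data.frames
#' @param structure,frame,metric,region,mode filters (use
#'   `mode = "slicewise"` for regional comparisons)
#' @return one-row StatReport data.frame (effect = mean 2D minus 3D)
#' @export
compare_2d_3d <- function(records_2d, records_3d, structure = "WG",
                          frame = "pairwise", metric = "DSC",
                          region = "whole", mode = "3D") {
  m2 <- case_means(filter_records(records_2d, structure, region, frame, metric, mode))
  m3 <- case_means(filter_records(records_3d, structure, region, frame, metric, mode))
  common <- intersect(names(m2), names(m3))
  if (length(common) < 3)
    stop("fewer than 3 common cases between the 2D and 3D arms", call. = FALSE)
  w <- wilcoxon_signed_rank(m2[common], m3[common])
  stat_report_row("wilcoxon-signed-rank",
                  sprintf("2D vs 3D (%s %s %s %s)", structure, frame, metric,
                          region),
                  w$statistic, mean(m2[common] - m3[common]),
                  p_raw = w$p_value, n = length(common))
}
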