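test_that("Holm adjustment matches the hand-applied step-down rule", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.037), 0.037)
  expect_equal(holm_adjust(c(0.5, 0.9)), c(1.0, 1.0))
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  # every permutation of three p-values agrees with an independent oracle
  ps <- c(0.012, 0.2, 0.049)
  for (perm in list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                    c(3, 2, 1))) {
    expect_equal(holm_adjust(ps[perm]), holm_oracle(ps[perm]))
  }
  # monotone and never below the raw p
  set.seed(1)
  p <- sort(runif(8))
  adj <- holm_adjust(p)
  expect_true(all(diff(adj) >= 0))
  expect_true(all(adj >= p))
})

test_that("the signed-rank test matches the reference implementation without zeros", {
  x <- c(2.1, -1.3, 3.5, 0.7, -2.2, 4.1, 1.9, -0.4, 2.8, 3.3)
  ours <- wilcoxon_signed_rank(x)
  ref <- wilcox.test(x, exact = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  # paired form
  set.seed(4)
  a <- rnorm(15); b <- rnorm(15)
  ours2 <- wilcoxon_signed_rank(a, b)
  ref2 <- wilcox.test(a, b, paired = TRUE, exact = TRUE)
  expect_equal(ours2$p_value, ref2$p.value, tolerance = 1e-10)
  # large-sample path with ties vs the normal approximation
  set.seed(5)
  d <- round(rnorm(40, 0.3), 1)
  d <- d[d != 0]
  ours3 <- wilcoxon_signed_rank(d)
  ref3 <- wilcox.test(d, exact = FALSE, correct = TRUE)
  expect_equal(ours3$p_value, ref3$p.value, tolerance = 1e-10)
})

test_that("Pratt zero handling matches the frozen scipy reference", {
  d <- c(0, 0, 1.5, -2, 3, 4, 5, -6, 7, 8, 9.5, 10, 11, 12.5)
  ours <- wilcoxon_signed_rank(d)
  expect_equal(ours$statistic, 90) # rank-sum of positive differences
  # scipy.stats.wilcoxon(d, zero_method='pratt', correction=True,
  #                      mode='approx') -> p = 0.015398453529599815
  expect_equal(ours$p_value, 0.015398453529599815, tolerance = 1e-8)
  # all-zero differences degenerate to p = 1
  expect_equal(wilcoxon_signed_rank(rep(0, 6))$p_value, 1)
})

test_that("Spearman rho, p and Fisher CI match the references", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 6.0, 0.8, 7.3, 2.9, 5.8)
  y <- c(2.0, 3.1, 2.5, 4.0, 5.2, 5.9, 1.1, 6.8, 3.5, 4.9)
  ours <- spearman_test(x, y)
  ref <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  # frozen scipy.stats.spearmanr values
  expect_equal(ours$rho, 0.9515151515151514, tolerance = 1e-12)
  expect_equal(ours$p_value, 2.279854920641689e-05, tolerance = 1e-8)
  expect_true(ours$ci95[1] < ours$rho && ours$rho < ours$ci95[2])
  # perfect monotone relations
  expect_equal(spearman_test(1:8, (1:8)^2)$rho, 1)
  expect_equal(spearman_test(1:8, -(1:8))$rho, -1)
})

make_records <- function(values, metric = "DSC", structure = "WG",
                         frame = "pairwise", case_ids = NULL,
                         rater_a = "r1", rater_b = "r2") {
  n <- length(values)
  if (is.null(case_ids)) case_ids <- sprintf("c%02d", seq_len(n))
  data.frame(case_id = case_ids, structure = structure, region = "whole",
             frame = frame, rater_a = rater_a, rater_b = rater_b,
             metric = metric, mode = "3D",
             units = "dimensionless", value = values,
             stringsAsFactors = FALSE)
}

test_that("pairwise summaries aggregate case-first and demand completeness", {
  # two cases with case-means 0.9 and 0.8, unequal pair counts:
  # case-first weighting gives 0.85, pooled would give 0.8667
  rec <- rbind(
    make_records(c(0.9, 0.9), case_ids = c("c1", "c1"),
                 rater_b = c("r2", "r3")),
    make_records(0.8, case_ids = "c2"))
  s <- pairwise_summary(rec)
  expect_equal(s$grand_mean, 0.85)
  expect_false(isTRUE(all.equal(s$grand_mean, mean(rec$value))))
  # constant records: SD 0
  s2 <- pairwise_summary(make_records(rep(0.7, 4)))
  expect_equal(s2$grand_mean, 0.7)
  expect_equal(s2$grand_sd, 0)
  # a case missing pairs is named
  expect_error(pairwise_summary(rec, n_raters = 3), "incomplete.*c2")
})

test_that("structure comparisons are symmetric and handle degenerate input", {
  set.seed(8)
  vals_wg <- runif(12, 0.88, 0.95)
  vals_tz <- vals_wg - runif(12, 0.01, 0.06)
  rec <- rbind(make_records(vals_wg, structure = "WG"),
               make_records(vals_tz, structure = "TZ"))
  ab <- compare_structures(rec, "WG", "TZ")
  ba <- compare_structures(rec, "TZ", "WG")
  expect_equal(ab$p_raw, ba$p_raw)
  expect_equal(ab$effect, -ba$effect)
  expect_lt(ab$p_raw, 0.05)
  expect_gt(ab$effect, 0)
  # identical values: degenerate, p = 1
  rec_id <- rbind(make_records(vals_wg, structure = "WG"),
                  make_records(vals_wg, structure = "TZ"))
  expect_equal(compare_structures(rec_id, "WG", "TZ")$p_raw, 1)
})

test_that("feature correlations recover perfect and null relationships", {
  vals <- seq(0.80, 0.95, length.out = 12)
  rec <- make_records(vals)
  feats <- data.frame(case_id = sprintf("c%02d", 1:12), f_same = vals,
                      f_rev = rev(vals))
  expect_equal(correlate_with_feature(rec, feats, "f_same")$effect, 1)
  expect_equal(correlate_with_feature(rec, feats, "f_rev")$effect, -1)
  # permuted feature: small |rho| on average across permutations
  set.seed(9)
  rhos <- replicate(50, {
    feats$f_perm <- sample(vals)
    correlate_with_feature(rec, feats, "f_perm")$effect
  })
  expect_lt(abs(mean(rhos)), 0.15)
  expect_gt(mean(abs(rhos) < 0.6), 0.9)
})

test_that("group-vs-consensus contrasts form one Holm family", {
  set.seed(10)
  cases <- sprintf("c%02d", 1:10)
  groups <- c(r1 = "expert", r2 = "expert", r3 = "senior", r4 = "senior",
              r5 = "junior", r6 = "junior")
  rec <- do.call(rbind, lapply(names(groups), function(r) {
    base <- ifelse(groups[[r]] == "expert", 0.95, 0.90)
    df <- make_records(rnorm(10, base, 0.01), frame = "consensus",
                       case_ids = cases)
    df$rater_a <- r
    df$rater_b <- "consensus"
    df
  }))
  out <- compare_groups_to_consensus(rec, groups)
  expect_equal(nrow(out), 3)
  expect_equal(out$p_holm, holm_oracle(out$p_raw))
  expect_true(all(out$p_holm >= out$p_raw))
  # expert vs junior separated by construction
  ej <- out[grep("expert vs junior", out$comparison), ]
  expect_lt(ej$p_holm, 0.05)
  # identical groups degenerate to p 1
  rec_id <- rec
  rec_id$value <- 0.9
  out_id <- compare_groups_to_consensus(rec_id, groups)
  expect_true(all(out_id$p_holm == 1))
})

test_that("binary factors are tested with the Mann-Whitney U reference", {
  # fixture matching the frozen scipy mannwhitneyu reference
  vals <- c(3.1, 2.4, 4.8, 5.5, 1.9, 3.3, 4.1, 2.0, 2.2, 3.0, 1.5, 2.7, 3.9)
  rec <- make_records(vals)
  feats <- data.frame(case_id = sprintf("c%02d", 1:13),
                      lesion_flag = c(rep(TRUE, 7), rep(FALSE, 6)))
  out <- compare_binary_factor(rec, feats, "lesion_flag")
  expect_equal(out$statistic, 32)
  # scipy.stats.mannwhitneyu(a, b, alternative='two-sided',
  #                          method='asymptotic', use_continuity=True)
  expect_equal(out$p_raw, 0.13361440253771614, tolerance = 1e-8)
  feats$lesion_flag <- TRUE
  expect_error(compare_binary_factor(rec, feats, "lesion_flag"),
               "fewer than 2 levels")
})

test_that("2D vs 3D comparisons pair cases across record sets", {
  set.seed(11)
  v3 <- runif(10, 0.90, 0.95)
  v2 <- v3 - runif(10, 0.005, 0.02)
  r3 <- make_records(v3)
  r2 <- make_records(v2)
  out <- compare_2d_3d(r2, r3)
  expect_lt(out$p_raw, 0.05)
  expect_lt(out$effect, 0)
  expect_equal(out$n, 10)
})
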