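test_that("pearson correlation matches hand-computed values", {
  d <- data.frame(x = c(1, 2, 3, 4), y = c(1, 2, 3, 5))
  out <- pearson_corr(d, x, y)
  # cov = 6.5/3, var_x = 5/3, var_y = 8.75/3 -> r = 6.5/sqrt(43.75)
  expect_equal(out$r, 6.5 / sqrt(43.75), tolerance = 1e-12)
  expect_equal(out$r, 0.9827, tolerance = 1e-4)
  # exact linear relation
  d2 <- data.frame(x = 1:10, y = 2 * (1:10))
  expect_equal(pearson_corr(d2, x, y)$r, 1)
  # degenerate input is reported as undefined
  d3 <- data.frame(x = rep(1, 5), y = 1:5)
  expect_warning(out3 <- pearson_corr(d3, x, y), "undefined")
  expect_true(is.na(out3$r))
})

test_that("ROC AUC equals brute-force pair counting on random instances", {
  d <- data.frame(s = c(1, 2, 3, 4), y = c(0, 1, 0, 1))
  expect_equal(roc_analysis(d, s, y, direction = "high-positive")$auc, 0.75)
  d2 <- data.frame(s = c(1, 2, 3, 4), y = c(0, 0, 1, 1))
  expect_equal(roc_analysis(d2, s, y, direction = "high-positive")$auc, 1)
  # all-tied scores: chance AUC by the ties convention
  d3 <- data.frame(s = rep(2, 10), y = rep(c(0, 1), 5))
  expect_equal(roc_analysis(d3, s, y, direction = "high-positive")$auc, 0.5)
  # property: trapezoidal AUC == Mann-Whitney pair counting, n <= 50
  set.seed(21)
  for (i in 1:20) {
    n <- sample(6:50, 1)
    sc <- round(rnorm(n), sample(0:1, 1))  # induce ties half the time
    lb <- rbinom(n, 1, 0.5)
    if (length(unique(lb)) < 2) lb[1:2] <- c(0, 1)
    d <- data.frame(s = sc, y = lb)
    expect_equal(roc_analysis(d, s, y, direction = "high-positive")$auc,
                 auc_bruteforce(sc, lb), tolerance = 1e-12)
    # low-positive direction mirrors the score axis
    expect_equal(roc_analysis(d, s, y, direction = "low-positive")$auc,
                 auc_bruteforce(-sc, lb), tolerance = 1e-12)
  }
})

test_that("ROC reporting: CI, Youden cutoff, class counts", {
  set.seed(5)
  d <- data.frame(s = c(rnorm(60, 1), rnorm(40, -1)),
                  y = rep(c(1, 0), c(60, 40)))
  r <- roc_analysis(d, s, y, direction = "high-positive")
  expect_equal(r$n_pos, 60)
  expect_equal(r$n_neg, 40)
  expect_true(r$auc_ci[1] <= r$auc && r$auc <= r$auc_ci[2])
  # the reported cutoff attains the maximal Youden index over the curve
  youden_at <- function(cut) {
    sens <- mean(d$s[d$y == 1] > cut)
    spec <- mean(d$s[d$y == 0] <= cut)
    sens + spec - 1
  }
  best <- max(sapply(sort(unique(d$s)), youden_at))
  expect_equal(r$sensitivity + r$specificity - 1, best, tolerance = 1e-9)
  expect_error(roc_analysis(data.frame(s = 1:4, y = rep(1, 4)), s, y),
               "Both classes")
})

test_that("Bland-Altman hand example and reported-value reconstruction", {
  # one subject, differences (+2, -2, +2, -2): naive SD with n-1 denominator
  d <- data.frame(ref = rep(50, 4), test = 50 + c(2, -2, 2, -2), id = 1)
  expect_warning(b <- bland_altman_rm(d, ref, test, id), "one subject")
  expect_equal(b$bias, 0)
  expect_equal(b$sd_diff, sqrt(16 / 3), tolerance = 1e-9)
  expect_equal(b$loa_high, 1.96 * sqrt(16 / 3), tolerance = 1e-9)
  expect_equal(b$loa_high, 4.527, tolerance = 1e-3)
  # identical pairs: zero everything
  d2 <- data.frame(ref = c(80, 90, 100, 70), test = c(80, 90, 100, 70),
                   id = c(1, 1, 2, 2))
  b2 <- bland_altman_rm(d2, ref, test, id)
  expect_equal(b2$bias, 0)
  expect_equal(b2$sd_diff, 0)
  expect_equal(c(b2$loa_low, b2$loa_high), c(0, 0))
  expect_equal(b2$percentage_error, 0)
  # reported bias/precision reproduce the reported LOA within input rounding
  expect_equal(1.69 - 1.96 * 14.13, -26.02, tolerance = 0.02)
  expect_equal(1.69 + 1.96 * 14.13, 29.40, tolerance = 0.02)
})

test_that("repeated-measures SD includes the between-subject component", {
  # subject-specific biases spread differences beyond the within-subject SD
  set.seed(9)
  subj <- rep(1:10, each = 20)
  bias_i <- rnorm(10, 0, 10)[subj]
  d <- data.frame(id = subj, ref = rnorm(200, 85, 15))
  d$test <- d$ref + bias_i + rnorm(200, 0, 3)
  b_rm <- bland_altman_rm(d, ref, test, id)
  b_naive <- bland_altman_rm(d, ref, test, id, adjust = "naive")
  expect_gt(b_rm$sd_diff, 3)                  # sees the between-subject spread
  expect_gt(b_rm$var_between, 0)
  expect_equal(sqrt(b_rm$var_within), 3, tolerance = 0.5)
  # with balanced data the two estimates are close but not forced equal
  expect_equal(b_rm$sd_diff, b_naive$sd_diff, tolerance = 0.25 * b_naive$sd_diff)
})

test_that("percentage error formula and scaling", {
  expect_equal(percentage_error(14.13, 83.78), 33.06, tolerance = 0.005)
  expect_equal(round(percentage_error(14.13, 83.78)), 33)
  expect_equal(percentage_error(0, 80), 0)
  expect_equal(percentage_error(20, 80), 2 * percentage_error(10, 80))
  expect_error(percentage_error(10, 0), "positive")
})

test_that("polar angles, exclusion zone and concordance follow the rules", {
  d <- data.frame(id = 1, ref = c(0, 20, 40, 45), test = c(0, 20, 20, 25))
  p <- polar_trend(d, ref, test, id, exclusion_radius = 10)
  # identity change -> 0 deg; flat test against +20 ref -> 45 deg
  expect_equal(p$points$angle_deg[1:2], c(0, 45))
  expect_true(all(p$points$angle_deg > -90 & p$points$angle_deg <= 90))
  # small change (radius 5) excluded from the denominator
  expect_true(p$points$excluded[3])
  expect_equal(p$n_used, 2)
  expect_equal(p$concordance_rate, 50)  # 0 deg in, 45 deg out at the 30 deg limit
  # all-excluded: undefined rate
  d2 <- data.frame(id = 1, ref = c(0, 5), test = c(0, 5))
  expect_warning(p2 <- polar_trend(d2, ref, test, id, exclusion_radius = 10),
                 "undefined")
  expect_true(is.na(p2$concordance_rate))
})

test_that("polar trending is symmetric under method swap", {
  d <- difference_dataset(0, 12, n = 120, seed = 14)
  p1 <- polar_trend(d, hb_ref_gL, hb_test_gL, pig_id)
  p2 <- polar_trend(d, hb_test_gL, hb_ref_gL, pig_id)
  expect_equal(p2$points$angle_deg, -p1$points$angle_deg, tolerance = 1e-9)
  expect_equal(p2$concordance_rate, p1$concordance_rate)
  expect_equal(p2$n_excluded, p1$n_excluded)
})

test_that("error-grid zones encode the transfusion decision bands", {
  d <- data.frame(ref = c(80, 55, 65, 55, 105, 100, 60),
                  test = c(80, 105, 95, 58, 55, 60, 100))
  g <- error_grid(d, ref, test)
  expect_equal(as.character(g$pairs$zone),
               c("A", "C", "A", "A", "C", "A", "A"))
  expect_equal(sum(g$zones$pct), 100)
  # same-band pairs are never B or C; swap never changes the zone
  set.seed(31)
  r <- runif(200, 30, 130); t <- runif(200, 30, 130)
  g1 <- error_grid(data.frame(ref = r, test = t), ref, test)
  g2 <- error_grid(data.frame(ref = t, test = r), ref, test)
  expect_equal(as.character(g1$pairs$zone), as.character(g2$pairs$zone))
  same_band <- g1$pairs$band_ref == g1$pairs$band_test
  expect_true(all(g1$pairs$zone[same_band] == "A"))
  expect_error(error_grid(data.frame(ref = -1, test = 50), ref, test),
               "positive")
})

test_that("LOA sample-size plan follows the closed form", {
  plan <- loa_sample_size(s = 20, n = 300)
  expect_equal(plan$se_loa, 2)
  expect_equal(plan$ci95_halfwidth, 3.92)
  # quadrupling n halves the SE
  expect_equal(loa_sample_size(20, 1200)$se_loa, 1)
  expect_error(loa_sample_size(0, 10), "positive")
  expect_error(loa_sample_size(10, 1), "at least 2")
})

test_that("agreement statistics are invariant to row order", {
  d <- metric_dataset(150, seed = 17)
  perm <- withr::with_seed(1, sample(nrow(d)))
  ds <- d[perm, ]
  b1 <- glance(bland_altman_rm(predict_hb(d), hb_ref_gL, hb_dppg_gL, pig_id))
  b2 <- glance(bland_altman_rm(predict_hb(ds), hb_ref_gL, hb_dppg_gL, pig_id))
  expect_equal(b1, b2)
  d$state <- d$hb_ref_gL < 60
  ds <- d[perm, ]
  expect_equal(roc_analysis(d, ratio_red, state, "low-positive")$auc,
               roc_analysis(ds, ratio_red, state, "low-positive")$auc)
  g1 <- error_grid(predict_hb(d), hb_ref_gL, hb_dppg_gL)$zones
  g2 <- error_grid(predict_hb(ds), hb_ref_gL, hb_dppg_gL)$zones
  expect_equal(g1, g2)
})
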