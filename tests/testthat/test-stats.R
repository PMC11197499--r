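test_that("WSS ratios are one for uniform fields and scale-invariant", {
  quads <- rep(c("ventral", "dorsal", "superior", "inferior"), each = 3)
  sides <- rep(c("inner", "outer"), 6)
  lab <- fake_labels(quads, curve_side = sides)
  f <- fake_wss_field(rep(5, 12))
  expect_equal(rwss_vi_ds(f, lab), 1)
  expect_equal(rwss_inner_outer(f, lab), 1)
  f2 <- fake_wss_field(runif(12, 2, 9))
  f3 <- fake_wss_field(10 * f2$wss_magnitude)
  expect_equal(rwss_vi_ds(f3, lab), rwss_vi_ds(f2, lab), tolerance = 1e-12)
  expect_equal(rwss_inner_outer(f3, lab), rwss_inner_outer(f2, lab),
               tolerance = 1e-12)
})

test_that("group means reproduce the published regional ratio arithmetic", {
  # ventral+inferior mean 6.41 Pa vs dorsal+superior 8.91 Pa -> 0.719
  lab <- fake_labels(c("ventral", "inferior", "dorsal", "superior"))
  f <- fake_wss_field(c(6.41, 6.41, 8.91, 8.91))
  expect_equal(rwss_vi_ds(f, lab), 6.41 / 8.91, tolerance = 1e-12)
  expect_equal(rwss_vi_ds(f, lab), 0.719, tolerance = 1e-3)
  # inner 6.31 Pa vs outer 8.24 Pa -> 0.766
  lab2 <- fake_labels(c("ventral", "dorsal"),
                      curve_side = c("inner", "outer"))
  f2 <- fake_wss_field(c(6.31, 8.24))
  expect_equal(rwss_inner_outer(f2, lab2), 6.31 / 8.24, tolerance = 1e-12)
  expect_equal(rwss_inner_outer(f2, lab2), 0.766, tolerance = 1e-3)
  # empty groups error
  expect_error(rwss_inner_outer(f, lab), "undefined")
})

test_that("paired t matches the textbook statistic and is antisymmetric", {
  a <- c(5.1, 6.3, 4.8, 7.2, 5.9)
  b <- c(4.2, 5.9, 5.1, 6.0, 5.2)
  res <- paired_t(a, b)
  d <- a - b
  expect_equal(res$t, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(paired_t(b, a)$t, -res$t)
  # constant shift: enormous t, tiny p
  shifted <- paired_t(a + 3, a + rnorm(5, 0, 1e-9))
  expect_lt(shifted$p, 1e-6)
  expect_error(paired_t(a, a), "zero variance")
  expect_error(paired_t(a, b[1:3]), "equal length")
})

test_that("summary-statistic t-test reproduces raw-data t.test", {
  set.seed(31)
  x <- rnorm(20, 5, 2); y <- rnorm(25, 6, 1.5)
  ours <- two_sample_t_summary(x = x, y = y)
  ref <- t.test(x, y)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  ours_s <- two_sample_t_summary(x = x, y = y, var_equal = TRUE)
  ref_s <- t.test(x, y, var.equal = TRUE)
  expect_equal(ours_s$p, ref_s$p.value, tolerance = 1e-12)
  # identical summaries: t = 0, p = 1; antisymmetry under swap
  expect_equal(two_sample_t_summary(5, 1, 10, 5, 1, 10)$t, 0)
  expect_equal(two_sample_t_summary(5, 1, 10, 5, 1, 10)$p, 1)
  f <- two_sample_t_summary(49.3, 16.0, 25, 56.4, 15.0, 43)
  b <- two_sample_t_summary(56.4, 15.0, 43, 49.3, 16.0, 25)
  expect_equal(f$t, -b$t)
})

test_that("the age-summary comparison lands in the published neighborhood", {
  for (ve in c(FALSE, TRUE)) {
    p <- two_sample_t_summary(49.3, 16.0, 25, 56.4, 15.0, 43,
                              var_equal = ve)$p
    expect_gt(p, 0.06)
    expect_lt(p, 0.09)
  }
})

test_that("ANOVA F matches a hand sum-of-squares decomposition", {
  set.seed(8)
  groups <- list(v = rnorm(12, 6.9, 2.7), d = rnorm(12, 8.8, 2.8),
                 s = rnorm(12, 8.9, 2.6), i = rnorm(12, 5.3, 1.9))
  res <- one_way_anova_posthoc(groups)
  # brute-force oracle
  y <- unlist(groups); n <- length(y); k <- 4
  grand <- mean(y)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  F_hand <- (ssb / (k - 1)) / (ssw / (n - k))
  expect_equal(res$F, F_hand, tolerance = 1e-10)
  expect_equal(res$p, pf(F_hand, k - 1, n - k, lower.tail = FALSE),
               tolerance = 1e-10)
  # Bonferroni: corrected = min(1, 6 * raw) for 4 groups
  expect_equal(res$pairwise$p_bonferroni,
               pmin(1, 6 * res$pairwise$p_raw))
  expect_equal(nrow(res$pairwise), 6L)
})

test_that("identical groups give F = 0 and capped pairwise p = 1", {
  g <- list(a = rep(4, 5), b = rep(4, 5), c = rep(4, 5), d = rep(4, 5))
  res <- one_way_anova_posthoc(g)
  expect_equal(res$F, 0)
  expect_true(all(res$pairwise$p_bonferroni == 1))
  expect_error(one_way_anova_posthoc(list(a = 1:3)), ">= 2 groups")
})

test_that("Fisher exact equals the hypergeometric enumeration oracle", {
  set.seed(12)
  for (trial in 1:60) {
    tab <- matrix(rpois(4, 6), 2)
    expect_equal(fisher_exact(tab)$p, fisher_oracle(tab), tolerance = 1e-9,
                 label = paste(tab, collapse = ","))
  }
  # small-margin sweep
  for (a in 0:4) for (b in 0:4) for (c_ in 0:4) for (d in 0:4) {
    tab <- matrix(c(a, c_, b, d), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact(tab)$p, fisher_oracle(tab), tolerance = 1e-9)
  }
})

test_that("published contingency rows land on their printed p-values", {
  # agreement to the printed 3-decimal precision
  expect_lt(abs(fisher_exact(matrix(c(2, 14, 23, 29), 2))$p - 0.036),
            5e-4)
  expect_lt(abs(fisher_exact(matrix(c(7, 27, 18, 16), 2))$p - 0.011),
            5e-4)
})

test_that("Cohen's kappa is 1 for identical ratings and near 0 by chance", {
  r <- sample(letters[1:4], 60, replace = TRUE)
  res <- cohen_kappa(r, r)
  expect_equal(res$kappa, 1)
  expect_true(res$excellent)
  set.seed(44)
  a <- sample(1:4, 10000, replace = TRUE)
  b <- sample(1:4, 10000, replace = TRUE)
  expect_lt(abs(cohen_kappa(a, b)$kappa), 0.03)
  # threshold flag: 0.751 counts as excellent, 0.75 does not
  expect_true(0.751 > 0.75)
  mk <- cohen_kappa(c(1, 1, 2, 2), c(1, 1, 2, 2))
  expect_true(mk$excellent)
  und <- cohen_kappa(rep("x", 5), rep("x", 5))
  expect_true(is.na(und$kappa))
})

test_that("kappa agrees with the e1071 cross-check when available", {
  skip_if_not_installed("e1071")
  set.seed(9)
  a <- sample(1:3, 200, replace = TRUE)
  b <- ifelse(runif(200) < 0.7, a, sample(1:3, 200, replace = TRUE))
  ours <- cohen_kappa(a, b)$kappa
  ref <- e1071::classAgreement(table(a, b))$kappa
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("ICC(2,1) is 1 for identical raters and recovers ground truth", {
  m <- cbind(1:10, 1:10, 1:10)
  expect_equal(icc_agreement(m)$icc, 1, tolerance = 1e-12)
  # heavy noise drives it toward 0
  set.seed(3)
  noisy <- cbind(rnorm(60), rnorm(60))
  expect_lt(abs(icc_agreement(noisy)$icc), 0.3)
  # variance components chosen for ICC = 0.8: sigma_b^2 = 4 sigma_e^2
  set.seed(17)
  n <- 500
  subj <- rnorm(n, 0, 2)
  mm <- cbind(subj + rnorm(n, 0, 1), subj + rnorm(n, 0, 1))
  est <- icc_agreement(mm)
  expect_equal(est$icc, 0.8, tolerance = 0.05)
  expect_true(est$excellent)
  expect_match(est$model, "two-way random")
  # zero between-subject variance is undefined
  flat <- matrix(5, 10, 3)
  expect_true(is.na(icc_agreement(flat)$icc))
})

test_that("regional tables carry one row per populated region", {
  fx <- tiny_curved()
  field <- compute_wss(fx$sol, fx$mesh)
  labels <- wall_labels(fx$mesh)
  tab <- regional_wss_table(field, labels, vessel_id = "v1")
  expect_true(all(c("vessel_id", "segment", "quadrant", "mean_wss_pa",
                    "total_area_m2", "n_faces") %in% names(tab)))
  expect_true(all(tab$mean_wss_pa >= 0))
  expect_lte(nrow(tab), 12L)
  # area-weighted means match direct recomputation
  r1 <- tab[tab$segment == "middle" & tab$quadrant == "ventral", ]
  sel <- which(labels$labels$segment == "middle" &
               labels$labels$quadrant == "ventral")
  expect_equal(r1$mean_wss_pa, regional_mean_wss(field, sel))
})
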