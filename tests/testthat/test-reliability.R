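test_that("within-subject CV matches its closed form and symmetries", {
  expect_equal(within_subject_cv(7.2, 7.2), 0)
  # (9, 11): 100 * sd / mean = 100 * sqrt(2) / 10, frozen independently
  expect_equal(within_subject_cv(9, 11), 14.142135623730951)
  expect_equal(within_subject_cv(9, 11), within_subject_cv(11, 9))
  # scale invariant, not shift invariant
  expect_equal(within_subject_cv(3 * 9, 3 * 11), within_subject_cv(9, 11))
  expect_false(isTRUE(all.equal(within_subject_cv(9 + 5, 11 + 5),
                                within_subject_cv(9, 11))))
  expect_error(within_subject_cv(-1, 1), "undefined-CV")
})

test_that("ICC reproduces its defining cases", {
  set.seed(2)
  s <- rnorm(8)
  # perfect agreement
  expect_equal(icc_absolute_agreement(cbind(s, s))$icc, 1.0)
  # independent columns, large n: ICC near 0
  big <- cbind(rnorm(10000), rnorm(10000))
  expect_lt(abs(icc_absolute_agreement(big)$icc), 0.02)
  # 5 x 2 integer toy table against the aov variance-component oracle
  toy <- cbind(c(9, 7, 5, 8, 6), c(10, 6, 6, 9, 5))
  expect_equal(icc_absolute_agreement(toy)$icc, icc_oracle_aov(toy),
               tolerance = 1e-12)
  # errors
  expect_error(icc_absolute_agreement(matrix(1, 5, 2)), "degenerate-variance")
  expect_error(icc_absolute_agreement(cbind(1:2, 2:3)), "insufficient-subjects")
})

test_that("ICC is invariant to common affine rescaling and labeled sensibly", {
  set.seed(3)
  s <- rnorm(12)
  mat <- cbind(s + rnorm(12, 0, 0.4), s + rnorm(12, 0, 0.4))
  r1 <- icc_absolute_agreement(mat)
  r2 <- icc_absolute_agreement(3.7 * mat + 11)
  expect_equal(r1$icc, r2$icc, tolerance = 1e-12)
  expect_true(r1$label %in% c("poor", "fair", "good", "excellent"))
})

test_that("ICC estimator is consistent: bias vanishes at large n", {
  # at n = 10 the ICC(A,1) mean-squares ratio is biased low; the bias is a
  # small-sample property of the estimator and disappears with n
  ratio <- 0.75
  set.seed(6)
  est <- replicate(200, {
    s <- rnorm(400, 0, sqrt(ratio))
    mat <- cbind(s + rnorm(400, 0, sqrt(1 - ratio)),
                 s + rnorm(400, 0, sqrt(1 - ratio)))
    icc_absolute_agreement(mat)$icc
  })
  expect_lt(abs(mean(est) - ratio), 3 * sd(est) / sqrt(200))
})

test_that("Bland-Altman bias and limits follow their construction", {
  set.seed(4)
  x <- rnorm(9, 10)
  ident <- bland_altman(cbind(x, x))
  expect_equal(ident$bias, 0)
  expect_equal(ident$loa_low, 0)
  expect_equal(ident$loa_high, 0)
  # constant shift: bias -c, zero-width limits
  shifted <- bland_altman(cbind(x, x + 1.5))
  expect_equal(shifted$bias, -1.5)
  expect_equal(shifted$sd_diff, 0)
  # swapping sessions negates bias and mirrors the limits
  y <- x + rnorm(9, 0.2, 0.3)
  a <- bland_altman(cbind(x, y)); b <- bland_altman(cbind(y, x))
  expect_equal(a$bias, -b$bias)
  expect_equal(a$loa_low, -b$loa_high)
  expect_equal(a$loa_high, -b$loa_low)
  expect_equal(a$points$mean, b$points$mean)
})

test_that("Pearson correlation matches the covariance definition", {
  x <- c(4.1, 5.2, 3.8, 6.0, 5.5)
  expect_equal(pearson_between_sessions(cbind(x, 2 * x + 3)), 1)
  expect_equal(pearson_between_sessions(cbind(x, -x)), -1)
  y <- c(4.4, 4.9, 4.2, 5.1, 6.1)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_between_sessions(cbind(x, y)), manual)
  # affine maps with positive slope leave r unchanged
  expect_equal(pearson_between_sessions(cbind(2 * x - 1, 0.5 * y + 4)),
               pearson_between_sessions(cbind(x, y)))
  expect_error(pearson_between_sessions(cbind(rep(1, 5), x)),
               "degenerate-variance")
})

test_that("repeated-measures ANOVA matches the aov Error-strata oracle", {
  set.seed(8)
  design <- expand.grid(subject = 1:4, approach = c("voxel", "roi"),
                        algorithm = c("one", "two"))
  design$cv <- rnorm(16, 10, 2)
  mine <- rm_anova_2x2(design)
  oracle <- rm_anova_oracle_aov(design)
  expect_equal(mine$F, unname(oracle[, "F"]), tolerance = 1e-10)
  expect_equal(mine$p, unname(oracle[, "p"]), tolerance = 1e-10)
})

test_that("a pure additive approach effect is detected and nothing else", {
  design <- expand.grid(subject = 1:6, approach = c("voxel", "roi"),
                        algorithm = c("one", "two"))
  base <- rep(c(3, 4, 5, 4.5, 3.5, 4.2), 4)  # subject baselines
  design$cv <- base + ifelse(design$approach == "roi", 2, 0)
  res <- rm_anova_2x2(design)
  # the approach contrast is exact (zero error MS -> p = 0); the other
  # effects carry no sum of squares at all
  expect_equal(res$p[res$effect == "approach"], 0)
  expect_equal(res$ss[res$effect == "algorithm"], 0, tolerance = 1e-20)
  expect_equal(res$ss[res$effect == "approach:algorithm"], 0, tolerance = 1e-20)
})

test_that("ANOVA design validation and the fixed-effects option", {
  design <- expand.grid(subject = 1:5, approach = c("a", "b"),
                        algorithm = c("x", "y"))
  set.seed(10); design$cv <- rnorm(20)
  expect_error(rm_anova_2x2(design[-3, ]), "missing-cell")
  fixed <- rm_anova_2x2(design, method = "fixed")
  oracle <- anova(stats::lm(cv ~ approach * algorithm, data = design))
  expect_equal(fixed$F, oracle$`F value`[1:3], tolerance = 1e-12)
})

test_that("reliability report assembles all statistics coherently", {
  set.seed(12)
  rows <- expand.grid(subject = 1:6, roi = c("wm", "gm"), parameter = c("F", "D"),
                      approach = c("voxel_wise", "roi_wise"),
                      algorithm = c("one_step", "two_step"))
  truth <- rnorm(nrow(rows), 10, 1)
  rows$session1 <- truth + rnorm(nrow(rows), 0, 0.3)
  rows$session2 <- truth + rnorm(nrow(rows), 0, 0.3)
  rep <- reliability_report(rows)
  expect_s3_class(rep, "reliability_report")
  expect_equal(nrow(rep$stats), 16)  # 2 roi x 2 param x 4 configs
  expect_true(all(rep$stats$wscv_mean >= 0))
  # limits of agreement symmetric about the bias
  expect_equal(rep$stats$loa_high - rep$stats$bias,
               rep$stats$bias - rep$stats$loa_low)
  expect_equal(nrow(rep$anova), 4 * 3)  # per roi x parameter, 3 effects
  # CSV serialization round-trips the stats table
  td <- withr::local_tempdir()
  paths <- write_reliability_report(rep, td)
  back <- read.csv(paths[["stats"]])
  expect_equal(back$icc, rep$stats$icc, tolerance = 1e-12)
})
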