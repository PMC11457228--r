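test_that("descriptive rows report mean, sd and type-7 centiles", {
  r <- descriptive_table(c(2, 4), "toy")
  expect_equal(r$mean, 3)
  expect_equal(r$sd, sqrt(2))

  r2 <- descriptive_table(1:100, "seq")
  # linear interpolation of order statistics: q_p = 1 + p * 99
  expect_equal(r2$p50, 50.5)
  expect_equal(r2$p25, 25.75)
  expect_equal(r2$p3, 1 + 0.03 * 99)
  expect_equal(r2$p97, 1 + 0.97 * 99)

  r3 <- descriptive_table(rep(7.5, 10), "const")
  expect_equal(r3$sd, 0)
  expect_true(all(unlist(r3[paste0("p", c(3, 5, 10, 25, 50, 75, 90, 95, 97))]) == 7.5))

  expect_warning(r4 <- descriptive_table(c(NA, 3), "short"), "fewer than 2")
  expect_true(is.na(r4$mean))
})

test_that("centile rows are monotone non-decreasing for random inputs", {
  set.seed(99)
  cents <- paste0("p", c(3, 5, 10, 25, 50, 75, 90, 95, 97))
  for (i in 1:20) {
    v <- switch(1 + i %% 3, rnorm(50), rexp(37), runif(11, -5, 5))
    r <- descriptive_table(v, "x")
    expect_false(is.unsorted(unlist(r[cents])))
  }
})

test_that("random-effect correlations match the direct Pearson formula", {
  eff <- data.frame(alpha = c(1, 2, 3), beta = c(1, 2, 4),
                    gamma = c(2, 1, 0))
  out <- random_effect_correlations(eff)
  # by-hand Pearson for (1,2,3) vs (1,2,4)
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r["size", "tempo"], r_hand, tolerance = 1e-12)
  expect_equal(r_hand, 0.98198, tolerance = 1e-4)
  # t-transform p-value with n - 2 df
  tstat <- r_hand * sqrt(1 / (1 - r_hand^2))
  expect_equal(out$p["size", "tempo"], 2 * pt(-abs(tstat), 1),
               tolerance = 1e-10)
  # perfect correlation
  eff2 <- data.frame(alpha = 1:6, beta = 1:6 * 2, gamma = rnorm(6))
  out2 <- random_effect_correlations(eff2)
  expect_equal(out2$r["size", "tempo"], 1)
  expect_lt(out2$p["size", "tempo"], 1e-10)
  # degenerate input
  eff3 <- data.frame(alpha = rep(1, 5), beta = 1:5, gamma = rnorm(5))
  # the constant component voids two of the three pairs
  out3 <- suppressWarnings(random_effect_correlations(eff3))
  expect_warning(expect_warning(random_effect_correlations(eff3),
                                "zero-variance"), "zero-variance")
  expect_true(is.na(out3$r["size", "tempo"]))
})

test_that("quintile contrasts rank, group and test as specified", {
  params <- data.frame(subject_id = sprintf("s%02d", 1:10),
                       aphv = 1:10, phv = 1:10, gsi = 10:1, flag = "")
  ct <- quintile_contrast(params, "aphv", "aphv")
  expect_equal(ct$k, 2L)
  expect_equal(ct$diff, 8)      # top {9,10} minus bottom {1,2}
  # antisymmetry: reversing the ranking negates the difference
  params_rev <- params; params_rev$aphv <- -params$aphv
  ct_rev <- quintile_contrast(params_rev, "aphv", "phv")
  expect_equal(ct_rev$diff, -quintile_contrast(params, "aphv", "phv")$diff)
  # Welch statistic agrees with the direct formula
  set.seed(5)
  params2 <- data.frame(subject_id = sprintf("s%03d", 1:57),
                        aphv = rnorm(57), phv = rnorm(57), gsi = rnorm(57),
                        flag = "")
  ct2 <- quintile_contrast(params2, "aphv", "phv")
  k <- ct2$k
  o <- order(params2$aphv, params2$subject_id)
  top <- params2$phv[o[(57 - k + 1):57]]; bot <- params2$phv[o[1:k]]
  se <- sqrt(var(top) / k + var(bot) / k)
  t_hand <- (mean(top) - mean(bot)) / se
  df_hand <- se^4 / ((var(top) / k)^2 / (k - 1) + (var(bot) / k)^2 / (k - 1))
  expect_equal(ct2$t, t_hand, tolerance = 1e-10)
  expect_equal(ct2$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-10)
})

test_that("self-ranked contrasts are positive and the null is calibrated", {
  set.seed(31)
  # type-I error of the Welch test at alpha = 0.05 under independence
  rejections <- 0L
  for (i in 1:400) {
    params <- data.frame(subject_id = sprintf("s%03d", 1:200),
                         aphv = rnorm(200), phv = rnorm(200),
                         gsi = rnorm(200), flag = "")
    ct <- quintile_contrast(params, "aphv", "phv")
    if (ct$p <= 0.05) rejections <- rejections + 1L
    if (i <= 20)
      expect_gt(quintile_contrast(params, "gsi", "gsi")$diff, 0)
  }
  # 400 * 0.05 = 20 expected, binomial sd ~ 4.4
  expect_gt(rejections, 6)
  expect_lt(rejections, 34)
})

test_that("contrast requires enough unflagged subjects", {
  params <- data.frame(subject_id = sprintf("s%02d", 1:12),
                       aphv = 1:12, phv = 1:12, gsi = 1:12,
                       flag = c(rep("", 8), rep("end_censored", 4)))
  expect_error(quintile_contrast(params, "aphv", "phv"), "at least 10")
})

test_that("reports are deterministic and complete", {
  tpl <- boys_template()
  set.seed(12)
  eff <- data.frame(subject_id = sprintf("s%02d", 1:30),
                    alpha = rnorm(30, 0, 5), beta = rnorm(30, 0, 0.6),
                    gamma = rnorm(30, 0, 0.12))
  fit <- template_as_fit(tpl, eff)
  params <- extract_spurt_parameters(fit)
  contrasts <- quintile_contrast_table(params)
  expect_equal(nrow(contrasts), 9L)

  d1 <- tempfile(); d2 <- tempfile()
  f1 <- build_report(fit, params, contrasts, dir = d1, prefix = "boys")
  f2 <- build_report(fit, params, contrasts, dir = d2, prefix = "boys")
  expect_true(all(file.exists(f1)))
  for (nm in c("descriptives", "correlations", "contrasts")) {
    expect_identical(readLines(f1[[nm]]), readLines(f2[[nm]]))
  }
  desc <- utils::read.csv(f1[["descriptives"]])
  expect_equal(nrow(desc), 5L)

  # no contrast section when contrasts are omitted
  f3 <- build_report(fit, params, NULL, dir = tempfile(), prefix = "x")
  expect_false("contrasts" %in% names(f3))

  # mixed-sex input is rejected
  pm <- params; pm$sex[1] <- "female"
  expect_error(build_report(fit, pm, contrasts, dir = tempfile()), "single-sex")
})
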