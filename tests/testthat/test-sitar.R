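test_that("prediction implements the shape-invariant transformation", {
  tpl <- boys_template()
  fit <- template_as_fit(tpl, data.frame(subject_id = "x", alpha = 0,
                                         beta = 0, gamma = 0))
  ages <- seq(7.5, 16, 0.25)
  g <- template_height(tpl, ages)

  # (0,0,0) returns the mean curve exactly
  expect_equal(predict_height(fit, c(0, 0, 0), ages), g)
  # pure size shift
  expect_equal(predict_height(fit, c(5, 0, 0), ages), g + 5)
  # pure tempo shift: curve moved one year later
  expect_equal(predict_height(fit, c(0, 1, 0), ages),
               template_height(tpl, ages - 1))
})

test_that("velocity is the analytic age-derivative of height", {
  tpl <- girls_template()
  fit <- template_as_fit(tpl, data.frame(subject_id = "x", alpha = 0,
                                         beta = 0, gamma = 0))
  ages <- seq(7.5, 16, length.out = 100)
  h <- 1e-4
  for (u in list(c(0, 0, 0), c(3, -0.4, 0.2))) {
    fd <- (predict_height(fit, u, ages + h, extrapolate = TRUE) -
           predict_height(fit, u, ages - h, extrapolate = TRUE)) / (2 * h)
    expect_lt(max(abs(fd - predict_velocity(fit, u, ages,
                                            extrapolate = TRUE))), 1e-5)
  }
  # gamma = 0, beta = 0: velocity is the template derivative
  expect_equal(predict_velocity(fit, c(0, 0, 0), ages),
               template_velocity(tpl, ages))
})

test_that("the velocity effect doubles peak velocity at gamma = log 2", {
  tpl <- boys_template()
  fit <- template_as_fit(tpl, data.frame(subject_id = "x", alpha = 0,
                                         beta = 0, gamma = 0))
  ages <- seq(8, 16, 0.005)
  v0 <- max(predict_velocity(fit, c(0, 0, 0), ages))
  v2 <- max(predict_velocity(fit, c(0, 0, log(2)), ages, extrapolate = TRUE))
  expect_equal(v2, 2 * v0, tolerance = 1e-6)
})

test_that("ages outside the guard band require explicit extrapolation", {
  tpl <- boys_template()
  fit <- template_as_fit(tpl, data.frame(subject_id = "x", alpha = 0,
                                         beta = 0, gamma = 0))
  expect_error(predict_height(fit, c(0, 0, 0), 18), "extrapolate")
  expect_silent(predict_height(fit, c(0, 0, 0), 18, extrapolate = TRUE))
  expect_silent(predict_height(fit, c(0, 0, 0), 16.6))  # inside the band
})

test_that("mean absolute error matches per-row recomputation", {
  sf <- memo("smallfit30", small_fit(seed = 11, n = 30))
  fit <- sf$fit; d <- sf$data
  d_use <- d[d$subject_id %in% fit$effects$subject_id, ]
  mae <- mean_absolute_error(fit, d_use)
  # brute force row by row
  resid <- vapply(seq_len(nrow(d_use)), function(r) {
    abs(d_use$height[r] -
          predict_height(fit, d_use$subject_id[r], d_use$age[r],
                         extrapolate = TRUE))
  }, numeric(1))
  expect_equal(mae, mean(resid), tolerance = 1e-12)
  # residuals {+1, -1} give MAE 1; perfect predictions give 0
  p <- d_use[1:2, ]
  p$height <- predict_height(fit, p$subject_id[1], p$age, extrapolate = TRUE)
  expect_equal(mean_absolute_error(fit, growth_data(p)), 0, tolerance = 1e-10)
  p$height <- p$height + c(1, -1)
  expect_equal(mean_absolute_error(fit, growth_data(p)), 1, tolerance = 1e-10)
  # unknown subject is an error
  bad <- p; bad$subject_id <- "nope"
  expect_error(mean_absolute_error(fit, growth_data(bad)), "absent")
})

test_that("noiseless data are fitted to self-consistency", {
  pre <- boys_preset()
  pre$noise_sd <- 0; pre$miss_prob <- 0; pre$visit_jitter <- 0
  d <- simulate_cohort(pre, 35, seed = 4)
  fit <- fit_sitar(d, options = list(
    knots = pre$template$basis$interior_knots,
    boundary_knots = pre$template$basis$boundary_knots,
    pivot = pre$age_pivot, tol = 1e-5, max_iter = 150))
  expect_lt(mean_absolute_error(fit, d), 0.05)
})

test_that("fitting is equivariant under height and time shifts", {
  pre <- boys_preset()
  d <- simulate_cohort(pre, 25, seed = 6)
  opts <- list(knots = pre$template$basis$interior_knots,
               boundary_knots = pre$template$basis$boundary_knots,
               pivot = pre$age_pivot, tol = 1e-5)
  f0 <- memo("equivariance_base", fit_sitar(d, options = opts))

  # h -> h + 10: alpha distribution unchanged (centred), mean curve +10,
  # beta and gamma unchanged
  d_up <- d; d_up$height <- d$height + 10
  f_up <- fit_sitar(growth_data(as.data.frame(d_up)), options = opts)
  expect_equal(f_up$effects$alpha, f0$effects$alpha, tolerance = 0.02)
  expect_equal(f_up$effects$beta, f0$effects$beta, tolerance = 0.02)
  expect_equal(f_up$effects$gamma, f0$effects$gamma, tolerance = 0.01)
  ages <- seq(8, 16, 0.5)
  expect_equal(predict_height(f_up, c(0, 0, 0), ages),
               predict_height(f0, c(0, 0, 0), ages) + 10, tolerance = 0.05)

  # t -> t + 1 with the same pivot: beta absorbs the shift, gamma unchanged
  d_sh <- as.data.frame(d); d_sh$age <- d_sh$age + 1
  opts_sh <- opts
  opts_sh$knots <- opts$knots + 1
  opts_sh$boundary_knots <- range(d_sh$age)
  f_sh <- fit_sitar(growth_data(d_sh), options = opts_sh)
  # per-subject curves shift by one year: compare predictions
  ids <- f0$effects$subject_id[1:5]
  for (id in ids) {
    expect_equal(predict_height(f_sh, id, ages + 1, extrapolate = TRUE),
                 predict_height(f0, id, ages, extrapolate = TRUE),
                 tolerance = 0.1)
  }
  expect_equal(f_sh$effects$gamma, f0$effects$gamma, tolerance = 0.02)
})

test_that("random effects are centred and the objective is monotone", {
  sf <- memo("smallfit30", small_fit(seed = 11, n = 30))
  fit <- sf$fit
  U <- as.matrix(fit$effects[, c("alpha", "beta", "gamma")])
  sds <- apply(U, 2, sd)
  expect_lt(max(abs(colMeans(U)) / sds), 1e-6)
  tr <- fit$logLik_trace
  expect_true(all(diff(tr) >= -1e-6 * abs(tr[-length(tr)])))
  # covariance reported is symmetric positive definite
  expect_equal(fit$omega, t(fit$omega))
  expect_gt(min(eigen(fit$omega, symmetric = TRUE)$values), 0)
  expect_gt(fit$resid_sd, 0)
})

test_that("subjects with too few measurements are dropped with a warning", {
  pre <- boys_preset()
  d <- simulate_cohort(pre, 12, seed = 19)
  short <- as.data.frame(d[d$subject_id != d$subject_id[1], ])
  extra <- data.frame(subject_id = "tiny", sex = "male",
                      age = c(9, 12), height = c(131, 150))
  dd <- growth_data(rbind(short, extra))
  expect_warning(fit <- fit_sitar(dd, options = list(
    knots = pre$template$basis$interior_knots,
    boundary_knots = pre$template$basis$boundary_knots,
    pivot = pre$age_pivot, tol = 1e-4, max_iter = 60)),
    "fewer than")
  expect_false("tiny" %in% fit$effects$subject_id)
})

test_that("fits serialise to JSON and round-trip exactly", {
  sf <- memo("smallfit30", small_fit(seed = 11, n = 30))
  fit <- sf$fit
  p <- tempfile(fileext = ".json")
  write_sitar_fit(fit, p)
  fit2 <- read_sitar_fit(p)
  expect_identical(fit2$coef, fit$coef)
  expect_identical(fit2$effects$alpha, fit$effects$alpha)
  expect_identical(fit2$effects$gamma, fit$effects$gamma)
  expect_equal(fit2$omega, fit$omega)
  ages <- seq(8, 16, 0.25)
  id <- fit$effects$subject_id[3]
  expect_identical(predict_height(fit2, id, ages),
                   predict_height(fit, id, ages))
  expect_identical(predict_velocity(fit2, id, ages),
                   predict_velocity(fit, id, ages))
})
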