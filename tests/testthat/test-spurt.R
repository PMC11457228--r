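test_that("peak finding matches analytic maxima", {
  pk <- find_peak(function(t) 9 - (t - 12)^2, window = c(8, 16))
  expect_equal(pk$aphv, 12, tolerance = 1e-3)
  expect_equal(pk$phv, 9, tolerance = 1e-6)
  expect_false(pk$boundary)

  pk2 <- find_peak(function(t) 2 + 6 * exp(-(t - 11)^2 / 2), window = c(7, 16))
  expect_equal(pk2$aphv, 11, tolerance = 1e-3)
  expect_equal(pk2$phv, 8, tolerance = 1e-6)

  # maximum on the boundary is flagged
  pk3 <- find_peak(function(t) -t, window = c(7, 16))
  expect_true(pk3$boundary)
})

test_that("takeoff sits at the acceleration maximum (Gaussian closed form)", {
  # v(t) = A exp(-(t-p)^2 / (2 s^2)): v' is maximal at t = p - s where
  # v = A exp(-1/2)
  A <- 9; p <- 12; s <- 2
  v <- function(t) A * exp(-(t - p)^2 / (2 * s^2))
  tk <- find_takeoff(v, aphv = p, window = c(7, p))
  expect_equal(tk$aogs, p - s, tolerance = 1e-3)
  expect_equal(tk$ogsv, A * exp(-0.5), tolerance = 1e-4)
  expect_equal(tk$ogsv, 5.4587, tolerance = 1e-3)

  # monotonically decreasing velocity: no interior acceleration maximum
  tk2 <- find_takeoff(function(t) 10 - 0.5 * t, aphv = 16, window = c(7, 16))
  expect_true(tk2$boundary)
})

test_that("spurt end solves v(end) = ogsv after the peak", {
  # symmetric Gaussian: end = p + s, so gsi = 2 s
  A <- 9; p <- 12; s <- 2
  v <- function(t) A * exp(-(t - p)^2 / (2 * s^2))
  en <- find_spurt_end(v, aphv = p, ogsv = A * exp(-0.5), search_limit = 18)
  expect_equal(en$end_age, p + s, tolerance = 1e-3)
  expect_false(en$censored)

  en2 <- find_spurt_end(function(t) 9 - (t - 12)^2, aphv = 12, ogsv = 5,
                        search_limit = 18)
  expect_equal(en2$end_age, 14, tolerance = 1e-3)

  # velocity that never falls back: censored at the search limit
  en3 <- find_spurt_end(function(t) 8 + 0 * t, aphv = 12, ogsv = 5,
                        search_limit = 18)
  expect_true(en3$censored)
})

test_that("extraction agrees with an exhaustive fine-grid scan", {
  tpl <- boys_template()
  v <- function(t) template_velocity(tpl, t)
  a <- function(t) template_accel(tpl, t)
  out <- extract_spurt_curve(v, a, window = c(7, 16), search_limit = 18)

  g <- seq(7, 16, by = 1e-4)
  vg <- v(g)
  expect_equal(out$aphv, g[which.max(vg)], tolerance = 1e-3)
  ag <- a(g[g <= out$aphv])
  expect_equal(out$aogs, g[which.max(ag)], tolerance = 1e-3)
  # defining equation of the end age
  expect_lt(abs(v(out$end_age) - out$ogsv), 1e-3)
  expect_equal(out$gsi, out$end_age - out$aogs)
})

test_that("extraction is equivariant under tempo shifts", {
  tpl <- girls_template()
  eff <- data.frame(subject_id = c("base", "late"),
                    alpha = 0, beta = c(0, 0.8), gamma = 0)
  fit <- template_as_fit(tpl, eff)
  sp <- extract_spurt_parameters(fit, window = c(6, 16.5), search_limit = 19)
  base <- sp[sp$subject_id == "base", ]
  late <- sp[sp$subject_id == "late", ]
  expect_equal(late$aogs, base$aogs + 0.8, tolerance = 1e-3)
  expect_equal(late$aphv, base$aphv + 0.8, tolerance = 1e-3)
  expect_equal(late$end_age, base$end_age + 0.8, tolerance = 1e-3)
  expect_equal(late$phv, base$phv, tolerance = 1e-6)
  expect_equal(late$ogsv, base$ogsv, tolerance = 1e-3)
  expect_equal(late$gsi, base$gsi, tolerance = 2e-3)
})

test_that("extraction follows the velocity-scale law", {
  # positive gamma compresses the age axis about the pivot: velocities
  # scale by e^gamma, durations by e^-gamma
  tpl <- boys_template()
  g <- 0.25
  eff <- data.frame(subject_id = c("base", "fast"),
                    alpha = 0, beta = 0, gamma = c(0, g))
  fit <- template_as_fit(tpl, eff)
  sp <- extract_spurt_parameters(fit, window = c(6, 16.5), search_limit = 19)
  base <- sp[sp$subject_id == "base", ]
  fast <- sp[sp$subject_id == "fast", ]
  expect_equal(fast$phv / base$phv, exp(g), tolerance = 1e-3)
  expect_equal(fast$ogsv / base$ogsv, exp(g), tolerance = 1e-3)
  expect_equal(fast$gsi / base$gsi, exp(-g), tolerance = 1e-3)
  expect_equal(fast$aphv - fast$aogs, (base$aphv - base$aogs) * exp(-g),
               tolerance = 1e-3)
  expect_gt(fast$phv, base$phv)
  expect_lt(fast$gsi, base$gsi)
})

test_that("identical subjects yield bit-identical parameters", {
  tpl <- boys_template()
  eff <- data.frame(subject_id = c("s1", "s2"),
                    alpha = 2.5, beta = -0.3, gamma = 0.1)
  fit <- template_as_fit(tpl, eff)
  sp <- extract_spurt_parameters(fit)
  expect_identical(unlist(sp[1, -1]), unlist(sp[2, -1]))
})

test_that("emitted parameter sets satisfy the ordering invariant", {
  pre <- boys_preset()
  set.seed(42)
  eff <- data.frame(subject_id = sprintf("s%02d", 1:25),
                    alpha = rnorm(25, 0, 5), beta = rnorm(25, 0, 0.7),
                    gamma = rnorm(25, 0, 0.13))
  fit <- template_as_fit(pre$template, eff)
  sp <- extract_spurt_parameters(fit)
  cl <- sp[!nzchar(sp$flag), ]
  expect_gt(nrow(cl), 20)
  expect_true(all(cl$aogs < cl$aphv))
  expect_true(all(cl$aphv < cl$end_age))
  expect_equal(cl$gsi, cl$end_age - cl$aogs)
  expect_true(all(cl$phv >= cl$ogsv))
})
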