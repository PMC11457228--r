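#' @title Template growth curves for cohort simulation
#' @description A template curve is the population-mean height curve used by
#'   the synthetic cohort generator: individual curves are produced from it
#'   by the size/tempo/velocity transformations of the shape-invariant
#'   growth model. The template height curve lives in the same natural cubic
#'   spline space that the model fit uses for its mean curve (interior knots
#'   at equally spaced quantiles of the study's age design), so simulated
#'   cohorts are generated from exactly the model class being fitted and
#'   parameter-recovery experiments are not confounded by curve
#'   misspecification. Calibration pins the template's own spurt geometry —
#'   takeoff, peak and spurt end — to prescribed values through linear
#'   constraints on the spline coefficients.
#' @name growth-template
NULL

#' Construct a growth template from a height spline
#'
#' @param basis an [natural_spline_basis()] object for the height curve.
#' @param coef numeric vector of length `basis$df + 1`: intercept followed
#'   by spline coefficients, in cm.
#' @param sex optional label ("male"/"female") carried for bookkeeping.
#' @return object of class `growth_template`.
#' @export
growth_template <- function(basis, coef, sex = NA_character_) {
  stopifnot(inherits(basis, "nspline_basis"),
            length(coef) == basis$df + 1L)
  structure(list(basis = basis, coef = as.numeric(coef), sex = sex),
            class = "growth_template")
}

#' Template height
#' @param template a `growth_template`.
#' @param t ages in decimal years (extended linearly outside the knot span).
#' @return height in cm.
#' @export
template_height <- function(template, t) {
  drop(cbind(1, nsb_eval(template$basis, t)) %*% template$coef)
}

#' Template height velocity (derivative of height)
#' @inheritParams template_height
#' @return velocity in cm/year.
#' @export
template_velocity <- function(template, t) {
  drop(nsb_eval(template$basis, t, deriv = 1L) %*% template$coef[-1L])
}

#' Template height acceleration (second derivative of height)
#' @inheritParams template_height
#' @return acceleration in cm/year^2.
#' @export
template_accel <- function(template, t) {
  drop(nsb_eval(template$basis, t, deriv = 2L) %*% template$coef[-1L])
}

#' @export
print.growth_template <- function(x, ...) {
  cat("Growth template (height spline)\n")
  cat("  sex:", x$sex, "\n")
  cat("  knot span:", format(x$basis$boundary_knots, digits = 4), "years,",
      x$basis$df, "basis functions\n")
  if (!is.null(x$calibration)) {
    cat("  calibrated spurt parameters:\n")
    print(round(unlist(x$calibration$achieved[1:6]), 3))
  }
  invisible(x)
}

# reference velocity control points built around the requested spurt
# geometry: declining mid-childhood velocity, a shallow pre-takeoff minimum
# (takeoff at *maximum acceleration* implies velocity dips below the takeoff
# velocity first), a front-loaded rise, and decline towards near-zero adult
# velocity
.reference_points <- function(targets, age_range = c(7, 16.5)) {
  aogs <- targets$aogs; ogsv <- targets$ogsv
  aphv <- targets$aphv; phv <- targets$phv
  end <- targets$aogs + targets$gsi
  amp <- phv - ogsv
  Tr <- aphv - aogs
  Ef <- end - aphv
  # takeoff at *maximum acceleration* implies a triangular acceleration
  # profile over the rise: velocity dips below the takeoff velocity first,
  # then rises quadratically (front-loaded); the fall mirrors it
  pts <- rbind(
    c(age_range[1], ogsv + 0.40),
    c(aogs - 0.77, ogsv - 0.35 * amp),
    c(aogs, ogsv),
    c(aogs + 0.45 * Tr, ogsv + 0.70 * amp),
    c(aogs + 0.75 * Tr, ogsv + 0.94 * amp),
    c(aphv, phv),
    c(aphv + 0.55 * Ef, ogsv + 0.70 * amp),
    c(end, ogsv),
    c(end + 0.6, pmax(ogsv - 0.60 * amp, 1.0)),
    c(end + 1.5, pmax(ogsv - 0.90 * amp, 0.8)),
    c(age_range[2] - 0.2, 0.85)
  )
  colnames(pts) <- c("age", "velocity")
  keep <- c(TRUE, diff(pts[, 1]) > 0.3)
  pts[keep & pts[, 1] <= age_range[2], , drop = FALSE]
}

# interior knots derived from the spurt targets: the acceleration of a
# cubic height spline is piecewise linear, so resolving the printed spurt
# geometry requires knots at the takeoff age (acceleration maximum), at the
# peak age (the acceleration kinks from its gentle rise-side decline into
# the steep post-peak fall), and shortly after the spurt end (where the
# fall bends back towards zero adult velocity); two pre-takeoff knots shape
# the childhood decline and its pre-spurt velocity minimum
.template_knots <- function(targets, age_range = c(7, 16.5)) {
  end <- targets$aogs + targets$gsi
  k <- c(targets$aogs - 1.77, targets$aogs - 0.77, targets$aogs,
         targets$aphv, end + 0.15, end + 1.15, end + 2.2)
  k <- sort(k)
  k <- k[k > age_range[1] + 0.15 & k < age_range[2] - 0.15]
  k[c(TRUE, diff(k) > 0.3)]
}

#' Calibrate a template curve to prescribed spurt parameters
#'
#' Solves for a template height spline whose extracted spurt parameters
#' equal the requested targets. The conditions — takeoff velocity and
#' maximal acceleration at the takeoff age, peak magnitude and zero slope at
#' the peak age, and return to the takeoff velocity at the spurt end — are
#' linear in the spline coefficients and imposed exactly; remaining freedom
#' least-squares matches a smooth reference velocity shape. Interior knots
#' are placed at the spurt landmarks (takeoff, peak, just past the end),
#' which is what makes this geometry representable by a cubic spline: its
#' piecewise-linear acceleration must peak exactly at a knot and kink at the
#' peak. The result is verified by running the spurt extraction on the
#' calibrated curve.
#'
#' @param targets named list with `aogs`, `ogsv`, `aphv`, `phv`, `gsi`
#'   (years / cm/year); the spurt end is `aogs + gsi`.
#' @param h7 height at age 7 in cm (anchors the curve's level).
#' @param sex optional label stored on the template.
#' @param age_range ages spanned by the spline knots (default the study
#'   design's 7-16.5 years).
#' @param reference optional two-column matrix (age, velocity) of control
#'   points for the reference shape; defaults to a shape built around the
#'   targets.
#' @param tol_age,tol_vel verification tolerances (years, cm/year).
#' @return a calibrated `growth_template`; its `calibration` field records
#'   targets, achieved values and verification status.
#' @export
calibrate_template <- function(targets, h7, sex = NA_character_,
                               age_range = c(7, 16.5),
                               reference = NULL,
                               tol_age = 0.02, tol_vel = 0.05) {
  need <- c("aogs", "ogsv", "aphv", "phv", "gsi")
  if (!all(need %in% names(targets)))
    stop("targets must include ", paste(need, collapse = ", "))
  if (!(targets$aogs < targets$aphv))
    stop("targets must satisfy aogs < aphv")
  if (!(targets$phv > targets$ogsv))
    stop("targets must satisfy phv > ogsv")
  end <- targets$aogs + targets$gsi
  if (end <= targets$aphv)
    stop("spurt end (aogs + gsi) must exceed aphv")

  if (is.null(reference)) reference <- .reference_points(targets, age_range)
  ref_fun <- stats::splinefun(reference[, 1], reference[, 2],
                              method = "monoH.FC")

  basis <- natural_spline_basis(age_range,
                                interior_knots = .template_knots(targets,
                                                                 age_range),
                                boundary_knots = age_range)

  grid <- seq(age_range[1], age_range[2], by = 0.05)
  X <- nsb_eval(basis, grid, deriv = 1L)      # velocity rows (no intercept)
  r <- ref_fun(grid)

  vel_row <- function(t) nsb_eval(basis, t, deriv = 1L)
  acc_row <- function(t) nsb_eval(basis, t, deriv = 2L)
  # maximal acceleration at takeoff: 2*amp/T, the triangle whose integral
  # over the rise is exactly the velocity gain amp (one row is therefore
  # redundant but consistent)
  a_max <- 2 * (targets$phv - targets$ogsv) / (targets$aphv - targets$aogs)
  A <- rbind(vel_row(targets$aogs),           # v(aogs)  = ogsv
             acc_row(targets$aogs),           # v'(aogs) = a_max
             vel_row(targets$aphv),           # v(aphv)  = phv
             acc_row(targets$aphv),           # v'(aphv) = 0
             vel_row(end))                    # v(end)   = ogsv
  b <- c(targets$ogsv, a_max, targets$phv, 0, targets$ogsv)

  # equality-constrained least squares via the null-space method; redundant
  # constraints (the triangular acceleration rows imply one velocity row)
  # are dropped if consistent
  qa <- qr(t(A))
  k <- qa$rank
  Q <- qr.Q(qa, complete = TRUE)
  R1 <- qr.R(qa)[seq_len(k), seq_len(k), drop = FALSE]
  c0 <- Q[, seq_len(k), drop = FALSE] %*%
    forwardsolve(t(R1), b[qa$pivot][seq_len(k)])
  if (max(abs(A %*% c0 - b)) > 1e-6)
    stop("inconsistent calibration constraints")
  if (k < ncol(A)) {
    Z <- Q[, -seq_len(k), drop = FALSE]
    z <- qr.solve(X %*% Z, r - drop(X %*% c0))
    spl_coef <- drop(c0 + Z %*% z)
  } else {
    spl_coef <- drop(c0)
  }
  intercept <- h7 - drop(nsb_eval(basis, 7) %*% spl_coef)

  tpl <- growth_template(basis, c(intercept, spl_coef), sex = sex)
  ach <- extract_spurt_curve(function(t) template_velocity(tpl, t),
                             acceleration = function(t) template_accel(tpl, t),
                             window = c(7, 16), search_limit = 18)
  ok <- nzchar(ach$flag) == FALSE &&
    abs(ach$aogs - targets$aogs) < tol_age &&
    abs(ach$aphv - targets$aphv) < tol_age &&
    abs(ach$phv - targets$phv) < tol_vel &&
    abs(ach$ogsv - targets$ogsv) < tol_vel &&
    abs(ach$gsi - targets$gsi) < 2 * tol_age &&
    min(template_velocity(tpl, grid)) > 0
  tpl$calibration <- list(targets = targets, achieved = ach, verified = ok)
  if (!ok) {
    stop("template calibration failed to reproduce the requested spurt ",
         "parameters; achieved: ",
         paste(sprintf("%s=%.3f", names(ach)[1:6], unlist(ach[1:6])),
               collapse = ", "))
  }
  tpl
}
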