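#' @title Shape-invariant (SITAR) growth model
#' @description The SITAR model describes every individual's height curve as
#'   a common natural cubic spline mean curve transformed by three
#'   subject-level random effects: a vertical size shift (alpha, cm), a
#'   horizontal tempo shift (beta, years), and a log-scale velocity factor
#'   (gamma) that compresses or stretches the age axis about a pivot age.
#'   Writing \eqn{x = c + (t - c - \beta_i) e^{\gamma_i}} for pivot `c`,
#'   \deqn{h_{it} = \alpha_i + g(x),}
#'   with height velocity \eqn{v_{it} = e^{\gamma_i} g'(x)}. Estimation is by
#'   approximate maximum likelihood via block-coordinate ascent: the spline
#'   coefficients, the per-subject effects (penalised by their covariance),
#'   and the variance components are updated in turn until the penalised
#'   log-likelihood stabilises.
#' @name sitar-model
NULL

.sitar_transform <- function(t, beta, gamma, pivot) {
  pivot + (t - pivot - beta) * exp(gamma)
}

# penalised complete-data log-likelihood: the objective of the alternating
# fit; every block update (spline refit, effect update, variance update)
# maximises it over its own block, so it is non-decreasing across outer
# iterations
.sitar_objective <- function(resid, U, sigma2, omega_inv, omega_logdet) {
  n <- nrow(U)
  N <- length(resid)
  -0.5 * N * log(2 * pi * sigma2) - sum(resid^2) / (2 * sigma2) -
    0.5 * n * (3 * log(2 * pi) + omega_logdet) -
    0.5 * sum((U %*% omega_inv) * U)
}

#' Fit the SITAR model to longitudinal height data
#'
#' @param data a [growth_data()] dataset (one sex; a mixed-sex dataset is
#'   fitted pooled, with a warning).
#' @param df number of spline basis functions for the mean curve; `df - 1`
#'   interior knots are placed at equally spaced quantiles of the observed
#'   ages. The default 6 puts interior knots at the sextiles, which is the
#'   coarsest grid that resolves the takeoff of both sexes (see the package
#'   vignette).
#' @param options list of fit options: `tol` (relative log-likelihood change
#'   declaring convergence, default 1e-6), `max_iter` (default 200),
#'   `min_measurements` (subjects with fewer are dropped, default 3),
#'   `guard` (extrapolation guard band in years, default 0.25),
#'   `pivot` (age-axis pivot; default mean observed age),
#'   `knots` (explicit interior knots overriding quantile placement; the
#'   study pipeline places them at the spurt landmarks of the stratum's
#'   template, since quantile knots cannot resolve the takeoff, see the
#'   vignette) and `boundary_knots` (with `knots`; default the age range).
#' @return object of class `sitar_fit`: spline `basis` and `coef`
#'   (intercept first), per-subject `effects` (alpha/beta/gamma, centred),
#'   `omega` (random-effect covariance including the Laplace conditional
#'   covariance), `resid_sd`, `logLik_trace`, `converged`, `iterations`,
#'   `pivot`, and the subject table used.
#' @export
fit_sitar <- function(data, df = 6L, options = list()) {
  stopifnot(inherits(data, "growth_data"))
  opt <- utils::modifyList(
    list(tol = 1e-6, max_iter = 200L, min_measurements = 3L, guard = 0.25,
         pivot = NULL, knots = NULL, boundary_knots = NULL), options)

  counts <- table(data$subject_id)
  small <- names(counts)[counts < opt$min_measurements]
  if (length(small)) {
    warning(length(small), " subject(s) with fewer than ",
            opt$min_measurements, " measurements dropped", call. = FALSE)
    data <- data[!data$subject_id %in% small, , drop = FALSE]
  }
  ids <- unique(data$subject_id)
  n <- length(ids)
  if (n < 2L) stop("need at least 2 subjects to fit")
  if (n < 20L) warning("fewer than 20 subjects; estimates will be unstable",
                       call. = FALSE)
  if (length(unique(data$sex)) > 1L)
    warning("mixed-sex dataset fitted as a single stratum", call. = FALSE)

  y <- data$height
  t_age <- data$age
  idx <- match(data$subject_id, ids)
  pivot <- if (is.null(opt$pivot)) mean(t_age) else opt$pivot
  basis <- if (is.null(opt$knots)) {
    natural_spline_basis(t_age, df = df)
  } else {
    natural_spline_basis(t_age, interior_knots = opt$knots,
                         boundary_knots = opt$boundary_knots)
  }

  # deterministic initialisation: size offsets from subject means,
  # no tempo/velocity shifts
  subj_mean <- tapply(y, idx, mean)
  U <- cbind(alpha = as.numeric(subj_mean - mean(y)), beta = 0, gamma = 0)
  omega <- diag(c(max(stats::var(U[, 1]), 1), 0.25, 0.01))
  sigma2 <- 1
  theta <- NULL

  g_eval <- function(x, deriv = 0L) {
    X <- cbind(if (deriv == 0L) 1 else 0, nsb_eval(basis, x, deriv))
    drop(X %*% theta)
  }

  refit_spline <- function() {
    x <- .sitar_transform(t_age, U[idx, 2], U[idx, 3], pivot)
    X <- cbind(1, nsb_eval(basis, x))
    theta <<- qr.coef(qr(X), y - U[idx, 1])
    drop(y - U[idx, 1] - X %*% theta)
  }

  update_effects <- function(omega_inv) {
    by_subj <- split(seq_along(y), idx)
    for (i in seq_len(n)) {
      rows <- by_subj[[i]]
      yi <- y[rows]; ti <- t_age[rows]
      fn <- function(u) {
        x <- .sitar_transform(ti, u[2], u[3], pivot)
        r <- yi - u[1] - g_eval(x)
        sum(r^2) / (2 * sigma2) + 0.5 * drop(u %*% omega_inv %*% u)
      }
      gr <- function(u) {
        x <- .sitar_transform(ti, u[2], u[3], pivot)
        r <- yi - u[1] - g_eval(x)
        gp <- g_eval(x, 1L)
        pen <- drop(omega_inv %*% u)
        c(-sum(r) / sigma2 + pen[1],
          sum(r * gp) * exp(u[3]) / sigma2 + pen[2],
          -sum(r * gp * (x - pivot)) / sigma2 + pen[3])
      }
      res <- stats::optim(U[i, ], fn, gr, method = "BFGS",
                          control = list(maxit = 50))
      if (res$value <= fn(U[i, ])) U[i, ] <<- res$par
    }
  }

  by_subj <- split(seq_along(y), idx)

  # Gauss-Newton conditional (Laplace) covariance at the current modes:
  # per-subject V_i = (J'J/s2 + W)^-1 with J the Jacobian of the
  # predictions in (alpha, beta, gamma)
  laplace_V <- function(omega_inv) {
    Vsum <- matrix(0, 3, 3)
    for (i in seq_len(n)) {
      rows <- by_subj[[i]]
      x <- .sitar_transform(t_age[rows], U[i, 2], U[i, 3], pivot)
      gp <- g_eval(x, 1L)
      J <- cbind(1, -gp * exp(U[i, 3]), gp * (x - pivot))
      Vsum <- Vsum + chol2inv(chol(crossprod(J) / sigma2 + omega_inv))
    }
    Vsum
  }

  resid <- refit_spline()
  sigma2 <- mean(resid^2)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    omega_inv <- .solve_psd(omega)
    update_effects(omega_inv)
    resid <- refit_spline()
    sigma2 <- mean(resid^2)
    omega <- crossprod(U) / n
    omega_inv <- .solve_psd(omega)
    ll <- .sitar_objective(resid, U, sigma2, omega_inv,
                           determinant(omega)$modulus[1])
    trace <- c(trace, ll)
    if (iter >= 2L) {
      rel <- abs(ll - trace[iter - 1L]) /
        (abs(trace[iter - 1L]) + .Machine$double.eps)
      if (rel < opt$tol) { converged <- TRUE; break }
    }
    if (iter >= opt$max_iter) break
  }
  if (!converged)
    warning("SITAR fit did not converge in ", opt$max_iter, " iterations",
            call. = FALSE)

  # centring polish: absorb the random-effect means into the mean curve.
  # A mean tempo/velocity shift is not exactly representable by reshaping
  # g alone (subjects with different gamma respond differently), so after
  # each recentring the effects are re-optimised and the cycle repeats
  # until the means vanish; the final pass recentres exactly and refits
  # only the mean curve, which leaves the effects untouched.
  for (polish in 1:6) {
    drift <- colMeans(U)
    U <- sweep(U, 2, drift)
    resid <- refit_spline()
    sigma2 <- mean(resid^2)
    omega <- crossprod(U) / n
    if (max(abs(drift)) < 1e-8) break
    update_effects(.solve_psd(omega))
  }
  U <- sweep(U, 2, colMeans(U))
  resid <- refit_spline()
  sigma2 <- mean(resid^2)

  # report Omega with the Laplace conditional covariance added, so the
  # random-effect dispersion is not understated by shrinkage
  omega <- crossprod(U) / n
  omega <- omega + laplace_V(.solve_psd(omega)) / n
  dimnames(omega) <- list(c("size", "tempo", "velocity"),
                          c("size", "tempo", "velocity"))

  subjects <- data.frame(
    subject_id = ids,
    sex = data$sex[match(ids, data$subject_id)],
    n_obs = as.integer(counts[ids]),
    stringsAsFactors = FALSE)
  effects <- data.frame(subjects, alpha = U[, 1], beta = U[, 2],
                        gamma = U[, 3], stringsAsFactors = FALSE)

  structure(list(basis = basis, coef = theta, pivot = pivot, df = basis$df,
                 effects = effects, omega = omega,
                 resid_sd = sqrt(sigma2), logLik_trace = trace,
                 converged = converged, iterations = iter,
                 guard = opt$guard, n_measurements = length(y)),
            class = "sitar_fit")
}

# inverse of a symmetric PSD matrix, ridge-regularised if needed
.solve_psd <- function(S) {
  out <- tryCatch(chol2inv(chol(S)), error = function(e) NULL)
  if (is.null(out)) {
    warning("near-singular covariance; ridge regularisation applied",
            call. = FALSE)
    out <- chol2inv(chol(S + diag(1e-8 * max(diag(S), 1), nrow(S))))
  }
  out
}

#' @export
print.sitar_fit <- function(x, ...) {
  cat("SITAR fit:", nrow(x$effects), "subjects,", x$n_measurements,
      "measurements\n")
  cat("  spline df:", x$df, " pivot:", format(x$pivot, digits = 4), "\n")
  cat("  residual SD:", format(x$resid_sd, digits = 3), "cm;",
      if (x$converged) "converged" else "NOT converged", "in",
      x$iterations, "iterations\n")
  cat("  random-effect SDs:",
      format(sqrt(diag(x$omega)), digits = 3), "\n")
  invisible(x)
}

.effects_for <- function(fit, subject) {
  if (is.character(subject)) {
    i <- match(subject, fit$effects$subject_id)
    if (is.na(i)) stop("subject not in fit: ", subject)
    unlist(fit$effects[i, c("alpha", "beta", "gamma")])
  } else {
    stopifnot(length(subject) == 3L)
    as.numeric(subject)
  }
}

.check_ages <- function(fit, ages, extrapolate) {
  lim <- fit$basis$boundary_knots + c(-1, 1) * fit$guard
  if (!extrapolate && (any(ages < lim[1]) || any(ages > lim[2])))
    stop("ages outside the supported range [",
         format(lim[1], digits = 4), ", ", format(lim[2], digits = 4),
         "]; set extrapolate = TRUE to override")
}

#' Predict height from a SITAR fit
#'
#' @param fit a `sitar_fit`.
#' @param subject a subject id present in the fit, or a numeric
#'   (alpha, beta, gamma) triple; `c(0, 0, 0)` gives the mean curve.
#' @param ages ages (years) at which to predict.
#' @param extrapolate allow ages beyond the boundary knots plus the guard
#'   band (the spline continues linearly there).
#' @return heights in cm.
#' @export
predict_height <- function(fit, subject = c(0, 0, 0), ages,
                           extrapolate = FALSE) {
  stopifnot(inherits(fit, "sitar_fit"))
  u <- .effects_for(fit, subject)
  .check_ages(fit, ages, extrapolate)
  x <- .sitar_transform(ages, u[2], u[3], fit$pivot)
  u[1] + drop(cbind(1, nsb_eval(fit$basis, x)) %*% fit$coef)
}

#' Predict height velocity from a SITAR fit
#'
#' The analytic derivative of [predict_height()] with respect to age:
#' \eqn{v(t) = e^{\gamma} g'(c + (t - c - \beta) e^{\gamma})}.
#'
#' @inheritParams predict_height
#' @return velocities in cm/year.
#' @export
predict_velocity <- function(fit, subject = c(0, 0, 0), ages,
                             extrapolate = FALSE) {
  stopifnot(inherits(fit, "sitar_fit"))
  u <- .effects_for(fit, subject)
  .check_ages(fit, ages, extrapolate)
  x <- .sitar_transform(ages, u[2], u[3], fit$pivot)
  exp(u[3]) * drop(nsb_eval(fit$basis, x, 1L) %*% fit$coef[-1L])
}

#' Mean absolute error of a SITAR fit on a dataset
#'
#' Mean over all measurements of |observed - predicted| using each
#' subject's own fitted random effects.
#'
#' @param fit a `sitar_fit`.
#' @param data a [growth_data()] dataset whose subjects are all present in
#'   the fit.
#' @return MAE in cm.
#' @export
mean_absolute_error <- function(fit, data) {
  stopifnot(inherits(fit, "sitar_fit"), inherits(data, "growth_data"))
  missing_subj <- setdiff(unique(data$subject_id), fit$effects$subject_id)
  if (length(missing_subj))
    stop("subject(s) absent from fit: ",
         paste(utils::head(missing_subj, 5), collapse = ", "))
  i <- match(data$subject_id, fit$effects$subject_id)
  x <- .sitar_transform(data$age, fit$effects$beta[i], fit$effects$gamma[i],
                        fit$pivot)
  pred <- fit$effects$alpha[i] +
    drop(cbind(1, nsb_eval(fit$basis, x)) %*% fit$coef)
  mean(abs(data$height - pred))
}

#' Extract pubertal spurt parameters for subjects of a SITAR fit
#'
#' Runs the takeoff/peak/end extraction on each subject's fitted velocity
#' curve. Subjects whose peak or takeoff lands on the search-window boundary
#' or whose spurt end is censored at the search limit are flagged and should
#' be excluded from summaries (`flag` column non-empty).
#'
#' @param fit a `sitar_fit`.
#' @param subjects subject ids (default: all subjects in the fit).
#' @param window age window searched for the takeoff and peak.
#' @param search_limit latest age searched for the spurt end.
#' @return data frame with one row per subject: `subject_id`, `sex`,
#'   `aogs`, `ogsv`, `aphv`, `phv`, `end_age`, `gsi`, `flag`.
#' @export
extract_spurt_parameters <- function(fit, subjects = NULL,
                                     window = c(7, 16), search_limit = 18) {
  stopifnot(inherits(fit, "sitar_fit"))
  if (is.null(subjects)) subjects <- fit$effects$subject_id
  rows <- lapply(subjects, function(id) {
    u <- .effects_for(fit, id)
    vel <- function(t) predict_velocity(fit, u, t, extrapolate = TRUE)
    acc <- function(t) {
      x <- .sitar_transform(t, u[2], u[3], fit$pivot)
      exp(2 * u[3]) * drop(nsb_eval(fit$basis, x, 2L) %*% fit$coef[-1L])
    }
    out <- extract_spurt_curve(vel, acc, window = window,
                               search_limit = search_limit)
    cbind(data.frame(subject_id = id,
                     sex = fit$effects$sex[match(id,
                                                 fit$effects$subject_id)],
                     stringsAsFactors = FALSE),
          out)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Serialise a SITAR fit to a plain-text JSON document
#'
#' All numeric values are written in full precision (17 significant digits),
#' so a read-back fit reproduces coefficients and effects exactly.
#'
#' @param fit a `sitar_fit`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sitar_fit <- function(fit, path) {
  stopifnot(inherits(fit, "sitar_fit"))
  doc <- list(
    format = "growthspurt-sitar-fit",
    version = 1L,
    df = fit$df,
    pivot = fit$pivot,
    guard = fit$guard,
    basis = list(interior_knots = fit$basis$interior_knots,
                 boundary_knots = fit$basis$boundary_knots),
    coef = fit$coef,
    effects = fit$effects,
    omega = fit$omega,
    resid_sd = fit$resid_sd,
    logLik_trace = fit$logLik_trace,
    converged = fit$converged,
    iterations = fit$iterations,
    n_measurements = fit$n_measurements)
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read back a serialised SITAR fit
#' @param path path written by [write_sitar_fit()].
#' @return a `sitar_fit`.
#' @export
read_sitar_fit <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "growthspurt-sitar-fit"))
    stop("not a serialised SITAR fit: ", path)
  basis <- natural_spline_basis(doc$basis$boundary_knots,
                                interior_knots = doc$basis$interior_knots,
                                boundary_knots = doc$basis$boundary_knots)
  omega <- as.matrix(doc$omega)
  dimnames(omega) <- list(c("size", "tempo", "velocity"),
                          c("size", "tempo", "velocity"))
  structure(list(basis = basis, coef = doc$coef, pivot = doc$pivot,
                 df = doc$df, effects = doc$effects, omega = omega,
                 resid_sd = doc$resid_sd, logLik_trace = doc$logLik_trace,
                 converged = doc$converged, iterations = doc$iterations,
                 guard = doc$guard, n_measurements = doc$n_measurements),
            class = "sitar_fit")
}
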