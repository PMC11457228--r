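#' @title Pubertal growth-spurt parameter extraction
#' @description Locate the pubertal growth spurt on a height-velocity curve:
#'   the takeoff (age of onset of the growth spurt, at maximum acceleration),
#'   the peak (age at and magnitude of peak height velocity), and the spurt
#'   end (where velocity falls back to its takeoff value), together with the
#'   growth spurt interval between takeoff and end.
#' @name spurt-extraction
NULL

# dense grid scan followed by local refinement; returns location, value and
# whether the maximum sits on the window boundary
.grid_argmax <- function(f, lower, upper, step = 0.01, tol = 1e-4) {
  if (upper - lower < 2 * step) {
    return(list(x = NA_real_, y = NA_real_, boundary = TRUE))
  }
  grid <- seq(lower, upper, by = step)
  vals <- f(grid)
  i <- which.max(vals)
  if (i == 1L || i == length(grid)) {
    return(list(x = grid[i], y = vals[i], boundary = TRUE))
  }
  opt <- stats::optimize(f, lower = grid[i - 1L], upper = grid[i + 1L],
                         maximum = TRUE, tol = tol)
  list(x = opt$maximum, y = opt$objective, boundary = FALSE)
}

#' Locate peak height velocity
#'
#' Finds the global maximum of a velocity curve over a search window by a
#' dense grid scan (default step 0.01 years) followed by local refinement.
#'
#' @param velocity function of age returning height velocity in cm/year.
#' @param window length-2 numeric, the age interval searched.
#' @param step grid step in years.
#' @param tol refinement tolerance in years.
#' @return list with `aphv` (years), `phv` (cm/year) and logical `boundary`
#'   set when the maximum lies on the window edge (no interior peak).
#' @export
find_peak <- function(velocity, window, step = 0.01, tol = 1e-4) {
  stopifnot(is.function(velocity), length(window) == 2L, diff(window) > 0)
  res <- .grid_argmax(velocity, window[1], window[2], step, tol)
  list(aphv = res$x, phv = res$y, boundary = res$boundary)
}

#' Locate the takeoff (onset of the growth spurt)
#'
#' The takeoff is the age at which the velocity curve rises most steeply,
#' i.e. the maximum of the acceleration (first derivative of velocity) before
#' the age at peak height velocity. The velocity at that age is the
#' onset-of-growth-spurt velocity.
#'
#' @param velocity function of age returning velocity (cm/year).
#' @param aphv age at peak height velocity (upper end of the search).
#' @param window length-2 numeric search window; its upper end is capped at
#'   `aphv`.
#' @param acceleration optional function of age returning the derivative of
#'   velocity; when omitted a central finite difference of `velocity` is used.
#' @param step,tol grid step and refinement tolerance in years.
#' @return list with `aogs` (years), `ogsv` (cm/year) and logical `boundary`.
#' @export
find_takeoff <- function(velocity, aphv, window, acceleration = NULL,
                         step = 0.01, tol = 1e-4) {
  stopifnot(is.function(velocity), is.finite(aphv))
  upper <- min(window[2], aphv)
  if (is.null(acceleration)) {
    h <- 1e-4
    acceleration <- function(t) (velocity(t + h) - velocity(t - h)) / (2 * h)
  }
  res <- .grid_argmax(acceleration, window[1], upper, step, tol)
  list(aogs = res$x,
       ogsv = if (is.na(res$x)) NA_real_ else velocity(res$x),
       boundary = res$boundary)
}

#' Locate the end of the growth spurt
#'
#' The end of the spurt is the first age after the peak at which velocity has
#' fallen back to the onset-of-growth-spurt velocity, found by bracketing and
#' root refinement on `velocity(t) - ogsv`.
#'
#' @param velocity function of age returning velocity (cm/year).
#' @param aphv age at peak height velocity.
#' @param ogsv onset-of-growth-spurt velocity (cm/year).
#' @param search_limit latest age searched; if velocity never falls to
#'   `ogsv` before it, the end age is censored at the limit.
#' @param tol root tolerance in years.
#' @return list with `end_age` (years) and logical `censored`.
#' @export
find_spurt_end <- function(velocity, aphv, ogsv, search_limit = 18,
                           tol = 1e-4) {
  stopifnot(is.function(velocity), is.finite(aphv), is.finite(ogsv))
  if (search_limit <= aphv) return(list(end_age = NA_real_, censored = TRUE))
  grid <- seq(aphv, search_limit, by = 0.01)
  below <- velocity(grid) - ogsv < 0
  idx <- which(below)[1]
  if (is.na(idx) || idx == 1L) {
    return(list(end_age = search_limit, censored = TRUE))
  }
  root <- stats::uniroot(function(t) velocity(t) - ogsv,
                         lower = grid[idx - 1L], upper = grid[idx],
                         tol = tol)
  list(end_age = root$root, censored = FALSE)
}

#' Extract all five spurt parameters from a velocity curve
#'
#' Composes [find_peak()], [find_takeoff()] and [find_spurt_end()]. Curves on
#' which any component lands on a window boundary, or whose spurt end is
#' censored at the search limit, are flagged; flagged rows carry the partial
#' results but should be excluded from cohort summaries.
#'
#' @param velocity function of age returning velocity (cm/year).
#' @param acceleration optional analytic derivative of `velocity`.
#' @param window length-2 age window searched for the peak and takeoff.
#' @param search_limit latest age searched for the spurt end.
#' @param step,tol grid step and refinement tolerance in years.
#' @return one-row data frame with columns `aogs`, `ogsv`, `aphv`, `phv`,
#'   `end_age`, `gsi` and `flag` ("" when clean, otherwise a comma-separated
#'   list of `peak_boundary`, `takeoff_boundary`, `end_censored`).
#' @export
extract_spurt_curve <- function(velocity, acceleration = NULL,
                                window = c(7, 16), search_limit = 18,
                                step = 0.01, tol = 1e-4) {
  flags <- character(0)
  pk <- find_peak(velocity, window, step, tol)
  if (pk$boundary) flags <- c(flags, "peak_boundary")
  tk <- list(aogs = NA_real_, ogsv = NA_real_, boundary = TRUE)
  en <- list(end_age = NA_real_, censored = TRUE)
  if (!pk$boundary) {
    tk <- find_takeoff(velocity, pk$aphv, window, acceleration, step, tol)
    if (tk$boundary) flags <- c(flags, "takeoff_boundary")
    if (!tk$boundary) {
      en <- find_spurt_end(velocity, pk$aphv, tk$ogsv, search_limit, tol)
      if (en$censored) flags <- c(flags, "end_censored")
    }
  }
  data.frame(aogs = tk$aogs, ogsv = tk$ogsv, aphv = pk$aphv, phv = pk$phv,
             end_age = en$end_age,
             gsi = if (en$censored || tk$boundary) NA_real_ else
               en$end_age - tk$aogs,
             flag = paste(flags, collapse = ","),
             stringsAsFactors = FALSE)
}
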