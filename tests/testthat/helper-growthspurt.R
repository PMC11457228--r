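# shared fixtures: built in code, cached across test files within a run

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# strip bookkeeping attributes so datasets can be compared on content
plain <- function(x) {
  x <- as.data.frame(x)
  attributes(x) <- attributes(x)[c("names", "row.names", "class")]
  rownames(x) <- NULL
  x
}

reference_means <- list(
  male = list(aogs = 10.17, ogsv = 5.43, aphv = 12.46, phv = 9.61,
              gsi = 3.58),
  female = list(aogs = 8.57, ogsv = 5.10, aphv = 10.99, phv = 8.32,
                gsi = 3.72))

boys_template <- function() memo("boys_template",
  calibrate_template(reference_means$male, h7 = 122.9, sex = "male"))

girls_template <- function() memo("girls_template",
  calibrate_template(reference_means$female, h7 = 121.8, sex = "female"))

boys_preset <- function() memo("boys_preset", load_preset("boys_gp2024"))
girls_preset <- function() memo("girls_preset", load_preset("girls_gp2024"))

# wrap a template plus per-subject effects as a sitar_fit, so prediction and
# extraction can be exercised against exactly known curves without fitting
template_as_fit <- function(template, effects, pivot = 11.5) {
  eff <- data.frame(subject_id = effects$subject_id,
                    sex = template$sex,
                    n_obs = NA_integer_,
                    alpha = effects$alpha, beta = effects$beta,
                    gamma = effects$gamma, stringsAsFactors = FALSE)
  structure(list(basis = template$basis, coef = template$coef,
                 pivot = pivot, df = template$basis$df, effects = eff,
                 omega = diag(3), resid_sd = 0, logLik_trace = numeric(0),
                 converged = TRUE, iterations = 0L, guard = 0.25,
                 n_measurements = 0L),
            class = "sitar_fit")
}

# small toy long-format table used by the data-handling tests
toy_growth_df <- function() {
  data.frame(
    subject_id = rep(c("A", "B", "C"), times = c(6, 4, 5)),
    sex = "male",
    age = c(7.5, 9.0, 11.0, 13.0, 15.0, 16.5,   # A: all five segments
            7.5, 9.0, 11.0, 13.0,               # B: nothing in [14.2, 16)
            7.2, 10.0, 11.5, 12.6, 14.8),       # C: all five segments
    height = c(121, 130, 139, 152, 166, 171,
               123, 131, 140, 153,
               120, 136, 142, 150, 163),
    stringsAsFactors = FALSE)
}

# a small quick-to-fit cohort: fewer subjects, reduced fit tolerance
small_fit <- function(seed = 11, n = 30, preset = boys_preset(),
                      tol = 1e-5, max_iter = 120) {
  d <- simulate_cohort(preset, n, seed = seed)
  fit <- fit_sitar(d, options = list(
    knots = preset$template$basis$interior_knots,
    boundary_knots = preset$template$basis$boundary_knots,
    pivot = preset$age_pivot, tol = tol, max_iter = max_iter))
  list(data = d, fit = fit)
}

# the six pipeline fits of the recovery experiment (both sexes, seeds 1-3),
# shared between the acceptance criteria
recovery_runs <- function(seeds = 1:3) {
  lapply(c(male = "boys_gp2024", female = "girls_gp2024"), function(p) {
    pre <- load_preset(p)
    lapply(seeds, function(s) memo(paste0("recov_", p, "_", s), {
      d <- simulate_cohort(pre, 150, seed = s)
      dd <- filter_age_segments(d)
      fit <- fit_sitar(dd, options = list(
        knots = pre$template$basis$interior_knots,
        boundary_knots = pre$template$basis$boundary_knots,
        pivot = pre$age_pivot))
      sp <- extract_spurt_parameters(fit)
      list(data = d, filtered = dd, fit = fit, params = sp,
           clean = sp[!nzchar(sp$flag), ])
    }))
  })
}
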