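#' @title Cohort presets and the synthetic cohort generator
#' @description A cohort preset bundles everything needed to simulate a
#'   mixed-longitudinal height cohort for one sex: the calibrated template
#'   mean curve, the covariance structure of the size/tempo/velocity random
#'   effects, the measurement noise scale, and the school-visit schedule with
#'   its missingness. The packaged presets `boys_gp2024` and `girls_gp2024`
#'   are calibrated so the template's own spurt parameters equal the cohort
#'   means the pipeline is meant to recover.
#' @name cohort-presets
NULL

.preset_cache <- new.env(parent = emptyenv())

#' Construct a cohort preset
#'
#' @param sex "male" or "female".
#' @param template a calibrated [growth_template()].
#' @param re_sds length-3 numeric: SDs of the size (cm), tempo (years) and
#'   velocity (log-scale) random effects.
#' @param re_corr 3x3 correlation matrix of the random effects
#'   (size/tempo/velocity order); must be symmetric positive semidefinite
#'   with unit diagonal.
#' @param noise_sd measurement noise SD in cm.
#' @param schedule numeric vector of nominal visit ages (years).
#' @param visit_jitter half-width of the uniform jitter applied to each
#'   nominal visit age (years).
#' @param miss_prob probability in [0, 1) that any scheduled visit is missed.
#' @param age_pivot pivot age (years) about which the tempo/velocity
#'   transformation stretches the age axis.
#' @return object of class `cohort_preset`.
#' @export
cohort_preset <- function(sex, template, re_sds, re_corr, noise_sd,
                          schedule, visit_jitter = 0.25, miss_prob = 0.31,
                          age_pivot = 11.5) {
  stopifnot(sex %in% .VALID_SEX, inherits(template, "growth_template"),
            length(re_sds) == 3L, all(re_sds >= 0),
            is.matrix(re_corr), all(dim(re_corr) == 3L),
            noise_sd >= 0, length(schedule) >= 1L,
            miss_prob >= 0, miss_prob < 1)
  if (max(abs(re_corr - t(re_corr))) > 1e-8 ||
      max(abs(diag(re_corr) - 1)) > 1e-8)
    stop("re_corr must be symmetric with unit diagonal")
  ev <- eigen(re_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("re_corr must be positive semidefinite")
  structure(list(sex = sex, template = template,
                 re_sds = stats::setNames(as.numeric(re_sds),
                                          c("size", "tempo", "velocity")),
                 re_corr = re_corr, noise_sd = noise_sd,
                 schedule = as.numeric(schedule),
                 visit_jitter = visit_jitter, miss_prob = miss_prob,
                 age_pivot = age_pivot),
            class = "cohort_preset")
}

#' @export
print.cohort_preset <- function(x, ...) {
  cat("Cohort preset (", x$sex, ")\n", sep = "")
  cat("  random-effect SDs:", format(x$re_sds, digits = 3), "\n")
  cat("  noise SD:", x$noise_sd, "cm;",
      length(x$schedule), "nominal visits, miss prob", x$miss_prob, "\n")
  invisible(x)
}

#' Load a packaged (or external) cohort preset
#'
#' Packaged presets are YAML files describing the calibration targets and
#' generative parameters; the template is calibrated on first use and
#' cached. `boys_gp2024` and `girls_gp2024` are the sex-specific defaults.
#'
#' @param name preset name (without extension) or a path to a YAML file.
#' @return a `cohort_preset`.
#' @export
load_preset <- function(name) {
  if (file.exists(name)) {
    path <- name
  } else {
    path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                        package = "growthspurt")
    if (!nzchar(path)) stop("unknown preset: ", name)
  }
  key <- normalizePath(path)
  if (!is.null(.preset_cache[[key]])) return(.preset_cache[[key]])
  y <- yaml::read_yaml(path)
  template <- calibrate_template(y$template$targets, h7 = y$template$h7,
                                 sex = y$sex)
  sched <- seq(y$schedule$from, y$schedule$to, by = y$schedule$by)
  preset <- cohort_preset(
    sex = y$sex, template = template,
    re_sds = unlist(y$random_effects$sds),
    re_corr = matrix(unlist(y$random_effects$correlation), 3, 3),
    noise_sd = y$noise_sd, schedule = sched,
    visit_jitter = y$schedule$jitter, miss_prob = y$schedule$miss_prob,
    age_pivot = y$age_pivot)
  .preset_cache[[key]] <- preset
  preset
}

# deterministic per-subject sub-stream: subject k of a cohort seeded with s
# always sees the same draws, whatever n_subjects is; the sex enters the
# stream so male and female cohorts with the same seed are independent
.subject_seed <- function(seed, k, sex = "male") {
  sex_code <- if (identical(sex, "female")) 1 else 0
  as.integer(((as.numeric(seed) + 7919 * sex_code) * 100003 + k) %%
               2147483647)
}

#' Simulate a mixed-longitudinal height cohort
#'
#' For each subject a size/tempo/velocity triple is drawn from the zero-mean
#' trivariate normal implied by the preset, visit ages are drawn from the
#' jittered schedule with independent per-visit missingness, and heights
#' follow the shape-invariant model around the template curve plus Gaussian
#' measurement noise. Fully reproducible: the same seed, preset and subject
#' index always produce the same measurements.
#'
#' @param preset a [cohort_preset()].
#' @param n_subjects number of subjects to simulate.
#' @param seed integer seed for the cohort.
#' @return a [growth_data()] dataset; per-subject true random effects are
#'   attached as attribute `true_effects`.
#' @export
simulate_cohort <- function(preset, n_subjects, seed = 1L) {
  stopifnot(inherits(preset, "cohort_preset"), n_subjects >= 1L)
  Sigma <- diag(preset$re_sds) %*% preset$re_corr %*% diag(preset$re_sds)
  c0 <- preset$age_pivot
  tpl <- preset$template
  prefix <- if (preset$sex == "male") "M" else "F"

  rows <- vector("list", n_subjects)
  eff <- matrix(NA_real_, n_subjects, 3,
                dimnames = list(NULL, c("alpha", "beta", "gamma")))
  for (k in seq_len(n_subjects)) {
    set.seed(.subject_seed(seed, k, preset$sex))
    u <- drop(MASS::mvrnorm(1L, mu = c(0, 0, 0), Sigma = Sigma))
    eff[k, ] <- u
    ages <- preset$schedule +
      stats::runif(length(preset$schedule), -preset$visit_jitter,
                   preset$visit_jitter)
    keep <- stats::runif(length(ages)) >= preset$miss_prob
    ages <- ages[keep]
    if (!length(ages)) next
    x <- c0 + (ages - c0 - u[2]) * exp(u[3])
    h <- u[1] + template_height(tpl, x) +
      stats::rnorm(length(ages), 0, preset$noise_sd)
    rows[[k]] <- data.frame(
      subject_id = sprintf("%s%04d", prefix, k),
      sex = preset$sex, age = ages, height = h,
      stringsAsFactors = FALSE)
  }
  d <- growth_data(do.call(rbind, rows),
                   provenance = sprintf("simulated %s cohort, n=%d, seed=%d",
                                        preset$sex, n_subjects, seed))
  attr(d, "true_effects") <- data.frame(
    subject_id = sprintf("%s%04d", prefix, seq_len(n_subjects)), eff,
    stringsAsFactors = FALSE)
  d
}
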