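#' @title Cohort-level statistical summaries
#' @description Descriptive centile tables for the extracted spurt
#'   parameters, Pearson correlations among the fitted random effects, and
#'   top-versus-bottom quintile contrasts between spurt parameters.
#' @name growth-analysis
NULL

.CENTILES <- c(3, 5, 10, 25, 50, 75, 90, 95, 97) / 100

#' Descriptive statistics row for one parameter
#'
#' Mean, sample SD (n-1 denominator) and the nine standard centiles
#' (3/5/10/25/50/75/90/95/97%) computed by linear interpolation of order
#' statistics (quantile type 7).
#'
#' @param values numeric vector of per-subject parameter values (NAs
#'   dropped).
#' @param name parameter name carried into the row.
#' @return one-row data frame: `parameter`, `n`, `mean`, `sd`, `p3` ... `p97`.
#' @export
descriptive_table <- function(values, name = "parameter") {
  values <- values[!is.na(values)]
  if (length(values) < 2L) {
    warning("fewer than 2 usable values for ", name, call. = FALSE)
    out <- as.data.frame(as.list(rep(NA_real_, 2 + length(.CENTILES))))
  } else {
    q <- stats::quantile(values, .CENTILES, type = 7, names = FALSE)
    out <- as.data.frame(as.list(c(mean(values), stats::sd(values), q)))
  }
  names(out) <- c("mean", "sd", paste0("p", .CENTILES * 100))
  cbind(data.frame(parameter = name, n = length(values),
                   stringsAsFactors = FALSE), out)
}

#' Descriptive table for all spurt parameters of one stratum
#'
#' @param params extraction table from [extract_spurt_parameters()]; flagged
#'   subjects are excluded.
#' @return data frame with one [descriptive_table()] row per parameter
#'   (aogs, aphv, ogsv, phv, gsi).
#' @export
spurt_descriptives <- function(params) {
  clean <- params[!nzchar(params$flag), , drop = FALSE]
  rows <- lapply(c("aogs", "aphv", "ogsv", "phv", "gsi"), function(p)
    descriptive_table(clean[[p]], p))
  do.call(rbind, rows)
}

#' Pearson correlations among the SITAR random effects
#'
#' Pairwise Pearson correlation coefficients between the fitted size, tempo
#' and velocity effects, with two-sided p-values from the t transform with
#' n - 2 degrees of freedom.
#'
#' @param fit a `sitar_fit`, or a data frame with columns
#'   `alpha`, `beta`, `gamma`.
#' @return list with `r` (3x3 correlation matrix, unit diagonal), `p`
#'   (3x3 p-value matrix, NA diagonal) and `n`.
#' @export
random_effect_correlations <- function(fit) {
  eff <- if (inherits(fit, "sitar_fit")) fit$effects else fit
  U <- as.matrix(eff[, c("alpha", "beta", "gamma")])
  n <- nrow(U)
  if (n < 3L) stop("need at least 3 subjects for correlations")
  nm <- c("size", "tempo", "velocity")
  r <- matrix(1, 3, 3, dimnames = list(nm, nm))
  p <- matrix(NA_real_, 3, 3, dimnames = list(nm, nm))
  for (i in 1:2) for (j in (i + 1):3) {
    if (stats::sd(U[, i]) == 0 || stats::sd(U[, j]) == 0) {
      warning("zero-variance random effect; correlation undefined",
              call. = FALSE)
      r[i, j] <- r[j, i] <- NA_real_
      next
    }
    ct <- stats::cor.test(U[, i], U[, j], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(r = r, p = p, n = n)
}

#' Top-versus-bottom quintile contrast between two spurt parameters
#'
#' Subjects are ranked by one parameter; the mean of another parameter is
#' compared between the `floor(0.2 n)` highest-ranked and lowest-ranked
#' subjects with a Welch two-sample t-test. Ties straddling the group
#' boundary are resolved by a stable sort on subject id, which makes the
#' grouping deterministic.
#'
#' @param params extraction table from [extract_spurt_parameters()]; flagged
#'   subjects are excluded.
#' @param rank_by name of the ranking parameter column.
#' @param outcome name of the outcome parameter column.
#' @return one-row data frame: `rank_by`, `outcome`, `k` (per-group size),
#'   `diff` (top mean minus bottom mean), `t`, `p`.
#' @export
quintile_contrast <- function(params, rank_by, outcome) {
  stopifnot(rank_by %in% names(params), outcome %in% names(params))
  clean <- params[!nzchar(params$flag), , drop = FALSE]
  n <- nrow(clean)
  if (n < 10L) stop("need at least 10 unflagged subjects")
  k <- floor(0.2 * n)
  o <- order(clean[[rank_by]], clean$subject_id)
  bottom <- clean[[outcome]][o[seq_len(k)]]
  top <- clean[[outcome]][o[seq.int(n - k + 1L, n)]]
  tt <- stats::t.test(top, bottom, var.equal = FALSE)
  data.frame(rank_by = rank_by, outcome = outcome, k = k,
             diff = mean(top) - mean(bottom),
             t = unname(tt$statistic), p = tt$p.value,
             stringsAsFactors = FALSE)
}

#' All pairwise quintile contrasts among APHV, PHV and GSI
#'
#' @param params extraction table from [extract_spurt_parameters()].
#' @param vars parameters contrasted (each used as both ranking and outcome).
#' @return data frame of [quintile_contrast()] rows, ranking parameter
#'   varying slowest.
#' @export
quintile_contrast_table <- function(params, vars = c("aphv", "phv", "gsi")) {
  rows <- list()
  for (rk in vars) for (oc in vars)
    rows[[length(rows) + 1L]] <- quintile_contrast(params, rk, oc)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble the full report for one stratum
#'
#' Writes the descriptive table, the random-effect correlation matrices and
#' the contrast table as comma-separated files, plus a mean velocity curve
#' plot and a spurt-parameter boxplot. Deterministic given its inputs.
#'
#' @param fit a `sitar_fit` (one sex stratum).
#' @param params extraction table from [extract_spurt_parameters()].
#' @param contrasts contrast table from [quintile_contrast_table()], or NULL
#'   to omit the contrast section.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix, e.g. the stratum label.
#' @return named character vector of the files written, invisibly.
#' @export
build_report <- function(fit, params, contrasts = NULL, dir = ".",
                         prefix = "cohort") {
  stopifnot(inherits(fit, "sitar_fit"))
  if (length(unique(params$sex)) > 1L)
    stop("build_report expects a single-sex stratum")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  f <- file.path(dir, paste0(prefix, "_descriptives.csv"))
  utils::write.csv(spurt_descriptives(params), f, row.names = FALSE)
  files["descriptives"] <- f

  cors <- random_effect_correlations(fit)
  f <- file.path(dir, paste0(prefix, "_correlations.csv"))
  utils::write.csv(data.frame(effect = rownames(cors$r),
                              round(cors$r, 6)), f, row.names = FALSE)
  files["correlations"] <- f
  f <- file.path(dir, paste0(prefix, "_correlation_pvalues.csv"))
  utils::write.csv(data.frame(effect = rownames(cors$p),
                              signif(cors$p, 6)), f, row.names = FALSE)
  files["correlation_pvalues"] <- f

  if (!is.null(contrasts) && nrow(contrasts)) {
    f <- file.path(dir, paste0(prefix, "_contrasts.csv"))
    utils::write.csv(contrasts, f, row.names = FALSE)
    files["contrasts"] <- f
  }

  ages <- seq(fit$basis$boundary_knots[1], fit$basis$boundary_knots[2],
              length.out = 200)
  vdat <- data.frame(age = ages,
                     velocity = predict_velocity(fit, c(0, 0, 0), ages))
  pl <- ggplot2::ggplot(vdat, ggplot2::aes(x = age, y = velocity)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Age (years)", y = "Height velocity (cm/year)",
                  title = paste("Mean height velocity curve -", prefix)) +
    ggplot2::theme_minimal()
  f <- file.path(dir, paste0(prefix, "_velocity.png"))
  ggplot2::ggsave(f, pl, width = 6, height = 4, dpi = 120)
  files["velocity_plot"] <- f

  clean <- params[!nzchar(params$flag), , drop = FALSE]
  long <- do.call(rbind, lapply(c("aogs", "aphv", "ogsv", "phv", "gsi"),
    function(p) data.frame(parameter = toupper(p), value = clean[[p]])))
  pb <- ggplot2::ggplot(long, ggplot2::aes(x = parameter, y = value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~parameter, scales = "free", nrow = 1) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste("Spurt parameters -", prefix)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
  f <- file.path(dir, paste0(prefix, "_boxplots.png"))
  ggplot2::ggsave(f, pb, width = 8, height = 3, dpi = 120)
  files["boxplots"] <- f

  invisible(files)
}
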