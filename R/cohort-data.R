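#' @title Longitudinal height data handling
#' @description Long-format mixed-longitudinal height data: one row per
#'   measurement with subject id, sex, decimal age (years) and height (cm).
#'   Construction validates every row, enforces per-subject ordering and
#'   uniqueness, and keeps a machine-readable validation report.
#' @name cohort-data
NULL

.VALID_SEX <- c("male", "female")

#' Construct a validated longitudinal height dataset
#'
#' Rows violating the measurement invariants (age in [0, 25), height in
#' (50, 230) cm, non-empty subject id, known sex) are dropped and recorded in
#' the validation report, as are duplicate (subject, age) rows (first
#' occurrence kept) and rows whose sex conflicts with the subject's
#' first-seen sex. Measurements are sorted by subject and age.
#'
#' @param x data frame with columns `subject_id`, `sex`, `age`, `height`.
#' @param provenance free-text note on where the data came from.
#' @return object of class `growth_data` (a data frame) with attributes
#'   `provenance` and `validation` (a data frame of per-row issues).
#' @export
growth_data <- function(x, provenance = "") {
  need <- c("subject_id", "sex", "age", "height")
  if (!all(need %in% names(x)))
    stop("missing required columns: ",
         paste(setdiff(need, names(x)), collapse = ", "))
  n <- nrow(x)
  issues <- list()
  note <- function(row, field, issue) {
    issues[[length(issues) + 1L]] <<- data.frame(
      row = row, field = field, issue = issue, stringsAsFactors = FALSE)
  }

  id <- trimws(as.character(x$subject_id))
  sex <- tolower(trimws(as.character(x$sex)))
  sex[sex %in% c("m", "boy", "boys", "1")] <- "male"
  sex[sex %in% c("f", "girl", "girls", "2")] <- "female"
  age <- suppressWarnings(as.numeric(x$age))
  height <- suppressWarnings(as.numeric(x$height))

  ok <- rep(TRUE, n)
  bad <- which(!nzchar(id) | is.na(id))
  for (r in bad) note(r, "subject_id", "empty subject id")
  ok[bad] <- FALSE
  bad <- which(!(sex %in% .VALID_SEX))
  for (r in bad) note(r, "sex", "unrecognised sex")
  ok[bad] <- FALSE
  bad <- which(is.na(age) & ok)
  for (r in bad) note(r, "age", "unparseable age")
  ok[bad] <- FALSE
  bad <- which(!is.na(age) & (age < 0 | age >= 25) & ok)
  for (r in bad) note(r, "age", "age outside [0, 25)")
  ok[bad] <- FALSE
  bad <- which(is.na(height) & ok)
  for (r in bad) note(r, "height", "unparseable height")
  ok[bad] <- FALSE
  bad <- which(!is.na(height) & (height <= 50 | height >= 230) & ok)
  for (r in bad) note(r, "height", "height outside (50, 230) cm")
  ok[bad] <- FALSE

  if (n > 0 && !any(ok))
    stop("no valid measurements after validation (", length(issues),
         " issues)")

  d <- data.frame(subject_id = id, sex = sex, age = age, height = height,
                  stringsAsFactors = FALSE)[ok, , drop = FALSE]
  rows <- which(ok)

  # one sex per subject: keep the first-seen sex
  first_sex <- tapply(d$sex, d$subject_id, `[`, 1L)
  conflict <- d$sex != first_sex[d$subject_id]
  for (r in rows[conflict])
    note(r, "sex", "sex conflicts with subject's first-seen sex")
  d <- d[!conflict, , drop = FALSE]
  rows <- rows[!conflict]

  # duplicate (subject, age): keep first occurrence
  dup <- duplicated(d[c("subject_id", "age")])
  for (r in rows[dup]) note(r, "age", "duplicate (subject, age) measurement")
  d <- d[!dup, , drop = FALSE]

  o <- order(d$subject_id, d$age)
  d <- d[o, , drop = FALSE]
  rownames(d) <- NULL

  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(row = integer(), field = character(), issue = character(),
               stringsAsFactors = FALSE)
  if (nrow(issues)) {
    warning(nrow(issues), " row(s) dropped during validation; see ",
            "validation_report()", call. = FALSE)
  }
  structure(d, provenance = provenance, validation = issues,
            class = c("growth_data", "data.frame"))
}

#' Per-row validation report of a dataset
#' @param data a `growth_data` object.
#' @return data frame with columns `row`, `field`, `issue` (one line per
#'   rejected or corrected input row).
#' @export
validation_report <- function(data) {
  stopifnot(inherits(data, "growth_data"))
  attr(data, "validation")
}

#' Read a long-format height table
#'
#' Reads a comma-separated long-format table (header required, UTF-8) and
#' validates it into a [growth_data()] object. `column_map` renames
#' arbitrarily named input columns onto the canonical
#' `subject_id`/`sex`/`age`/`height`.
#'
#' @param path file path.
#' @param column_map named character vector mapping canonical names to the
#'   file's column names, e.g. `c(subject_id = "id", age = "agey")`; unnamed
#'   canonical columns are looked up under their own names.
#' @return a `growth_data` object; row-level problems are collected in its
#'   validation report rather than failing the read (a fully invalid file
#'   does fail).
#' @export
read_growth_table <- function(path, column_map = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", encoding = "UTF-8")
  canon <- c("subject_id", "sex", "age", "height")
  map <- stats::setNames(canon, canon)
  map[names(column_map)] <- column_map
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols))
    stop("column(s) not found in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  d <- stats::setNames(raw[unname(map)], names(map))
  growth_data(d, provenance = paste0("read from ", path))
}

#' Write a long-format height table
#' @param data a `growth_data` object.
#' @param path output file path (comma-separated, header row, UTF-8).
#' @return `path`, invisibly.
#' @export
write_growth_table <- function(data, path) {
  stopifnot(inherits(data, "growth_data"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write the validation report as one machine-readable line per issue
#' @param data a `growth_data` object.
#' @param path output text file path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(data, path) {
  rep <- validation_report(data)
  writeLines(sprintf("row=%d\tfield=%s\tissue=%s",
                     rep$row, rep$field, rep$issue), path)
  invisible(path)
}

#' Age segmentation for the inclusion filter
#'
#' Strictly increasing boundaries defining half-open age intervals
#' `[b_k, b_{k+1})`. The default reproduces the study's five segments over
#' 7-16 years.
#'
#' @param boundaries numeric vector of at least two strictly increasing ages.
#' @return object of class `age_segments`.
#' @export
age_segments <- function(boundaries = c(7, 8.8, 10.6, 12.4, 14.2, 16)) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 2L || is.unsorted(boundaries, strictly = TRUE))
    stop("boundaries must be at least two strictly increasing ages")
  structure(list(boundaries = boundaries), class = "age_segments")
}

#' Keep only subjects observed in every age segment
#'
#' Retains exactly the subjects that have at least one measurement in every
#' half-open interval `[b_k, b_{k+1})` of the segmentation. All measurements
#' of retained subjects are kept, including those outside the segmented
#' span. Idempotent by construction.
#'
#' @param data a `growth_data` object.
#' @param seg an [age_segments()] object.
#' @return filtered `growth_data`.
#' @export
filter_age_segments <- function(data, seg = age_segments()) {
  stopifnot(inherits(data, "growth_data"), inherits(seg, "age_segments"))
  if (nrow(data) == 0L) return(data)
  b <- seg$boundaries
  nseg <- length(b) - 1L
  keep_subject <- vapply(split(data$age, data$subject_id), function(a) {
    idx <- findInterval(a, b, rightmost.closed = FALSE)
    all(seq_len(nseg) %in% idx[idx >= 1L & idx <= nseg])
  }, logical(1))
  out <- data[data$subject_id %in% names(keep_subject)[keep_subject], ,
              drop = FALSE]
  rownames(out) <- NULL
  structure(out, provenance = attr(data, "provenance"),
            validation = attr(data, "validation"),
            class = class(data))
}

#' Summary counts of a longitudinal dataset
#'
#' @param data a `growth_data` object.
#' @return list with `n_subjects`, `n_measurements`, per-sex subject and
#'   measurement counts, and `mean_measurements` (measurements per subject;
#'   `NA` for an empty dataset). The print method reports the mean to one
#'   decimal.
#' @export
summarize_dataset <- function(data) {
  stopifnot(inherits(data, "growth_data"))
  n_subj <- length(unique(data$subject_id))
  per_sex <- function(s) {
    d <- data[data$sex == s, , drop = FALSE]
    c(subjects = length(unique(d$subject_id)), measurements = nrow(d))
  }
  out <- list(
    n_subjects = n_subj,
    n_measurements = nrow(data),
    male = per_sex("male"),
    female = per_sex("female"),
    mean_measurements = if (n_subj > 0) nrow(data) / n_subj else NA_real_)
  class(out) <- "growth_data_summary"
  out
}

#' @export
print.growth_data_summary <- function(x, ...) {
  cat("Longitudinal height dataset\n")
  cat(sprintf("  %d measurements from %d subjects (%d boys, %d girls)\n",
              x$n_measurements, x$n_subjects,
              x$male[["subjects"]], x$female[["subjects"]]))
  if (!is.na(x$mean_measurements))
    cat(sprintf("  %.1f measurements per subject on average\n",
                x$mean_measurements))
  invisible(x)
}

#' @export
print.growth_data <- function(x, ...) {
  s <- summarize_dataset(x)
  print(s)
  if (nrow(attr(x, "validation")))
    cat("  ", nrow(attr(x, "validation")), "validation issue(s) recorded\n")
  invisible(x)
}
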