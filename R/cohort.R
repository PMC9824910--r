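#' Construct a longitudinal cohort object
#'
#' A cohort couples one row per subject of outcome information (observed
#' follow-up time and event indicator) with a long-format table of clinic
#' visits carrying covariate snapshots. All times are numeric offsets from
#' each subject's baseline visit; the first visit of every subject must be
#' at time 0 and visit times must be strictly increasing within subject.
#'
#' @param subjects data.frame with columns `subject_id`, `followup_time`,
#'   `event` (0/1), one row per subject.
#' @param visits data.frame with columns `subject_id`, `visit_time`, plus one
#'   numeric column per covariate.
#' @param covariate_names character vector naming the covariate columns of
#'   `visits`; defaults to every column other than `subject_id`/`visit_time`.
#' @param warn_no_time_covariate if `TRUE` (default), warn when none of the
#'   covariates carries timing information (a column named like "age" or
#'   "time"). A timing variable is usually needed so the model does not lose
#'   the chronology of the longitudinal record; localizing on visit time
#'   also supplies it.
#' @return An object of class `gla_cohort`.
#' @export
cohort <- function(subjects, visits, covariate_names = NULL,
                   warn_no_time_covariate = TRUE) {
  subjects <- as.data.frame(subjects)
  visits <- as.data.frame(visits)
  req_s <- c("subject_id", "followup_time", "event")
  req_v <- c("subject_id", "visit_time")
  miss <- setdiff(req_s, names(subjects))
  if (length(miss)) {
    stop("outcomes table is missing column(s): ", paste(miss, collapse = ", "))
  }
  miss <- setdiff(req_v, names(visits))
  if (length(miss)) {
    stop("visits table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(covariate_names)) {
    covariate_names <- setdiff(names(visits), req_v)
  } else {
    miss <- setdiff(covariate_names, names(visits))
    if (length(miss)) {
      stop("visits table is missing covariate column(s): ",
           paste(miss, collapse = ", "))
    }
  }
  subjects$subject_id <- as.character(subjects$subject_id)
  visits$subject_id <- as.character(visits$subject_id)

  if (anyDuplicated(subjects$subject_id)) {
    dup <- unique(subjects$subject_id[duplicated(subjects$subject_id)])
    stop("duplicated subject_id in outcomes table: ",
         paste(dup, collapse = ", "))
  }
  if (!is.numeric(subjects$followup_time) || any(subjects$followup_time < 0)) {
    stop("followup_time must be numeric and nonnegative")
  }
  if (!all(subjects$event %in% c(0, 1))) {
    stop("event must be 0 or 1")
  }
  if (!is.numeric(visits$visit_time) || any(visits$visit_time < 0)) {
    stop("visit_time must be numeric and nonnegative")
  }
  for (nm in covariate_names) {
    if (!is.numeric(visits[[nm]])) {
      stop("covariate column '", nm, "' is not numeric")
    }
  }

  key <- paste(visits$subject_id, visits$visit_time, sep = "\r")
  if (anyDuplicated(key)) {
    bad <- visits$subject_id[duplicated(key)]
    stop("duplicated (subject_id, visit_time) for subject(s): ",
         paste(unique(bad), collapse = ", "))
  }
  orphan <- setdiff(visits$subject_id, subjects$subject_id)
  if (length(orphan)) {
    stop("visits reference unknown subject(s): ",
         paste(orphan, collapse = ", "))
  }
  novisit <- setdiff(subjects$subject_id, visits$subject_id)
  if (length(novisit)) {
    stop("subject(s) without any visit: ", paste(novisit, collapse = ", "))
  }

  visits <- visits[order(visits$subject_id, visits$visit_time), , drop = FALSE]
  rownames(visits) <- NULL
  first <- !duplicated(visits$subject_id)
  if (any(visits$visit_time[first] != 0)) {
    bad <- visits$subject_id[first][visits$visit_time[first] != 0]
    stop("first visit not at time 0 for subject(s): ",
         paste(unique(bad), collapse = ", "))
  }

  if (warn_no_time_covariate &&
      !any(grepl("age|time", covariate_names, ignore.case = TRUE))) {
    warning("no timing covariate (visit time, baseline age or current age) ",
            "found among covariates; one is usually needed unless the ",
            "landmark variable itself carries the timing", call. = FALSE)
  }

  structure(
    list(subjects = subjects,
         visits = visits[, c(req_v, covariate_names), drop = FALSE],
         covariate_names = covariate_names),
    class = "gla_cohort"
  )
}

#' @export
print.gla_cohort <- function(x, ...) {
  cat("<gla_cohort> ", nrow(x$subjects), " subjects, ",
      nrow(x$visits), " visits, ",
      sum(x$subjects$event), " events\n", sep = "")
  cat("covariates: ", paste(x$covariate_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a longitudinal cohort from delimited text files
#'
#' Expects a long-format visits file (one row per clinic visit) and an
#' outcomes file (one row per subject). The delimiter is auto-detected
#' (comma or tab) unless given. Column names can be remapped through
#' `schema`. Visit rows with missing covariate values are dropped with a
#' diagnostic (no imputation is attempted).
#'
#' @param visits_path path to the visits file.
#' @param outcomes_path path to the outcomes file.
#' @param schema named list remapping the expected roles to file column
#'   names: entries `subject_id`, `visit_time`, `followup_time`, `event`,
#'   and optionally `covariates` (character vector; default: every other
#'   column of the visits file).
#' @param delim field delimiter; `NULL` (default) auto-detects.
#' @param ... passed to [cohort()].
#' @return A `gla_cohort`; the number of visit rows dropped for missing
#'   covariates is available as `attr(, "n_dropped_missing")`.
#' @export
read_cohort <- function(visits_path, outcomes_path, schema = list(),
                        delim = NULL, ...) {
  defaults <- list(subject_id = "subject_id", visit_time = "visit_time",
                   followup_time = "followup_time", event = "event",
                   covariates = NULL)
  schema <- utils::modifyList(defaults, schema)

  dv <- if (is.null(delim)) detect_delim(visits_path) else delim
  do <- if (is.null(delim)) detect_delim(outcomes_path) else delim
  visits <- utils::read.table(visits_path, header = TRUE, sep = dv,
                              stringsAsFactors = FALSE, check.names = FALSE)
  outcomes <- utils::read.table(outcomes_path, header = TRUE, sep = do,
                                stringsAsFactors = FALSE, check.names = FALSE)

  for (role in c("subject_id", "visit_time")) {
    if (!schema[[role]] %in% names(visits)) {
      stop("visits file is missing column '", schema[[role]],
           "' (role: ", role, ")")
    }
  }
  for (role in c("subject_id", "followup_time", "event")) {
    if (!schema[[role]] %in% names(outcomes)) {
      stop("outcomes file is missing column '", schema[[role]],
           "' (role: ", role, ")")
    }
  }

  covs <- schema$covariates
  if (is.null(covs)) {
    covs <- setdiff(names(visits), c(schema$subject_id, schema$visit_time))
  }
  miss <- setdiff(covs, names(visits))
  if (length(miss)) {
    stop("visits file is missing covariate column(s): ",
         paste(miss, collapse = ", "))
  }
  for (nm in c(schema$visit_time, covs)) {
    col <- visits[[nm]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))
      stop("non-numeric value in visits column '", nm, "' at data row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }

  v <- data.frame(subject_id = visits[[schema$subject_id]],
                  visit_time = visits[[schema$visit_time]],
                  check.names = FALSE)
  for (nm in covs) v[[nm]] <- visits[[nm]]

  complete <- stats::complete.cases(v)
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    message(n_dropped, " visit row(s) dropped for missing covariate values")
    v <- v[complete, , drop = FALSE]
  }

  s <- data.frame(subject_id = outcomes[[schema$subject_id]],
                  followup_time = outcomes[[schema$followup_time]],
                  event = outcomes[[schema$event]])

  out <- cohort(s, v, covariate_names = covs, ...)
  attr(out, "n_dropped_missing") <- n_dropped
  out
}

#' Write a cohort back to delimited text files
#'
#' Inverse of [read_cohort()] up to column order.
#'
#' @param x a `gla_cohort`.
#' @param visits_path,outcomes_path output paths.
#' @param delim field delimiter (default comma).
#' @export
write_cohort <- function(x, visits_path, outcomes_path, delim = ",") {
  stopifnot(inherits(x, "gla_cohort"))
  utils::write.table(x$visits, visits_path, sep = delim, row.names = FALSE,
                     quote = FALSE)
  utils::write.table(x$subjects, outcomes_path, sep = delim,
                     row.names = FALSE, quote = FALSE)
  invisible(x)
}

#' Stack a cohort into a landmark dataset
#'
#' Each clinic visit occurring strictly before the subject's observed
#' follow-up time contributes one row, pairing the visit's covariates with
#' the residual survival time (follow-up time minus visit time) and the
#' subject-level event indicator. Visits at or after the follow-up time are
#' excluded and counted in the `n_dropped` attribute.
#'
#' @param x a `gla_cohort`.
#' @return A data.frame of class `landmark_dataset` with columns
#'   `subject_id`, `visit_time`, `residual_time`, `event`, and the cohort's
#'   covariates; attributes `covariate_names` and `n_dropped`.
#' @export
build_landmark_dataset <- function(x) {
  stopifnot(inherits(x, "gla_cohort"))
  idx <- match(x$visits$subject_id, x$subjects$subject_id)
  fu <- x$subjects$followup_time[idx]
  keep <- x$visits$visit_time < fu
  n_dropped <- sum(!keep)
  if (!any(keep)) {
    stop("no eligible visits: every visit is at or after follow-up time")
  }
  lm <- data.frame(
    subject_id = x$visits$subject_id[keep],
    visit_time = x$visits$visit_time[keep],
    residual_time = fu[keep] - x$visits$visit_time[keep],
    event = x$subjects$event[idx][keep]
  )
  for (nm in x$covariate_names) lm[[nm]] <- x$visits[[nm]][keep]
  rownames(lm) <- NULL
  structure(lm,
            covariate_names = x$covariate_names,
            n_dropped = n_dropped,
            class = c("landmark_dataset", "data.frame"))
}

#' Export a landmark dataset as delimited text
#'
#' For interoperability with external survival software: one row per
#' at-risk visit with the residual time and event indicator.
#'
#' @param x a `landmark_dataset`.
#' @param path output path.
#' @param delim field delimiter (default comma).
#' @export
write_landmark_dataset <- function(x, path, delim = ",") {
  stopifnot(inherits(x, "landmark_dataset"))
  utils::write.table(as.data.frame(x), path, sep = delim, row.names = FALSE,
                     quote = FALSE)
  invisible(x)
}

#' Append summaries of a covariate's recent history at each visit
#'
#' Derived features of the longitudinal history, such as the recent mean or
#' slope of a biomarker, can be predictive beyond the current value. For
#' each visit, the requested statistic is computed over that subject's
#' observations of the covariate in the window `[visit_time - window,
#' visit_time]` (inclusive). Visits with fewer than 2 in-window observations
#' get slope 0 and mean equal to the current value.
#'
#' @param x a `gla_cohort`.
#' @param feature_specs list of specs, each a list with elements `covariate`
#'   (name), `window` (positive window length), `statistic` (`"mean"` or
#'   `"slope"`). The new column is named `<covariate>_<statistic><window>`.
#' @return The cohort with the new covariate columns appended.
#' @export
add_history_features <- function(x, feature_specs) {
  stopifnot(inherits(x, "gla_cohort"))
  if (!is.list(feature_specs[[1]])) feature_specs <- list(feature_specs)
  v <- x$visits
  new_names <- character(0)
  for (spec in feature_specs) {
    nm <- spec$covariate
    if (!nm %in% x$covariate_names) {
      stop("unknown covariate '", nm, "'")
    }
    stopifnot(spec$window > 0, spec$statistic %in% c("mean", "slope"))
    out_nm <- paste0(nm, "_", spec$statistic, spec$window)
    vals <- numeric(nrow(v))
    for (id in unique(v$subject_id)) {
      rows <- which(v$subject_id == id)
      tt <- v$visit_time[rows]
      zz <- v[[nm]][rows]
      for (k in seq_along(rows)) {
        in_win <- tt >= tt[k] - spec$window & tt <= tt[k]
        if (spec$statistic == "mean") {
          vals[rows[k]] <- if (sum(in_win) < 2) zz[k] else mean(zz[in_win])
        } else {
          vals[rows[k]] <- if (sum(in_win) < 2) 0 else
            stats::coef(stats::lm(zz[in_win] ~ tt[in_win]))[2]
        }
      }
    }
    v[[out_nm]] <- vals
    new_names <- c(new_names, out_nm)
  }
  x$visits <- v
  x$covariate_names <- c(x$covariate_names, new_names)
  x
}

#' Restrict a cohort to a subset of subjects
#'
#' @param x a `gla_cohort`.
#' @param subject_ids character vector of subject ids to keep.
#' @return The restricted `gla_cohort`.
#' @export
subset_cohort <- function(x, subject_ids) {
  stopifnot(inherits(x, "gla_cohort"))
  subject_ids <- as.character(subject_ids)
  cohort(x$subjects[x$subjects$subject_id %in% subject_ids, , drop = FALSE],
         x$visits[x$visits$subject_id %in% subject_ids, , drop = FALSE],
         covariate_names = x$covariate_names,
         warn_no_time_covariate = FALSE)
}
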