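#' Construct a single subject's data
#'
#' One subject consists of a longitudinal biomarker record (strictly
#' increasing measurement times in months and the measured values in ng/ml),
#' a censoring interval for the event, and fixed baseline covariates.  For
#' an interval-censored subject the event is known to lie in `(t_L, t_R]`;
#' for a right-censored subject `t_R` is the last negative screening time
#' and `t_L` is unused (`NA`).
#'
#' @param id subject identifier (scalar).
#' @param times numeric vector of measurement times, months since baseline.
#' @param values numeric vector of biomarker values (ng/ml).
#' @param t_L left censoring bound in months (`NA` if right-censored).
#' @param t_R right bound in months (detection time, or last negative screen
#'   when right-censored).
#' @param right_censored logical flag.
#' @param covariates named numeric vector of baseline covariates.
#' @return An object of class `icjm_subject`.
#' @export
subject_data <- function(id, times, values, t_L, t_R, right_censored,
                         covariates = numeric(0)) {
  s <- structure(list(id = id, times = as.numeric(times),
                      values = as.numeric(values),
                      t_L = as.numeric(t_L), t_R = as.numeric(t_R),
                      right_censored = isTRUE(right_censored),
                      covariates = covariates),
                 class = "icjm_subject")
  validate_subject(s)
  s
}

validate_subject <- function(s) {
  where <- sprintf("subject '%s'", s$id)
  if (length(s$times) < 1L)
    stop(where, ": at least one longitudinal record is required")
  if (length(s$times) != length(s$values))
    stop(where, ": times and values differ in length")
  if (any(!is.finite(s$values)))
    stop(where, ": non-finite biomarker value")
  if (any(s$times < 0))
    stop(where, ": negative measurement time")
  if (any(diff(s$times) <= 0))
    stop(where, ": measurement times must be strictly increasing")
  if (!is.finite(s$t_R) || s$t_R <= 0)
    stop(where, ": t_R must be a positive time")
  if (!s$right_censored) {
    if (!is.finite(s$t_L) || s$t_L < 0)
      stop(where, ": t_L must be a nonnegative time for interval censoring")
    if (s$t_L >= s$t_R)
      stop(where, ": invalid censoring interval (t_L >= t_R)")
  }
  if (any(s$times > s$t_R))
    stop(where, ": longitudinal times exceed the censoring bound t_R")
  if (length(s$covariates) && any(!is.finite(s$covariates)))
    stop(where, ": non-finite covariate")
  invisible(s)
}

#' Assemble subjects into a dataset
#'
#' @param subjects list of [subject_data()] objects.
#' @return An object of class `icjm_data` (a list of subjects).
#' @export
icjm_data <- function(subjects) {
  stopifnot(is.list(subjects))
  for (s in subjects) {
    if (!inherits(s, "icjm_subject")) stop("all elements must be icjm_subject")
  }
  ids <- vapply(subjects, function(s) as.character(s$id), character(1))
  if (anyDuplicated(ids)) stop("duplicated subject ids")
  structure(subjects, class = c("icjm_data", "list"))
}

#' @export
print.icjm_data <- function(x, ...) {
  nev <- sum(!vapply(x, `[[`, logical(1), "right_censored"))
  nm <- sum(vapply(x, function(s) length(s$times), integer(1)))
  cat(sprintf("<icjm_data> %d subjects, %d events, %d measurements\n",
              length(x), nev, nm))
  invisible(x)
}

covariate_names <- function(data) {
  if (!length(data)) return(character(0))
  names(data[[1]]$covariates)
}

#' Read a dataset from the paired CSV layout
#'
#' The longitudinal file has columns `id`, `time`, `value`; the survival
#' file has columns `id`, `t_L`, `t_R`, `right_censored` plus one column per
#' baseline covariate.  `t_L` is empty for right-censored subjects.  Times
#' are numeric months.
#'
#' @param longitudinal_path,survival_path paths to the two CSV files.
#' @return An `icjm_data` object with one subject per survival row,
#'   longitudinal records sorted by time.
#' @export
read_dataset <- function(longitudinal_path, survival_path) {
  if (!file.exists(longitudinal_path)) stop("file not found: ", longitudinal_path)
  if (!file.exists(survival_path)) stop("file not found: ", survival_path)
  long <- read.csv(longitudinal_path, stringsAsFactors = FALSE)
  surv <- read.csv(survival_path, stringsAsFactors = FALSE)
  need_long <- c("id", "time", "value")
  need_surv <- c("id", "t_L", "t_R", "right_censored")
  if (!all(need_long %in% names(long)))
    stop("format error: longitudinal file must have columns ",
         paste(need_long, collapse = ", "))
  if (!all(need_surv %in% names(surv)))
    stop("format error: survival file must have columns ",
         paste(need_surv, collapse = ", "))
  cov_cols <- setdiff(names(surv), need_surv)
  surv$t_L <- suppressWarnings(as.numeric(surv$t_L))
  surv$t_R <- suppressWarnings(as.numeric(surv$t_R))
  only_long <- setdiff(unique(long$id), surv$id)
  only_surv <- setdiff(surv$id, unique(long$id))
  if (length(only_long) || length(only_surv))
    stop("consistency error: subjects present in one file only: ",
         paste(c(only_long, only_surv), collapse = ", "))
  subjects <- lapply(seq_len(nrow(surv)), function(i) {
    row <- surv[i, ]
    li <- long[long$id == row$id, , drop = FALSE]
    li <- li[order(li$time), , drop = FALSE]
    covs <- as.numeric(row[cov_cols])
    names(covs) <- cov_cols
    subject_data(id = row$id, times = li$time, values = li$value,
                 t_L = row$t_L, t_R = row$t_R,
                 right_censored = as.logical(row$right_censored),
                 covariates = covs)
  })
  icjm_data(subjects)
}

#' Write a dataset to the paired CSV layout
#'
#' Inverse of [read_dataset()]; numeric values are written with 15
#' significant digits so that a write/read round trip preserves the data.
#' An empty dataset produces two header-only files.
#'
#' @param data an `icjm_data` object.
#' @param longitudinal_path,survival_path output paths.
#' @return invisibly, `data`.
#' @export
write_dataset <- function(data, longitudinal_path, survival_path) {
  stopifnot(inherits(data, "icjm_data"))
  fmt <- function(x) formatC(x, digits = 15, format = "g")
  cn <- covariate_names(data)
  long_rows <- lapply(data, function(s)
    data.frame(id = s$id, time = fmt(s$times), value = fmt(s$values),
               stringsAsFactors = FALSE))
  surv_rows <- lapply(data, function(s) {
    row <- data.frame(id = s$id,
                      t_L = if (s$right_censored) "" else fmt(s$t_L),
                      t_R = fmt(s$t_R),
                      right_censored = s$right_censored,
                      stringsAsFactors = FALSE)
    for (nm in cn) row[[nm]] <- fmt(s$covariates[[nm]])
    row
  })
  empty_long <- data.frame(id = character(0), time = character(0),
                           value = character(0))
  empty_surv <- data.frame(id = character(0), t_L = character(0),
                           t_R = character(0), right_censored = logical(0))
  long_df <- if (length(long_rows)) do.call(rbind, long_rows) else empty_long
  surv_df <- if (length(surv_rows)) do.call(rbind, surv_rows) else empty_surv
  write.csv(long_df, longitudinal_path, row.names = FALSE, quote = FALSE)
  write.csv(surv_df, survival_path, row.names = FALSE, quote = FALSE)
  invisible(data)
}

#' Longitudinal records as a long-format data frame
#'
#' @param x an `icjm_data` object.
#' @param ... unused.
#' @return data frame with columns `id`, `time`, `value`.
#' @export
as.data.frame.icjm_data <- function(x, ...) {
  do.call(rbind, lapply(x, function(s)
    data.frame(id = s$id, time = s$times, value = s$values,
               stringsAsFactors = FALSE)))
}
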