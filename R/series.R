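#' A subject's binned activity-count series
#'
#' One subject's activity counts on the within-day bin grid, possibly over
#' several days. Counts must be non-negative integers; each (day, bin) pair
#' may appear at most once. Day replicates share the same within-day time
#' `t = bin / bins_per_day` — the model has no day effect, so all a
#' subject's observations inform one 24-hour curve.
#'
#' @param subject_id subject identifier (coerced to character).
#' @param day integer day indices (>= 1), one per observation.
#' @param bin integer within-day bin indices in `[1, bins_per_day]`.
#' @param count non-negative integer activity counts.
#' @param bins_per_day number of bins per day (default 96).
#' @param group optional binary group label (0/1).
#' @param covariates optional named list of subject-level covariates.
#' @return An object of class `activity_series`: a list with `subject_id`,
#'   a data frame `data` (columns `day`, `bin`, `t`, `count`),
#'   `bins_per_day`, `group`, `covariates`.
#' @export
activity_series <- function(subject_id, day, bin, count, bins_per_day = 96,
                            group = NULL, covariates = NULL) {
  subject_id <- as.character(subject_id)[1]
  n <- length(count)
  if (length(day) != n || length(bin) != n)
    stop("'day', 'bin' and 'count' must have equal length")
  if (n == 0) stop("empty series for subject ", subject_id)
  day <- as.integer(day); bin <- as.integer(bin)
  if (any(is.na(day)) || any(day < 1))
    stop("subject ", subject_id, ": day indices must be integers >= 1")
  if (any(is.na(bin)) || any(bin < 1) || any(bin > bins_per_day))
    stop("subject ", subject_id, ": bin indices must be in [1, ",
         bins_per_day, "]")
  if (!is.numeric(count) || any(!is.finite(count)) ||
      any(count < 0) || any(count != round(count)))
    stop("subject ", subject_id,
         ": counts must be non-negative integers")
  if (anyDuplicated(paste(day, bin)))
    stop("subject ", subject_id, ": duplicate (day, bin) pairs")
  structure(list(
    subject_id = subject_id,
    data = data.frame(day = day, bin = bin,
                      t = bin / bins_per_day,
                      count = as.integer(round(count))),
    bins_per_day = as.integer(bins_per_day),
    group = group,
    covariates = covariates
  ), class = "activity_series")
}

#' @export
print.activity_series <- function(x, ...) {
  cat(sprintf("Activity series '%s': %d observations over %d day(s), %d bins/day\n",
              x$subject_id, nrow(x$data), length(unique(x$data$day)),
              x$bins_per_day))
  if (!is.null(x$group)) cat("  group:", x$group, "\n")
  invisible(x)
}

#' Per-bin daily activity profile
#'
#' Averages a subject's counts within each within-day bin across days — the
#' standard display of an actigraphy record as one mean 24-hour profile
#' (fitting itself uses the raw observations, not these averages).
#'
#' @param series an [activity_series()].
#' @return data frame with columns `bin`, `t`, `mean_count`, `n_days`.
#' @export
daily_profile <- function(series) {
  stopifnot(inherits(series, "activity_series"))
  d <- series$data
  agg <- stats::aggregate(d$count, by = list(bin = d$bin),
                          FUN = function(z) c(mean(z), length(z)))
  data.frame(bin = agg$bin,
             t = agg$bin / series$bins_per_day,
             mean_count = agg$x[, 1],
             n_days = as.integer(agg$x[, 2]))
}

# internal: check a cohort is a non-empty list of activity_series
check_cohort <- function(cohort) {
  if (inherits(cohort, "activity_series")) cohort <- list(cohort)
  if (!is.list(cohort) || length(cohort) == 0 ||
      !all(vapply(cohort, inherits, logical(1), "activity_series")))
    stop("expected a list of 'activity_series' objects")
  cohort
}
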