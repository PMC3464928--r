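#' Aggregate raw device epochs into within-day bins
#'
#' Sums raw epoch counts (e.g. 30-second Actiwatch-style epochs) into
#' analysis bins (default 15 minutes, i.e. 96 bins/day), the resolution the
#' model is fitted at. An epoch belongs to the bin containing its start
#' time. Bins observed with fewer than `completeness` of their expected
#' epochs are treated as missing and omitted from the output (never filled
#' with zero).
#'
#' @param time epoch start times: numeric seconds from midnight of day 1,
#'   or `POSIXct` (converted relative to midnight of the first day).
#'   Strictly increasing.
#' @param count non-negative integer epoch counts.
#' @param epoch_seconds epoch length in seconds (default 30); must divide
#'   `bin_minutes * 60`.
#' @param bin_minutes bin width in minutes (default 15); must divide 1440.
#' @param completeness minimum fraction of a bin's epochs that must be
#'   present (default 1, full bins only).
#' @return Data frame with columns `day`, `bin`, `t`, `count`, suitable for
#'   [activity_series()].
#' @export
aggregate_epochs <- function(time, count, epoch_seconds = 30,
                             bin_minutes = 15, completeness = 1) {
  if (inherits(time, "POSIXct")) {
    day0 <- trunc(time[1], units = "days")
    time <- as.numeric(difftime(time, day0, units = "secs"))
  }
  time <- as.numeric(time)
  if (length(time) != length(count)) stop("'time' and 'count' lengths differ")
  if (length(time) == 0) stop("empty epoch series")
  if (any(diff(time) <= 0)) stop("epoch timestamps must be strictly increasing")
  if (any(!is.finite(count)) || any(count < 0))
    stop("epoch counts must be non-negative")
  if ((bin_minutes * 60) %% epoch_seconds != 0)
    stop("epoch_seconds must divide bin_minutes * 60")
  if (1440 %% bin_minutes != 0) stop("bin_minutes must divide the 1440-minute day")
  bins_per_day <- as.integer(1440 / bin_minutes)
  per_bin <- as.integer(bin_minutes * 60 / epoch_seconds)
  completeness <- max(min(completeness, 1), 0)

  day <- floor(time / 86400) + 1L
  secs <- time %% 86400
  bin <- floor(secs / (bin_minutes * 60)) + 1L
  key <- (day - 1L) * bins_per_day + bin
  sums <- tapply(count, key, sum)
  nper <- tapply(count, key, length)
  keep <- nper >= completeness * per_bin
  keys <- as.integer(names(sums))[keep]
  out <- data.frame(
    day = (keys - 1L) %/% bins_per_day + 1L,
    bin = (keys - 1L) %% bins_per_day + 1L,
    count = as.integer(round(sums[keep]))
  )
  out$t <- out$bin / bins_per_day
  out <- out[order(out$day, out$bin), c("day", "bin", "t", "count")]
  rownames(out) <- NULL
  out
}

#' Read a cohort from a long-format delimited file
#'
#' Reads the canonical long-format table (one row per subject-day-bin
#' count) and validates it into a list of [activity_series()]. Malformed
#' rows are reported with their file line numbers (header = line 1). An
#' optional covariate table keyed by subject id attaches a binary `group`
#' label and any further covariates to each series.
#'
#' @param path path to the delimited count file.
#' @param schema named character vector mapping the roles `subject`, `day`,
#'   `bin`, `count` to column names in the file.
#' @param covariates_path optional path to a covariate file with a column
#'   named by `schema["subject"]` (or `subject`) plus `group` and others.
#' @param sep field separator (default comma).
#' @param bins_per_day bins per day used for validation and the time map
#'   (default 96).
#' @return List of [activity_series()], ordered by subject id.
#' @export
read_cohort <- function(path,
                        schema = c(subject = "subject", day = "day",
                                   bin = "bin", count = "count"),
                        covariates_path = NULL, sep = ",",
                        bins_per_day = 96) {
  if (!file.exists(path)) stop("file not found: ", path)
  need <- c("subject", "day", "bin", "count")
  if (!all(need %in% names(schema)))
    stop("schema must map ", paste(need, collapse = ", "))
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(schema[need]), names(df))
  if (length(missing_cols) > 0)
    stop("missing columns in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  sub <- as.character(df[[schema[["subject"]]]])
  day <- suppressWarnings(as.numeric(df[[schema[["day"]]]]))
  bin <- suppressWarnings(as.numeric(df[[schema[["bin"]]]]))
  cnt <- suppressWarnings(as.numeric(df[[schema[["count"]]]]))

  bad <- !is.finite(cnt) | cnt < 0 | cnt != round(cnt)
  if (any(bad))
    stop("invalid counts (must be non-negative integers) at line ",
         paste(line[bad][seq_len(min(5, sum(bad)))], collapse = ", line "))
  bad <- !is.finite(day) | day < 1 | day != round(day)
  if (any(bad))
    stop("invalid day indices at line ",
         paste(line[bad][seq_len(min(5, sum(bad)))], collapse = ", line "))
  bad <- !is.finite(bin) | bin < 1 | bin > bins_per_day | bin != round(bin)
  if (any(bad))
    stop("invalid bin indices at line ",
         paste(line[bad][seq_len(min(5, sum(bad)))], collapse = ", line "))
  key <- paste(sub, day, bin)
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))
    stop("duplicate (subject, day, bin) at line ",
         paste(line[d][seq_len(min(5, length(d)))], collapse = ", line "))
  }

  covs <- NULL
  if (!is.null(covariates_path)) {
    if (!file.exists(covariates_path))
      stop("file not found: ", covariates_path)
    covs <- utils::read.table(covariates_path, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE)
    subcol <- if (schema[["subject"]] %in% names(covs))
      schema[["subject"]] else "subject"
    if (!subcol %in% names(covs))
      stop("covariate file needs a subject id column")
    covs$.__subject <- as.character(covs[[subcol]])
  }

  ids <- sort(unique(sub))
  lapply(ids, function(id) {
    sel <- sub == id
    group <- NULL; cv <- NULL
    if (!is.null(covs)) {
      row <- covs[covs$.__subject == id, , drop = FALSE]
      if (nrow(row) == 1) {
        if ("group" %in% names(row)) group <- row$group[[1]]
        keep <- setdiff(names(row), c(".__subject", subcol, "group"))
        if (length(keep) > 0) cv <- as.list(row[1, keep, drop = FALSE])
      }
    }
    activity_series(id, day[sel], bin[sel], cnt[sel],
                    bins_per_day = bins_per_day, group = group,
                    covariates = cv)
  })
}

#' Write a cohort to a long-format delimited file
#'
#' Inverse of [read_cohort()]: writes one row per observation with columns
#' `subject`, `day`, `bin`, `count`. Reading the file back yields an
#' identical in-memory cohort.
#'
#' @param cohort list of [activity_series()] or a `simulated_cohort`.
#' @param path output file path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  if (inherits(cohort, "simulated_cohort")) cohort <- cohort$series
  cohort <- check_cohort(cohort)
  rows <- do.call(rbind, lapply(cohort, function(s)
    data.frame(subject = s$subject_id, day = s$data$day, bin = s$data$bin,
               count = s$data$count, stringsAsFactors = FALSE)))
  utils::write.table(rows, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a stage-1 parameter table
#'
#' @param fit a `circshape_fit`.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path, sep = ",") {
  stopifnot(inherits(fit, "circshape_fit"))
  utils::write.table(fit$subjects, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
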