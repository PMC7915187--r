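# On-disk contract of the pipeline: three small CSV tables in, one result
# table out.  All tables are plain text; dates are ISO-8601 calendar dates.
#
#   polls:     date,n1,n2,n3,n4   (counts)  or  date,p1,p2,p3,p4 (proportions)
#   registry:  hospital_id,annual_ga_count
#   reference: date,percent
#   estimates: date,median,ci_low,ci_high,percent_of_baseline

#' Construct a validated poll series
#'
#' A poll series is a dated sequence of response distributions over the four
#' ordered restriction states (1 = no restrictions ... 4 = no scheduled
#' surgery).  The series carries a pre-survey baseline distribution,
#' `c(1, 0, 0, 0)` by default: before the disruption every hospital is
#' assumed unrestricted.
#'
#' @param dates `Date` vector, strictly increasing.
#' @param proportions numeric matrix, one row per date, 4 columns; each row
#'   must sum to 1 within `tol` and is re-normalized to sum exactly 1.
#' @param counts optional integer matrix of response counts; when given,
#'   proportions are computed as `counts / rowSums(counts)`.
#' @param baseline length-4 probability vector for the pre-survey state
#'   distribution.
#' @param tol allowed deviation of each row sum from 1 before
#'   re-normalization; `1e-6` for exact data, `0.015` when parsing
#'   percentages rounded to one decimal.
#' @return a `poll_series`: a data.frame with columns `date`, `p1`..`p4`
#'   (and `n1`..`n4` if counts were supplied), with the baseline stored as an
#'   attribute.
#' @export
poll_series <- function(dates, proportions = NULL, counts = NULL,
                        baseline = c(1, 0, 0, 0), tol = 1e-6) {
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("unparseable date in poll series")
  if (length(dates) >= 2 && any(diff(dates) <= 0)) {
    stop("poll dates must be strictly increasing")
  }
  if (is.null(proportions) && is.null(counts)) {
    stop("supply proportions or counts")
  }
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    if (any(counts < 0)) stop("negative response count")
    if (any(counts != round(counts))) stop("non-integer response count")
    totals <- rowSums(counts)
    if (any(totals == 0)) stop("poll with zero total responses")
    proportions <- counts / totals
  }
  proportions <- as.matrix(proportions)
  if (ncol(proportions) != N_STATES || nrow(proportions) != length(dates)) {
    stop("proportions must have one row per date and 4 columns")
  }
  if (any(proportions < 0)) stop("negative proportion")
  sums <- rowSums(proportions)
  bad <- which(abs(sums - 1) > tol)
  if (length(bad) > 0) {
    stop(sprintf("proportions in row %d sum to %.4f, outside 1 +/- %g",
                 bad[1], sums[bad[1]], tol))
  }
  proportions <- proportions / sums
  stopifnot(length(baseline) == N_STATES, abs(sum(baseline) - 1) < 1e-9,
            all(baseline >= 0))

  out <- data.frame(date = dates)
  out[paste0("p", 1:4)] <- proportions
  if (!is.null(counts)) out[paste0("n", 1:4)] <- counts
  attr(out, "baseline") <- baseline / sum(baseline)
  class(out) <- c("poll_series", "data.frame")
  out
}

#' Proportion matrix of a poll series
#' @param polls a `poll_series`.
#' @return numeric matrix, one row per poll date.
#' @export
poll_proportions <- function(polls) {
  as.matrix(polls[paste0("p", 1:4)])
}

#' Read a poll series from CSV
#'
#' Accepts either response counts (`date,n1,n2,n3,n4`) or proportions
#' (`date,p1,p2,p3,p4`).  Proportions parsed from rounded percentages are
#' accepted when each row sums to 1 within 0.015 and are re-normalized.
#'
#' @param path CSV file path.
#' @param dialect `"auto"` detects from the header; `"counts"` /
#'   `"proportions"` force an interpretation.
#' @param baseline pre-survey state distribution, default `c(1, 0, 0, 0)`.
#' @return a [poll_series()].
#' @export
read_poll_series <- function(path, dialect = c("auto", "counts", "proportions"),
                             baseline = c(1, 0, 0, 0)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("poll file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty poll file: ", path)
  has_counts <- all(paste0("n", 1:4) %in% names(df))
  has_props <- all(paste0("p", 1:4) %in% names(df))
  if (dialect == "auto") {
    dialect <- if (has_counts) "counts" else if (has_props) "proportions" else
      stop("poll file needs columns n1..n4 or p1..p4 plus date")
  }
  if (!"date" %in% names(df)) stop("poll file needs a date column")
  if (dialect == "counts") {
    if (!has_counts) stop("dialect 'counts' needs columns n1..n4")
    poll_series(df$date, counts = df[paste0("n", 1:4)], baseline = baseline)
  } else {
    if (!has_props) stop("dialect 'proportions' needs columns p1..p4")
    poll_series(df$date, proportions = df[paste0("p", 1:4)],
                baseline = baseline, tol = 0.015)
  }
}

#' Construct a hospital registry
#'
#' @param hospital_id character vector of unique identifiers.
#' @param annual_count annual general-anesthesia caseload per hospital
#'   (the reference number N_h); non-negative.
#' @return a `hospital_registry` data.frame with a derived `weekly_reference`
#'   column (`annual_count / 52`).
#' @export
hospital_registry <- function(hospital_id, annual_count) {
  hospital_id <- as.character(hospital_id)
  if (anyDuplicated(hospital_id)) stop("duplicate hospital_id")
  annual_count <- as.numeric(annual_count)
  if (anyNA(annual_count)) {
    stop("unparseable annual count at row ", which(is.na(annual_count))[1])
  }
  if (any(annual_count < 0)) stop("negative annual count")
  out <- data.frame(hospital_id = hospital_id,
                    annual_count = annual_count,
                    weekly_reference = annual_count / 52,
                    stringsAsFactors = FALSE)
  class(out) <- c("hospital_registry", "data.frame")
  out
}

#' Read and filter the hospital registry
#'
#' Reads `hospital_id,annual_ga_count` and keeps hospitals whose annual
#' general-anesthesia caseload is at least `min_annual` (default 100, the
#' eligibility rule used to drop facilities too small to contribute a stable
#' weekly reference).
#'
#' @param path CSV file path.
#' @param min_annual inclusive eligibility threshold on annual cases.
#' @return a [hospital_registry()].
#' @export
read_hospital_registry <- function(path, min_annual = 100) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character"))
  if (nrow(df) == 0) stop("empty registry file: ", path)
  if (!all(c("hospital_id", "annual_ga_count") %in% names(df))) {
    stop("registry file needs columns hospital_id,annual_ga_count")
  }
  counts <- suppressWarnings(as.numeric(df$annual_ga_count))
  if (anyNA(counts)) {
    stop("unparseable annual count at row ", which(is.na(counts))[1])
  }
  keep <- counts >= min_annual
  if (!any(keep)) stop("no hospitals left after min_annual filtering")
  hospital_registry(df$hospital_id[keep], counts[keep])
}

#' Construct a reference series
#'
#' An external weekly percent-of-previous-year volume series used for
#' validation of the simulated estimates.
#'
#' @param dates `Date` vector, strictly increasing.
#' @param percent non-negative values in percent units.
#' @return a `reference_series` data.frame.
#' @export
reference_series <- function(dates, percent) {
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("unparseable date in reference series")
  if (length(dates) >= 2 && any(diff(dates) <= 0)) {
    stop("reference dates must be strictly increasing")
  }
  percent <- as.numeric(percent)
  if (any(percent < 0) || anyNA(percent)) stop("percent must be >= 0")
  out <- data.frame(date = dates, percent = percent)
  class(out) <- c("reference_series", "data.frame")
  out
}

#' Read a reference series from CSV (`date,percent`)
#' @param path CSV file path.
#' @return a [reference_series()].
#' @export
read_reference_series <- function(path) {
  if (!file.exists(path)) stop("reference file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty reference file: ", path)
  reference_series(df$date, df$percent)
}

#' Write a volume estimate series to CSV
#'
#' One row per poll date: `date,median,ci_low,ci_high,percent_of_baseline`.
#' Values round-trip through [read_estimates()] to within 1e-9.
#'
#' @param series a `volume_estimate_series` (see [summarize_volumes()]).
#' @param path output CSV path.
#' @export
write_estimates <- function(series, path) {
  if (is.null(series) || nrow(series) == 0) stop("empty estimate series")
  df <- data.frame(date = format(series$date, "%Y-%m-%d"),
                   median = format(series$median, digits = 17),
                   ci_low = format(series$ci_low, digits = 17),
                   ci_high = format(series$ci_high, digits = 17),
                   percent_of_baseline = format(series$percent_of_baseline,
                                                digits = 17))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a volume estimate series written by [write_estimates()]
#' @param path CSV file path.
#' @return a `volume_estimate_series` data.frame.
#' @export
read_estimates <- function(path) {
  if (!file.exists(path)) stop("estimates file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "median", "ci_low", "ci_high", "percent_of_baseline")
  if (!all(need %in% names(df))) {
    stop("estimates file needs columns ", paste(need, collapse = ","))
  }
  df$date <- as.Date(df$date)
  class(df) <- c("volume_estimate_series", "data.frame")
  df
}
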