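# Cohort descriptive statistics for a tinnitus patient table.

#' Load the bundled chronic-tinnitus patient table
#'
#' Thirteen chronic tinnitus patients with sex, age, affected ear, tinnitus
#' duration, matched tinnitus frequency, THI and TQ severity scores and
#' in-scanner loudness rating.  Durations reported as a lower bound
#' (">x" years) are coerced to x and flagged.
#'
#' @param path TSV path; defaults to the table shipped with the package.
#' @return data.frame with one row per patient and a logical column
#'   \code{duration_lower_bound}.
#' @export
tinnitus_cohort <- function(path = system.file("extdata", "tinnitus_cohort.tsv",
                                               package = "rsnica")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(duration_years = "character"))
  lb <- startsWith(df$duration_years, ">")
  df$duration_lower_bound <- lb
  df$duration_years <- as.numeric(sub("^>", "", df$duration_years))
  .assert(all(df$thi >= 0 & df$thi <= 100), "THI scores must lie in [0,100]")
  .assert(all(df$tq >= 0), "TQ scores must be non-negative")
  .assert(all(df$frequency_hz > 0), "tinnitus frequencies must be positive")
  df
}

#' Summarize a patient cohort
#'
#' Means and sample SDs (n-1 denominator) of age, tinnitus duration and
#' matched frequency, plus (min, max) ranges of frequency, THI and TQ.
#' Lower-bound durations enter at their bound.  The \code{as_printed} element
#' rounds means to integers and truncates SDs, the convention of typical
#' clinical reporting.
#'
#' @param records data.frame as returned by \code{\link{tinnitus_cohort}}
#'   (\eqn{\ge} 2 rows).
#' @return object of class \code{cohort_summary}.
#' @export
summarize_cohort <- function(records) {
  .assert(is.data.frame(records) && nrow(records) >= 2,
          "need at least 2 patient records")
  s <- list(
    n = nrow(records),
    mean_age = mean(records$age_years), sd_age = stats::sd(records$age_years),
    mean_duration = mean(records$duration_years),
    sd_duration = stats::sd(records$duration_years),
    mean_freq = mean(records$frequency_hz), sd_freq = stats::sd(records$frequency_hz),
    freq_range = range(records$frequency_hz),
    thi_range = range(records$thi),
    tq_range = range(records$tq)
  )
  s$as_printed <- list(
    mean_age = round(s$mean_age), sd_age = round(s$sd_age),
    mean_duration = round(s$mean_duration), sd_duration = round(s$sd_duration),
    mean_freq = round(s$mean_freq), sd_freq = trunc(s$sd_freq)
  )
  structure(s, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  p <- x$as_printed
  cat(sprintf("<cohort_summary> n = %d\n", x$n))
  cat(sprintf("  age:       mean %d yrs (SD %d)\n", p$mean_age, p$sd_age))
  cat(sprintf("  duration:  mean %d yrs (SD %d)\n", p$mean_duration, p$sd_duration))
  cat(sprintf("  frequency: %g-%g Hz (mean %d, SD %d)\n",
              x$freq_range[1], x$freq_range[2], p$mean_freq, p$sd_freq))
  cat(sprintf("  THI range: %g-%g;  TQ range: %g-%g\n",
              x$thi_range[1], x$thi_range[2], x$tq_range[1], x$tq_range[2]))
  invisible(x)
}

#' Write a cohort summary as JSON
#'
#' @param summary a \code{\link{summarize_cohort}} result.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_cohort_summary_json <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
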