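#' Piecewise-constant intravenous infusion schedule
#'
#' An infusion schedule is an ordered set of half-open segments
#' `[start_h, end_h)` each delivering a constant rate (mg/h) into the central
#' compartment. Boluses are represented as short high-rate segments, never as
#' impulses: a 4,000 mg bolus given over 20 min is a 12,000 mg/h segment of
#' length 1/3 h.
#'
#' @param start_h,end_h,rate_mg_per_h numeric vectors of equal length giving
#'   segment boundaries (h) and rates (mg/h). Segments must be sorted by start,
#'   non-overlapping, with non-negative rates.
#' @return An object of class `infusion_schedule`: a data frame with columns
#'   `start_h`, `end_h`, `rate_mg_per_h`.
#' @examples
#' sched <- infusion_schedule(c(0, 2), c(1, 5), c(12000, 300))
#' schedule_total_dose(sched)
#' @export
infusion_schedule <- function(start_h = numeric(), end_h = numeric(),
                              rate_mg_per_h = numeric()) {
  stopifnot(length(start_h) == length(end_h),
            length(start_h) == length(rate_mg_per_h))
  s <- data.frame(start_h = as.numeric(start_h),
                  end_h = as.numeric(end_h),
                  rate_mg_per_h = as.numeric(rate_mg_per_h))
  s <- s[order(s$start_h), , drop = FALSE]
  rownames(s) <- NULL
  class(s) <- c("infusion_schedule", "data.frame")
  validate_schedule(s)
  s
}

validate_schedule <- function(s) {
  if (nrow(s) == 0L) return(invisible(s))
  if (any(!is.finite(as.matrix(s[c("start_h", "end_h", "rate_mg_per_h")]))))
    stop("infusion schedule contains non-finite values")
  if (any(s$end_h <= s$start_h))
    stop("infusion schedule segments must have end_h > start_h")
  if (any(s$rate_mg_per_h < 0))
    stop("infusion rates must be non-negative")
  if (nrow(s) > 1L && any(s$start_h[-1L] < s$end_h[-nrow(s)] - 1e-12))
    stop("infusion schedule segments overlap")
  invisible(s)
}

#' Total drug mass delivered by a schedule
#'
#' @param schedule an [infusion_schedule()].
#' @param up_to_h optional truncation time (h); only delivery before this time
#'   is counted.
#' @return Delivered mass (mg).
#' @export
schedule_total_dose <- function(schedule, up_to_h = Inf) {
  if (nrow(schedule) == 0L) return(0)
  dur <- pmax(0, pmin(schedule$end_h, up_to_h) - pmin(schedule$start_h, up_to_h))
  sum(dur * schedule$rate_mg_per_h)
}

#' Infusion rate at given times
#'
#' Evaluates the piecewise-constant rate under the half-open `[start, end)`
#' convention; times outside every segment yield 0.
#'
#' @param schedule an [infusion_schedule()].
#' @param t_h numeric vector of times (h).
#' @return Rates (mg/h), one per element of `t_h`.
#' @export
schedule_rate_at <- function(schedule, t_h) {
  r <- numeric(length(t_h))
  for (i in seq_len(nrow(schedule))) {
    inside <- t_h >= schedule$start_h[i] & t_h < schedule$end_h[i]
    r[inside] <- schedule$rate_mg_per_h[i]
  }
  r
}

#' Append a segment to a schedule
#' @param schedule an [infusion_schedule()].
#' @param start_h,end_h,rate_mg_per_h the new segment.
#' @return The extended schedule.
#' @export
schedule_append <- function(schedule, start_h, end_h, rate_mg_per_h) {
  infusion_schedule(c(schedule$start_h, start_h),
                    c(schedule$end_h, end_h),
                    c(schedule$rate_mg_per_h, rate_mg_per_h))
}

#' Read and write infusion schedules as JSON
#'
#' The on-disk format is a JSON array of objects with keys `start_h`, `end_h`,
#' `rate_mg_per_h`.
#'
#' @param schedule an [infusion_schedule()].
#' @param path file path.
#' @return `read_schedule_json` returns an [infusion_schedule()];
#'   `write_schedule_json` returns `path` invisibly.
#' @export
write_schedule_json <- function(schedule, path) {
  jsonlite::write_json(as.data.frame(unclass(schedule)), path,
                       digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_schedule_json
#' @export
read_schedule_json <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(d) == 0L) return(infusion_schedule())
  infusion_schedule(d$start_h, d$end_h, d$rate_mg_per_h)
}
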