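## Pressure logs, the accumulated pressure impact (AUPI) metric, and study
## summaries.

#' Read a pressure log from a comma-separated file
#'
#' Expects a header `time_min,pressure_mmHg`. Malformed rows are reported
#' with their line numbers; non-monotone times and negative pressures are
#' rejected naming the first offending line.
#'
#' @param path path to the CSV file.
#' @param subjectId subject label to attach (default: file name).
#' @return A [PressureLog-class].
#' @export
readPressureLog <- function(path, subjectId = NULL) {
  raw <- readLines(path)
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) < 2L)
    stop("empty pressure log (need a header and at least one sample): ", path)
  header <- trimws(strsplit(raw[1], ",")[[1]])
  if (!identical(header, c("time_min", "pressure_mmHg")))
    stop("expected header 'time_min,pressure_mmHg', got '", raw[1], "'")
  n <- length(raw) - 1L
  tm <- numeric(n); pr <- numeric(n)
  for (i in seq_len(n)) {
    parts <- strsplit(raw[i + 1L], ",")[[1]]
    vals <- suppressWarnings(as.numeric(trimws(parts)))
    if (length(vals) != 2L || any(is.na(vals)))
      stop("malformed pressure log row at line ", i + 1L, ": '",
           raw[i + 1L], "'")
    tm[i] <- vals[1]; pr[i] <- vals[2]
  }
  if (n > 1L) {
    bad <- which(diff(tm) <= 0)
    if (length(bad))
      stop("non-monotone time at line ", bad[1] + 2L,
           " (t = ", tm[bad[1] + 1L], " after t = ", tm[bad[1]], ")")
  }
  neg <- which(pr < 0)
  if (length(neg))
    stop("negative pressure at line ", neg[1] + 1L)
  pressureLog(tm, pr, subjectId %||% basename(path))
}

#' Write a pressure log as CSV
#'
#' @param log a [PressureLog-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePressureLog <- function(log, path) {
  write.csv(logSamples(log), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Accumulated pressure impact (AUPI)
#'
#' Time integral of intrarenal pressure from irrigation start (the first
#' log sample) to `t`, in mmHg·min, by the trapezoidal rule on the sampled
#' points — exact for piecewise-linear logs, hence exact for staircase
#' protocols with linear level transitions. Non-decreasing in `t`, additive
#' over adjacent intervals, and invariant to inserting collinear samples.
#'
#' With `subtractBaseline = TRUE` the pressure at the first sample is
#' subtracted before integrating (negative excess truncated at zero),
#' giving the pressure load above the pre-irrigation baseline instead of
#' the absolute load.
#'
#' @param log a [PressureLog-class].
#' @param t evaluation time(s), minutes, within the log's time span.
#' @param subtractBaseline integrate pressure above the first-sample
#'   baseline instead of absolute pressure.
#' @return AUPI in mmHg·min, one value per `t`.
#' @examples
#' accumulatedPressure(pressureLog(c(0, 60), c(20, 20)), 60)  # 1200
#' @export
accumulatedPressure <- function(log, t, subtractBaseline = FALSE) {
  s <- logSamples(log)
  tm <- s$time_min
  pr <- s$pressure_mmHg
  if (subtractBaseline) pr <- pmax(pr - pr[1], 0)
  if (any(t < tm[1] - 1e-9) || any(t > tm[length(tm)] + 1e-9))
    stop("t outside the log time span [", tm[1], ", ", tm[length(tm)], "]")
  cumA <- c(0, cumsum(diff(tm) * (head(pr, -1) + tail(pr, -1)) / 2))
  vapply(t, function(tt) {
    i <- findInterval(tt, tm, rightmost.closed = TRUE)
    i <- min(max(i, 1L), length(tm))
    if (tt <= tm[i]) return(cumA[i])
    p_t <- pr[i] + (pr[i + 1L] - pr[i]) * (tt - tm[i]) / (tm[i + 1L] - tm[i])
    cumA[i] + (tt - tm[i]) * (pr[i] + p_t) / 2
  }, 0.0)
}

#' Interpolated pressure at a time point
#'
#' Linear interpolation of the log at `t` (used to report the concurrent
#' pressure of a scan).
#'
#' @param log a [PressureLog-class].
#' @param t time(s) in minutes within the log span.
#' @return Pressure(s) in mmHg.
#' @export
pressureAtTime <- function(log, t) {
  s <- logSamples(log)
  if (nrow(s) == 1L) return(rep(s$pressure_mmHg, length(t)))
  approx(s$time_min, s$pressure_mmHg, xout = t, rule = 1)$y
}

#' Build a staircase pressure protocol
#'
#' Piecewise-linear staircase through the given pressure levels, each held
#' for `levelDuration` minutes, with linear transitions of width
#' `rampWidth` centred on the level boundaries. Centred ramps leave the
#' time integral identical to the ideal rectangle sum, so AUPI of the
#' returned log is exact for the nominal staircase.
#'
#' @param levels pressure levels in mmHg, in protocol order.
#' @param levelDuration minutes each level is held.
#' @param rampWidth transition width in minutes (> 0, < `levelDuration`).
#' @param subjectId subject label.
#' @return A [PressureLog-class].
#' @examples
#' accumulatedPressure(staircaseLog(), 70)  # 2100 mmHg·min
#' @export
staircaseLog <- function(levels = c(10, 20, 30, 40, 50), levelDuration = 14,
                         rampWidth = 1, subjectId = "") {
  stopifnot(rampWidth > 0, rampWidth < levelDuration)
  K <- length(levels)
  tm <- 0; pr <- levels[1]
  for (k in seq_len(K - 1)) {
    b <- k * levelDuration
    tm <- c(tm, b - rampWidth / 2, b + rampWidth / 2)
    pr <- c(pr, levels[k], levels[k + 1])
  }
  tm <- c(tm, K * levelDuration)
  pr <- c(pr, levels[K])
  pressureLog(tm, pr, subjectId)
}

#' Summarise per-subject study endpoints
#'
#' Arithmetic mean and (min, max) range of every numeric endpoint across
#' subjects, plus means rounded to reporting precision: nearest integer for
#' times (minutes) and pressures (mmHg), nearest percent for fractions
#' (columns whose name contains "fraction").
#'
#' @param records data.frame of per-subject endpoint records, one row per
#'   subject; non-numeric columns (e.g. subject ids) are carried through
#'   `perSubject` but not summarised.
#' @return A [StudySummary-class].
#' @examples
#' rec <- data.frame(first_change_pressure_mmHg = c(25, 20, 22, 22, 16))
#' studyRoundedMeans(summarizeStudy(rec))  # 21
#' @export
summarizeStudy <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("need at least one subject record")
  num <- vapply(records, is.numeric, TRUE)
  cols <- names(records)[num]
  if (length(cols) == 0L) stop("no numeric endpoint columns to summarise")
  means <- vapply(records[cols], mean, 0.0)
  rng <- vapply(records[cols], range, numeric(2))
  rounded <- vapply(cols, function(nm) {
    if (grepl("fraction", nm, ignore.case = TRUE))
      round(means[[nm]] * 100) / 100   # nearest percent, kept as fraction
    else round(means[[nm]])
  }, 0.0)
  new("StudySummary", perSubject = records, means = means,
      roundedMeans = setNames(rounded, cols),
      ranges = as.data.frame(matrix(rng, nrow = 2,
                                    dimnames = list(c("min", "max"), cols))))
}
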