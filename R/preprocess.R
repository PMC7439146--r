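#' Read a raw wearable recording from CSV exports
#'
#' Loads the two per-participant device exports: minute-level heart rate
#' (`hr.csv`: columns `timestamp`, `bpm`) and 15-minute step counts
#' (`steps.csv`: columns `timestamp`, `steps`, bin-start timestamps), plus
#' an optional minute-level sleep-stage export (`stages.csv`: columns
#' `timestamp`, `stage`). Missing heart-rate minutes may appear as absent
#' rows or empty bpm cells. All timestamps are parsed in a single fixed
#' timezone.
#'
#' @param hr_csv,steps_csv,stages_csv file paths; `stages_csv` may be
#'   `NULL`.
#' @param participant_id identifier stored with the recording.
#' @param tz fixed timezone for timestamp parsing.
#' @return an object of class `raw_recording`: list with data frames
#'   `hr` (time, bpm), `steps15` (time, steps) and optionally `stages`
#'   (time, stage).
#' @export
read_recording <- function(hr_csv, steps_csv, stages_csv = NULL,
                           participant_id = "unknown", tz = "UTC") {
  parse_time <- function(x) {
    t <- as.POSIXct(x, tz = tz, tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                               "%Y-%m-%d %H:%M:%S",
                                               "%Y-%m-%dT%H:%M",
                                               "%Y-%m-%d %H:%M"))
    if (any(is.na(t))) stop("unparseable timestamp(s), e.g. ",
                            x[which(is.na(t))[1]])
    t
  }
  hr <- read.csv(hr_csv, stringsAsFactors = FALSE)
  names(hr)[1:2] <- c("time", "bpm")
  hr$time <- parse_time(hr$time)
  hr$bpm <- suppressWarnings(as.numeric(hr$bpm))
  steps <- read.csv(steps_csv, stringsAsFactors = FALSE)
  names(steps)[1:2] <- c("time", "steps")
  steps$time <- parse_time(steps$time)
  steps$steps <- as.numeric(steps$steps)
  stages <- NULL
  if (!is.null(stages_csv)) {
    stages <- read.csv(stages_csv, stringsAsFactors = FALSE)
    names(stages)[1:2] <- c("time", "stage")
    stages$time <- parse_time(stages$time)
  }
  raw_recording(hr = hr, steps15 = steps, stages = stages,
                participant_id = participant_id)
}

#' Construct and validate a raw recording
#'
#' @param hr data frame (time, bpm), 1-minute resolution; `NA` bpm marks
#'   missing minutes.
#' @param steps15 data frame (time, steps), bin starts on 15-minute
#'   boundaries, non-negative integer counts.
#' @param stages optional data frame (time, stage).
#' @param participant_id identifier.
#' @return object of class `raw_recording`.
#' @export
raw_recording <- function(hr, steps15, stages = NULL,
                          participant_id = "unknown") {
  dedupe <- function(df, what) {
    df$time <- round_to_minute(df$time)
    if (anyDuplicated(df$time)) {
      warning("duplicate ", what, " timestamps: keeping first occurrence")
      df <- df[!duplicated(df$time), , drop = FALSE]
    }
    if (is.unsorted(as.numeric(df$time)))
      df <- df[order(df$time), , drop = FALSE]
    df
  }
  hr <- dedupe(hr, "heart-rate")
  steps15 <- dedupe(steps15, "step")
  ok_bpm <- is.na(hr$bpm) | (hr$bpm > 20 & hr$bpm < 250)
  if (!all(ok_bpm))
    stop("bpm outside the plausible (20, 250) range at ",
         format(hr$time[!ok_bpm][1]))
  if (any(is.na(steps15$steps) | steps15$steps < 0))
    stop("negative or missing step counts are not allowed")
  mins <- as.integer(format(steps15$time, "%M"))
  secs <- as.integer(format(steps15$time, "%S"))
  bad <- mins %% 15L != 0L | secs != 0L
  if (any(bad))
    stop("step bin start not aligned to a 15-minute boundary: ",
         format(steps15$time[bad][1]))
  if (!is.null(stages)) stages <- dedupe(stages, "stage")
  structure(list(participant_id = participant_id, hr = hr,
                 steps15 = steps15, stages = stages),
            class = "raw_recording")
}

round_to_minute <- function(t) {
  as.POSIXct(floor(as.numeric(t) / 60) * 60,
             origin = "1970-01-01", tz = attr(t, "tzone") %||% "UTC")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Downscale 15-minute step counts to 1-minute values
#'
#' Each 15-minute total is evenly distributed across its 15 minutes
#' (count / 15, real-valued), so the per-bin sum is preserved exactly.
#' Minutes belonging to absent bins are returned missing.
#'
#' @param steps15 data frame (time, steps) with bin-start timestamps on
#'   15-minute boundaries.
#' @return data frame (time, step) at 1-minute resolution spanning the
#'   recorded bins.
#' @export
downscale_steps <- function(steps15) {
  if (is.list(steps15) && !is.data.frame(steps15) &&
      !is.null(steps15$steps15)) steps15 <- steps15$steps15
  if (nrow(steps15) == 0L) stop("empty step series")
  if (any(steps15$steps < 0)) stop("negative step count")
  mins <- as.integer(format(steps15$time, "%M"))
  if (any(mins %% 15L != 0L))
    stop("step bin start not aligned to a 15-minute boundary: ",
         format(steps15$time[mins %% 15L != 0L][1]))
  t0 <- steps15$time[1]
  t1 <- steps15$time[nrow(steps15)] + 14 * 60
  grid <- seq(t0, t1, by = 60)
  step <- rep(NA_real_, length(grid))
  idx <- match(as.numeric(steps15$time), as.numeric(grid))
  for (k in 0:14) step[idx + k] <- steps15$steps / 15
  data.frame(time = grid, step = step)
}

#' Screen calendar days for device nonwear
#'
#' A full calendar day is flagged as nonwear if more than 30 minutes of
#' heart rate are missing on that day, or if the day's total step count is
#' zero (free-living wearers register at least some steps on any day the
#' device is worn). Partial first/last days are excluded from day
#' counting. A participant whose nonwear fraction exceeds 50% of observed
#' days is marked excluded.
#'
#' @param rec a `raw_recording`.
#' @return object of class `nonwear_report`: data frame with one row per
#'   full calendar day (`day`, `missing_hr_minutes`, `total_steps`,
#'   `nonwear`), plus attributes `excluded` and `nonwear_fraction`.
#' @export
detect_nonwear_days <- function(rec) {
  stopifnot(inherits(rec, "raw_recording"))
  if (nrow(rec$hr) == 0L && nrow(rec$steps15) == 0L)
    stop("empty recording")
  tz <- attr(rec$hr$time, "tzone") %||% "UTC"
  span <- range(c(rec$hr$time, rec$steps15$time))
  d0 <- as.Date(span[1], tz = tz)
  d1 <- as.Date(span[2], tz = tz)
  # keep only days fully inside the recording span
  full0 <- if (format(span[1], "%H:%M") == "00:00") d0 else d0 + 1
  full1 <- if (format(span[2] + 60, "%H:%M") == "00:00") d1 else d1 - 1
  if (full1 < full0) stop("recording does not span a full calendar day")
  days <- seq(full0, full1, by = "day")

  hr_day <- as.Date(rec$hr$time, tz = tz)
  hr_present <- tapply(!is.na(rec$hr$bpm), factor(hr_day, levels = as.character(days)),
                       sum)
  hr_present[is.na(hr_present)] <- 0
  st_day <- as.Date(rec$steps15$time, tz = tz)
  st_tot <- tapply(rec$steps15$steps, factor(st_day, levels = as.character(days)),
                   sum)
  st_tot[is.na(st_tot)] <- 0

  rep_df <- data.frame(day = days,
                       missing_hr_minutes = 1440 - as.numeric(hr_present),
                       total_steps = as.numeric(st_tot))
  rep_df$nonwear <- rep_df$missing_hr_minutes > 30 | rep_df$total_steps == 0
  frac <- mean(rep_df$nonwear)
  structure(rep_df, excluded = frac > 0.5, nonwear_fraction = frac,
            class = c("nonwear_report", "data.frame"))
}

#' Build the aligned minute-level observation series
#'
#' Produces the canonical per-minute bivariate series used by the HMM:
#' heart rate (bpm) and activity level `act = log(step + 1)` with the
#' 15-minute step totals evenly downscaled to minutes. Nonwear days are
#' dropped; remaining missing heart-rate minutes are kept and flagged, to
#' be handled by the missing-data likelihood.
#'
#' @param rec a `raw_recording`.
#' @param report a `nonwear_report`; computed from `rec` if `NULL`.
#' @return an [epoch_series].
#' @export
build_epoch_series <- function(rec, report = NULL) {
  stopifnot(inherits(rec, "raw_recording"))
  if (is.null(report)) report <- detect_nonwear_days(rec)
  if (attr(report, "excluded"))
    stop("participant excluded: more than 50% nonwear days")
  keep_days <- report$day[!report$nonwear]
  if (length(keep_days) == 0L) stop("participant excluded: all days nonwear")
  tz <- attr(rec$hr$time, "tzone") %||% "UTC"

  grids <- lapply(keep_days, function(d) {
    t0 <- as.POSIXct(paste(d, "00:00:00"), tz = tz)
    seq(t0, by = 60, length.out = 1440)
  })
  grid <- do.call(c, grids)

  hr <- rep(NA_real_, length(grid))
  m <- match(as.numeric(round_to_minute(rec$hr$time)), as.numeric(grid))
  hr[m[!is.na(m)]] <- rec$hr$bpm[!is.na(m)]

  ds <- downscale_steps(rec$steps15)
  step <- rep(NA_real_, length(grid))
  m <- match(as.numeric(ds$time), as.numeric(grid))
  step[m[!is.na(m)]] <- ds$step[!is.na(m)]

  epoch_series(time = grid, hr = hr, step = step)
}

#' Minute-level epoch series
#'
#' The canonical container for aligned 1-minute observations: heart rate,
#' downscaled step value, activity level `act = log(step + 1)`, a
#' missing-heart-rate flag, and calendar bookkeeping (day, day of week).
#'
#' @param time POSIXct minute timestamps (strictly increasing).
#' @param hr heart rate in bpm (`NA` = missing).
#' @param step per-minute (possibly fractional) step value (`NA` =
#'   missing).
#' @return data frame of class `epoch_series` with columns `time`, `hr`,
#'   `step`, `act`, `hr_missing`, `day`, `dow` (0 = Sunday ... 6 =
#'   Saturday).
#' @export
epoch_series <- function(time, hr, step) {
  stopifnot(length(time) == length(hr), length(hr) == length(step))
  if (any(!is.na(step) & step < 0)) stop("step values must be non-negative")
  if (length(time) > 1 && any(diff(as.numeric(time)) <= 0))
    stop("timestamps must be strictly increasing")
  tz <- attr(time, "tzone") %||% "UTC"
  out <- data.frame(time = time, hr = hr, step = step,
                    act = log(step + 1), hr_missing = is.na(hr))
  out$day <- as.Date(out$time, tz = tz)
  out$dow <- as.POSIXlt(out$time, tz = tz)$wday
  class(out) <- c("epoch_series", "data.frame")
  out
}

#' Write / read the canonical per-minute CSV
#'
#' @param series an [epoch_series].
#' @param path output file.
#' @export
write_epochs <- function(series, path) {
  df <- as.data.frame(series)
  df$time <- format(df$time, "%Y-%m-%dT%H:%M:%S")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_epochs
#' @param tz timezone used when parsing timestamps back in.
#' @export
read_epochs <- function(path, tz = "UTC") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  time <- as.POSIXct(df$time, tz = tz, format = "%Y-%m-%dT%H:%M:%S")
  epoch_series(time = time, hr = df$hr, step = df$step)
}
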