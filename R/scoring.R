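#' Map hidden states to sleep/wake labels
#'
#' The state with the higher mean heart rate *and* higher mean activity
#' level is the active (wake) state; the other is sleep. If the two
#' channels rank the states discordantly, activity decides (movement is
#' the more direct wake marker) and a warning is emitted. Univariate fits
#' are labelled by their single channel's mean.
#'
#' @param fit an `hmm_fit` (or [hmm_parameters] together with `scheme`).
#' @param scheme emission scheme when `fit` is a bare parameter set.
#' @return character vector of length 2 mapping state index to
#'   `"sleep"`/`"wake"`.
#' @export
label_states <- function(fit, scheme = NULL) {
  if (inherits(fit, "hmm_fit")) {
    params <- fit$parameters
    scheme <- fit$scheme
  } else {
    params <- fit
    if (is.null(scheme)) stop("supply `scheme` with bare parameters")
    scheme <- check_scheme(scheme)
  }
  decide <- function(v, what) {
    if (v[1] == v[2])
      stop("degenerate fit: equal state means on the ", what, " channel")
    which.max(v)
  }
  wake <- switch(scheme,
    HR_ONLY = decide(params$mu_hr, "heart-rate"),
    ACT_ONLY = decide(params$mu_act, "activity"),
    {
      by_hr <- decide(params$mu_hr, "heart-rate")
      by_act <- decide(params$mu_act, "activity")
      if (by_hr != by_act)
        warning("state ranking discordant between channels; ",
                "labelling wake by the higher mean activity level")
      by_act
    })
  labels <- c("sleep", "sleep")
  labels[wake] <- "wake"
  labels
}

#' Score a series: decode, label and (optionally) rescore
#'
#' Convenience wrapper running Viterbi decoding, state labelling and
#' Webster rescoring in one call.
#'
#' @param fit an `hmm_fit`.
#' @param series the [epoch_series] the fit was computed on.
#' @param rescore apply [webster_rescore()] to the decoded labels.
#' @param surround passed to [webster_rescore()].
#' @return object of class `scored_series`: data frame with columns
#'   `time` (if present in `series`), `raw_label`, `rescored_label`.
#' @export
score_series <- function(fit, series, rescore = TRUE, surround = "both") {
  path <- viterbi_decode(fit, series)
  labels <- label_states(fit)[path$states]
  out <- data.frame(raw_label = labels,
                    rescored_label = if (rescore)
                      webster_rescore(labels, surround = surround) else labels,
                    stringsAsFactors = FALSE)
  if (!is.null(series$time)) out <- cbind(time = series$time, out)
  class(out) <- c("scored_series", "data.frame")
  out
}

check_labels <- function(labels) {
  if (inherits(labels, "scored_series"))
    labels <- labels$rescored_label %||% labels$raw_label
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("sleep", "wake"))
  if (length(bad))
    stop("labels must be 'sleep' or 'wake'; found: ",
         paste(bad, collapse = ", "))
  labels
}

#' Webster rescoring rules
#'
#' Actigraphy-style post-processing correcting the systematic
#' wake-scored-as-sleep error. Five rules are applied sequentially, each
#' as one left-to-right pass over the sequence as updated by the earlier
#' rules; rescored minutes count as wake for the later rules. Rules never
#' convert wake to sleep:
#' 1. after >= 4 minutes scored wake, the first sleep minute is rescored
#'    wake;
#' 2. after >= 10 wake minutes, the first 3 sleep minutes are rescored;
#' 3. after >= 15 wake minutes, the first 4 sleep minutes are rescored;
#' 4. sleep runs of <= 6 minutes flanked by >= 10 wake minutes are
#'    rescored entirely;
#' 5. sleep runs of <= 10 minutes flanked by >= 20 wake minutes are
#'    rescored entirely.
#'
#' For rules 4-5 the flanking requirement is applied on *both* sides by
#' default (the original formulation); `surround = "either"` relaxes it to
#' one side. Sleep runs at the sequence boundary lack a flank and are
#' never rescored by rules 4-5; rules 1-3 need a preceding wake run.
#'
#' @param labels character vector of `"sleep"`/`"wake"` minute labels (or
#'   a `scored_series`).
#' @param surround `"both"` (default) or `"either"`: whether rules 4-5
#'   require the wake flank on both sides or on at least one.
#' @return rescored character vector, same length.
#' @export
webster_rescore <- function(labels, surround = c("both", "either")) {
  surround <- match.arg(surround)
  lab <- check_labels(labels)
  lab <- rescore_after_wake(lab, 4L, 1L)
  lab <- rescore_after_wake(lab, 10L, 3L)
  lab <- rescore_after_wake(lab, 15L, 4L)
  lab <- rescore_surrounded(lab, 6L, 10L, surround)
  lab <- rescore_surrounded(lab, 10L, 20L, surround)
  lab
}

# rules 1-3: after a wake run of >= n_wake, rescore the first n_rescore
# minutes of the following sleep bout
rescore_after_wake <- function(lab, n_wake, n_rescore) {
  T_ <- length(lab)
  wake_run <- 0L
  t <- 1L
  while (t <= T_) {
    if (lab[t] == "wake") {
      wake_run <- wake_run + 1L
      t <- t + 1L
    } else {
      s <- t
      while (t <= T_ && lab[t] == "sleep") t <- t + 1L
      blen <- t - s
      if (wake_run >= n_wake) {
        k <- min(n_rescore, blen)
        lab[s:(s + k - 1L)] <- "wake"
        # a fully rescored bout merges its flanking wake runs
        wake_run <- if (k == blen) wake_run + k else 0L
      } else {
        wake_run <- 0L
      }
    }
  }
  lab
}

# rules 4-5: sleep runs of <= max_len flanked by wake runs of >= n_flank
rescore_surrounded <- function(lab, max_len, n_flank, surround) {
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # effective left-wake length grows as converted runs merge
  left_wake <- 0L
  for (i in seq_along(r$values)) {
    if (r$values[i] == "wake") {
      left_wake <- left_wake + r$lengths[i]
      next
    }
    right_wake <- if (i < length(r$values) && r$values[i + 1L] == "wake")
      r$lengths[i + 1L] else 0L
    has_left <- i > 1L
    has_right <- i < length(r$values)
    fire <- if (surround == "both")
      has_left && has_right && left_wake >= n_flank && right_wake >= n_flank
    else
      (has_left && left_wake >= n_flank) || (has_right && right_wake >= n_flank)
    if (r$lengths[i] <= max_len && fire) {
      lab[starts[i]:ends[i]] <- "wake"
      left_wake <- left_wake + r$lengths[i]
    } else {
      left_wake <- 0L
    }
  }
  lab
}

#' Cross-tabulate three scorers minute by minute
#'
#' Builds the 8-cell comparison between the activity-only HMM, the
#' heart-rate-only HMM and the fused bivariate model: per combination of
#' labels, the minute count, percentage of all minutes, and the mean (SD)
#' heart rate and activity level of the minutes in that cell.
#'
#' @param series the [epoch_series] providing `hr` and `act`.
#' @param act_labels,hr_labels,fusion_labels equal-length sleep/wake label
#'   vectors (or `scored_series` objects) from the three models.
#' @return object of class `scorer_crosstab`: data frame with columns
#'   `act_hmm`, `hr_hmm`, `fusion`, `n`, `pct`, `hr_mean`, `hr_sd`,
#'   `act_mean`, `act_sd`.
#' @export
compare_scorers <- function(series, act_labels, hr_labels, fusion_labels) {
  a <- check_labels(act_labels)
  h <- check_labels(hr_labels)
  f <- check_labels(fusion_labels)
  n <- length(a)
  if (length(h) != n || length(f) != n || nrow(series) != n)
    stop("scored series and epoch series must have equal length")
  combos <- expand.grid(fusion = c("wake", "sleep"),
                        hr_hmm = c("wake", "sleep"),
                        act_hmm = c("wake", "sleep"),
                        stringsAsFactors = FALSE)[, 3:1]
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sel <- a == combos$act_hmm[i] & h == combos$hr_hmm[i] &
      f == combos$fusion[i]
    cnt <- sum(sel)
    summ <- function(x) if (cnt > 0) c(mean(x[sel], na.rm = TRUE),
                                       sd(x[sel], na.rm = TRUE))
    else c(NA_real_, NA_real_)
    sh <- summ(series$hr); sa <- summ(series$act)
    data.frame(combos[i, , drop = FALSE], n = cnt, pct = 100 * cnt / n,
               hr_mean = sh[1], hr_sd = sh[2],
               act_mean = sa[1], act_sd = sa[2])
  }))
  rownames(out) <- NULL
  class(out) <- c("scorer_crosstab", "data.frame")
  out
}

#' Reclassify device sleep stages to binary sleep/wake
#'
#' Maps the consumer device's 7-value stage vocabulary onto sleep/wake:
#' `asleep`, `deep`, `light`, `rem` become sleep; `restless`, `awake`,
#' `wake` become wake.
#'
#' @param stages character vector of stage strings (`NA` preserved as
#'   missing).
#' @return character vector of `"sleep"`/`"wake"` (and `NA`).
#' @export
reclassify_fitbit <- function(stages) {
  if (length(stages) == 0L) return(character(0))
  map <- c(asleep = "sleep", deep = "sleep", light = "sleep", rem = "sleep",
           restless = "wake", awake = "wake", wake = "wake")
  s <- tolower(as.character(stages))
  known <- is.na(s) | s %in% names(map)
  if (!all(known))
    stop("unknown stage label(s): ",
         paste(unique(s[!known]), collapse = ", "))
  out <- rep(NA_character_, length(s))
  out[!is.na(s)] <- map[s[!is.na(s)]]
  out
}

#' Minute-by-minute agreement between two scorers
#'
#' Minutes missing (`NA`) in either scorer are excluded from the
#' comparison and counted.
#'
#' @param a,b equal-length label vectors (or `scored_series`).
#' @return list with `agreement` (fraction of compared minutes with equal
#'   labels), `n_compared`, `n_excluded`.
#' @export
minute_agreement <- function(a, b) {
  if (inherits(a, "scored_series")) a <- a$rescored_label
  if (inherits(b, "scored_series")) b <- b$rescored_label
  if (length(a) != length(b)) stop("series must be aligned and equal length")
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no overlapping scored minutes")
  list(agreement = mean(a[ok] == b[ok]),
       n_compared = sum(ok), n_excluded = sum(!ok))
}

#' Nightly total sleep time within the habitual bedtime window
#'
#' Counts the rescored sleep minutes inside each night's bedtime window.
#' Windows crossing midnight attach to the night of the bedtime. Nights
#' whose window overlaps removed (nonwear) minutes are flagged as
#' incomplete; nights with no data in the window are omitted with a
#' warning.
#'
#' @param scored a `scored_series` with a `time` column.
#' @param bedtime,risetime clock times `"HH:MM"`.
#' @return data frame with one row per night: `night` (date of the
#'   bedtime), `sleep_minutes`, `minutes_present`, `window_minutes`,
#'   `complete`.
#' @export
total_sleep_time <- function(scored, bedtime, risetime) {
  stopifnot(!is.null(scored$time))
  lab <- scored$rescored_label %||% scored$raw_label
  tz <- attr(scored$time, "tzone") %||% "UTC"
  parse_clock <- function(x) {
    p <- as.integer(strsplit(x, ":")[[1]])
    p[1] * 60L + p[2]
  }
  bed <- parse_clock(bedtime)
  rise <- parse_clock(risetime)
  wlen <- (rise - bed) %% 1440L
  if (wlen == 0L) stop("bedtime window must have positive length below 24h")

  days <- sort(unique(as.Date(scored$time, tz = tz)))
  nights <- lapply(days, function(d) {
    t0 <- as.POSIXct(paste(d, "00:00:00"), tz = tz) + bed * 60
    t1 <- t0 + wlen * 60
    sel <- scored$time >= t0 & scored$time < t1
    present <- sum(sel)
    if (present == 0L) return(NULL)
    data.frame(night = d,
               sleep_minutes = sum(lab[sel] == "sleep", na.rm = TRUE),
               minutes_present = present, window_minutes = wlen,
               complete = present == wlen)
  })
  dropped <- sum(vapply(nights, is.null, TRUE))
  if (dropped > 0)
    warning(dropped, " night(s) omitted: bedtime window not covered by data")
  out <- do.call(rbind, nights)
  if (is.null(out)) stop("no night's bedtime window is covered by the data")
  rownames(out) <- NULL
  out
}
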