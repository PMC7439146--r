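.daily_params <- c("gamma12", "gamma21",
                   "wake_mu_act", "wake_sigma2_act", "wake_mu_hr",
                   "wake_sigma2_hr", "wake_rho",
                   "sleep_mu_act", "sleep_sigma2_act", "sleep_mu_hr",
                   "sleep_sigma2_hr", "sleep_rho")

params_row <- function(p) {
  data.frame(gamma12 = p$Gamma[.wake_state, .sleep_state],
             gamma21 = p$Gamma[.sleep_state, .wake_state],
             wake_mu_act = p$mu_act[.wake_state],
             wake_sigma2_act = p$sigma2_act[.wake_state],
             wake_mu_hr = p$mu_hr[.wake_state],
             wake_sigma2_hr = p$sigma2_hr[.wake_state],
             wake_rho = p$rho[.wake_state],
             sleep_mu_act = p$mu_act[.sleep_state],
             sleep_sigma2_act = p$sigma2_act[.sleep_state],
             sleep_mu_hr = p$mu_hr[.sleep_state],
             sleep_sigma2_hr = p$sigma2_hr[.sleep_state],
             sleep_rho = p$rho[.sleep_state])
}

#' Fit one HMM per anchored calendar day
#'
#' Segments the epoch series into anchored 24-hour days (default anchor
#' 08:00, so a "day" runs 8 AM to 7:59 AM and contains one whole night)
#' and fits the chosen scheme independently to each complete 1440-minute
#' day. Days where EM degenerates (either state occupies fewer than
#' `min_state_minutes` posterior minutes) are marked invalid. Each day is
#' classified weekday/weekend by the calendar date of its anchor start.
#'
#' @param series an [epoch_series].
#' @param scheme emission scheme for the daily fits.
#' @param anchor_hour hour of day at which analysis days start.
#' @param seed integer seed (per-day seeds are derived from it).
#' @param init_fit optional participant-level `hmm_fit` whose parameters
#'   seed each day's EM (reduces day-level label switching).
#' @param n_restarts EM restarts per day (in addition to `init_fit`).
#' @param min_state_minutes minimum posterior occupancy for a valid day.
#' @return object of class `daily_fit_set`: data frame with one row per
#'   day (`day`, `weekday` flag, `valid`, log likelihood, the 12 reported
#'   parameters) and attribute `fits` (list of `hmm_fit`).
#' @export
fit_daily_models <- function(series, scheme = "M1", anchor_hour = 8,
                             seed = 1, init_fit = NULL, n_restarts = 1,
                             min_state_minutes = 30) {
  stopifnot(!is.null(series$time))
  tz <- attr(series$time, "tzone") %||% "UTC"
  anchor_day <- as.Date(series$time - anchor_hour * 3600, tz = tz)
  days <- sort(unique(anchor_day))
  init <- if (inherits(init_fit, "hmm_fit")) init_fit$parameters else init_fit

  rows <- list(); fits <- list()
  for (k in seq_along(days)) {
    d <- days[k]
    sel <- anchor_day == d
    n <- sum(sel)
    wd <- !(as.POSIXlt(as.POSIXct(paste(d, "00:00:00"), tz = tz))$wday
            %in% c(0L, 6L))
    if (n != 1440L) {
      pr <- params_row(empty_params()); pr[] <- NA_real_
      rows[[k]] <- cbind(data.frame(day = d, weekday = wd, valid = FALSE,
                                    log_likelihood = NA_real_), pr)
      fits[[k]] <- NULL
      next
    }
    fit <- tryCatch(
      suppressWarnings(fit_hmm(series[sel, , drop = FALSE], scheme = scheme,
                               n_restarts = n_restarts,
                               seed = (seed + k) %% .Machine$integer.max,
                               init = init)),
      error = function(e) NULL)
    valid <- !is.null(fit) && all(fit$occupancy >= min_state_minutes)
    pr <- if (!is.null(fit)) params_row(fit$parameters)
          else params_row(empty_params())
    if (!valid) pr[] <- NA_real_
    rows[[k]] <- cbind(data.frame(day = d, weekday = wd, valid = valid,
                                  log_likelihood = if (!is.null(fit))
                                    fit$log_likelihood else NA_real_), pr)
    fits[[k]] <- fit
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, fits = fits, scheme = scheme, anchor_hour = anchor_hour,
            class = c("daily_fit_set", "data.frame"))
}

empty_params <- function() {
  hmm_parameters(pi = c(0.5, 0.5), Gamma = matrix(0.5, 2, 2),
                 mu_hr = c(0, 1), sigma2_hr = c(1, 1),
                 mu_act = c(0, 1), sigma2_act = c(1, 1))
}

#' Weekday vs weekend comparison of daily parameter estimates
#'
#' For each of the 12 reported parameters (the two off-diagonal transition
#' probabilities and the per-state emission parameters; the diagonal
#' transition entries are omitted as redundant), runs a two-tailed
#' independent-samples t test of the weekday daily estimates against the
#' weekend ones. Welch's unequal-variance form is the default.
#'
#' @param daily a `daily_fit_set`.
#' @param var_equal use the pooled-variance t test instead of Welch.
#' @param p_adjust optional multiple-testing correction method passed to
#'   [stats::p.adjust()] (e.g. "BH"); default none, matching the raw
#'   per-parameter reporting convention.
#' @param alpha significance level.
#' @return data frame with columns `parameter`, `weekday_mean`,
#'   `weekend_mean`, `p_value`, `significant`, `note`.
#' @export
weekday_weekend_tests <- function(daily, var_equal = FALSE,
                                  p_adjust = NULL, alpha = 0.05) {
  ok <- daily$valid
  wd <- daily[ok & daily$weekday, , drop = FALSE]
  we <- daily[ok & !daily$weekday, , drop = FALSE]
  if (nrow(wd) < 2 || nrow(we) < 2)
    stop("need at least 2 valid days in each of the weekday and weekend ",
         "groups (have ", nrow(wd), " and ", nrow(we), ")")
  rows <- lapply(.daily_params, function(pn) {
    x <- wd[[pn]]; y <- we[[pn]]
    note <- ""
    p <- tryCatch(t.test(x, y, var.equal = var_equal)$p.value,
                  error = function(e) {
                    note <<- "not computable (zero variance)"
                    NA_real_
                  })
    data.frame(parameter = pn, weekday_mean = mean(x), weekend_mean = mean(y),
               p_value = p, note = note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(p_adjust)) out$p_value <- stats::p.adjust(out$p_value, p_adjust)
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out[c("parameter", "weekday_mean", "weekend_mean", "p_value",
        "significant", "note")]
}

#' Cohort summary of per-participant HMM parameters
#'
#' Mean (SD) of each estimated parameter across participants, separately
#' for the wake and sleep states, plus the mean transition matrix rows.
#'
#' @param fits list of per-participant `hmm_fit` objects.
#' @return data frame with columns `parameter`, `wake_mean`, `wake_sd`,
#'   `sleep_mean`, `sleep_sd`; transition rows are reported in the
#'   `wake_*` columns with parameter names `gamma_wake_to_sleep`,
#'   `gamma_sleep_to_wake`.
#' @export
summarize_cohort <- function(fits) {
  stopifnot(length(fits) >= 1)
  mat <- do.call(rbind, lapply(fits, function(f)
    as.numeric(params_row(f$parameters))))
  colnames(mat) <- .daily_params
  msd <- function(col) c(mean(mat[, col]),
                         if (nrow(mat) > 1) sd(mat[, col]) else 0)
  emis <- c("mu_act", "sigma2_act", "mu_hr", "sigma2_hr", "rho")
  rows <- lapply(emis, function(e) {
    w <- msd(paste0("wake_", e)); s <- msd(paste0("sleep_", e))
    data.frame(parameter = e, wake_mean = w[1], wake_sd = w[2],
               sleep_mean = s[1], sleep_sd = s[2])
  })
  g12 <- msd("gamma12"); g21 <- msd("gamma21")
  rows <- c(rows, list(
    data.frame(parameter = "gamma_wake_to_sleep", wake_mean = g12[1],
               wake_sd = g12[2], sleep_mean = NA, sleep_sd = NA),
    data.frame(parameter = "gamma_sleep_to_wake", wake_mean = g21[1],
               wake_sd = g21[2], sleep_mean = NA, sleep_sd = NA)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
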