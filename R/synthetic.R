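#' Participant profile for the synthetic generator
#'
#' Bundles a generating parameter set with the device-realism settings the
#' simulator needs: the heart-rate missingness process (aggregate rate and
#' mean run length of missing stretches) and the per-day probability that
#' the device was not worn.
#'
#' Defaults reflect free-living consumer-tracker recordings from older
#' adults: ~0.64% missing heart-rate minutes arriving in short runs, and
#' roughly one day in seven with the device off.
#'
#' @param params an [hmm_parameters] generating parameter set.
#' @param missing_rate target fraction of heart-rate minutes missing.
#' @param missing_run_mean mean length (minutes) of a missing run.
#' @param nonwear_prob per-day probability of a nonwear day.
#' @param n_days study length in days.
#' @return object of class `participant_profile`.
#' @export
participant_profile <- function(params, missing_rate = 0.0064,
                                missing_run_mean = 5, nonwear_prob = 0.15,
                                n_days = 90) {
  validate_hmm_parameters(params)
  stopifnot(missing_rate >= 0, missing_rate < 1, missing_run_mean >= 1,
            nonwear_prob >= 0, nonwear_prob <= 1, n_days >= 1)
  structure(list(params = params, missing_rate = missing_rate,
                 missing_run_mean = missing_run_mean,
                 nonwear_prob = nonwear_prob, n_days = n_days),
            class = "participant_profile")
}

#' Cohort prior for sampling participant profiles
#'
#' Mean and SD of each HMM parameter across a cohort of community-dwelling
#' older adults wearing a consumer tracker, used as the sampling
#' distribution by [sample_profile()]. State 1 is sleep, state 2 wake.
#'
#' @return list of `mean` and `sd` [hmm_parameters]-shaped components.
#' @export
cohort_prior <- function() {
  list(
    mean = list(mu_hr = c(66.37, 87.18), sigma2_hr = c(47.18, 241.16),
                mu_act = c(0.02, 2.24), sigma2_act = c(0.01, 1.16),
                rho = c(0.01, 0.54), gamma12 = 0.011, gamma21 = 0.017),
    sd = list(mu_hr = c(7.82, 12.52), sigma2_hr = c(36.91, 110.75),
              mu_act = c(0.07, 0.29), sigma2_act = c(0.04, 0.19),
              rho = c(0.01, 0.07), gamma12 = 0.003, gamma21 = 0.002))
}

#' Reference parameter sets for two example wearers
#'
#' Two fitted-parameter profiles typical of older-adult wearers, used
#' throughout the tests and examples: `older_adult_1` has strongly
#' separated state means (high daytime heart rate and activity);
#' `older_adult_2` has a smaller mean separation, near-zero sleep
#' activity, and a slightly lower chance of falling asleep from wake.
#'
#' @return named list of [participant_profile] objects.
#' @export
example_profiles <- function() {
  p1 <- hmm_parameters(
    pi = c(0.5, 0.5),
    Gamma = matrix(c(1 - 0.017, 0.017, 0.0097, 1 - 0.0097), 2, 2,
                   byrow = TRUE),
    mu_hr = c(74.39, 110.21), sigma2_hr = c(157.37, 213.68),
    mu_act = c(0.27, 2.98), sigma2_act = c(0.15, 0.83),
    rho = c(0.04, 0.41))
  p2 <- hmm_parameters(
    pi = c(0.5, 0.5),
    Gamma = matrix(c(1 - 0.017, 0.017, 0.0082, 1 - 0.0082), 2, 2,
                   byrow = TRUE),
    mu_hr = c(56.46, 80.17), sigma2_hr = c(58.56, 276.27),
    mu_act = c(0.005, 2.22), sigma2_act = c(0.005, 1.08),
    rho = c(0.01, 0.56))
  list(older_adult_1 = participant_profile(p1),
       older_adult_2 = participant_profile(p2))
}

#' Draw a participant profile from the cohort prior
#'
#' Each parameter is drawn from a normal distribution centred at the
#' cohort mean with the cohort SD, truncated (by rejection) to its valid
#' range: variances positive, transition probabilities in (0, 1), wake
#' correlation in (0, 1), sleep correlation in \[0, 1). Setting all SDs to
#' zero returns the cohort means exactly.
#'
#' @param config a [cohort_prior()]-shaped list.
#' @param seed integer seed; draws are deterministic given it.
#' @param ... passed to [participant_profile()].
#' @return a [participant_profile].
#' @export
sample_profile <- function(config = cohort_prior(), seed = 1, ...) {
  set.seed(as.integer(seed))
  draw <- function(m, s, lo = -Inf, hi = Inf) {
    vapply(seq_along(m), function(i) {
      if (s[i] == 0) {
        if (m[i] <= lo || m[i] >= hi)
          stop("infeasible truncation bounds for fixed value ", m[i])
        return(m[i])
      }
      for (k in 1:1000) {
        x <- rnorm(1, m[i], s[i])
        if (x > lo && x < hi) return(x)
      }
      stop("truncation bounds too tight around mean ", m[i])
    }, numeric(1))
  }
  mn <- config$mean; s <- config$sd
  mu_hr <- draw(mn$mu_hr, s$mu_hr)
  sigma2_hr <- draw(mn$sigma2_hr, s$sigma2_hr, lo = 1e-6)
  mu_act <- draw(mn$mu_act, s$mu_act)
  sigma2_act <- draw(mn$sigma2_act, s$sigma2_act, lo = 1e-6)
  rho_sleep <- draw(mn$rho[1], s$rho[1], lo = -1e-12, hi = 1)
  rho_wake <- draw(mn$rho[2], s$rho[2], lo = 0, hi = 1)
  g12 <- draw(mn$gamma12, s$gamma12, lo = 0, hi = 1)
  g21 <- draw(mn$gamma21, s$gamma21, lo = 0, hi = 1)
  params <- hmm_parameters(
    pi = c(0.5, 0.5),
    Gamma = matrix(c(1 - g21, g21, g12, 1 - g12), 2, 2, byrow = TRUE),
    mu_hr = mu_hr, sigma2_hr = sigma2_hr,
    mu_act = mu_act, sigma2_act = sigma2_act,
    rho = c(rho_sleep, rho_wake))
  participant_profile(params, ...)
}

get_params <- function(x) {
  if (inherits(x, "participant_profile")) x$params
  else if (inherits(x, "hmm_fit")) x$parameters
  else { validate_hmm_parameters(x); x }
}

#' Simulate the hidden state sequence
#'
#' First state from the initial distribution, then Markov transitions.
#'
#' @param profile a [participant_profile], `hmm_fit` or [hmm_parameters].
#' @param T_ number of minutes.
#' @param seed integer seed.
#' @return integer vector of states (1 = sleep, 2 = wake).
#' @export
simulate_states <- function(profile, T_, seed = 1) {
  p <- get_params(profile)
  stopifnot(T_ >= 1)
  set.seed(as.integer(seed))
  z <- integer(T_)
  u <- runif(T_)
  z[1] <- if (u[1] < p$pi[1]) 1L else 2L
  stay <- diag(p$Gamma)
  for (t in 2:T_) z[t] <- if (u[t] < stay[z[t - 1]]) z[t - 1] else
    (3L - z[t - 1])
  z
}

#' Simulate minute-level observations given states
#'
#' Draws (heart rate, activity) per minute from the state's emission
#' distribution: correlated bivariate normal under scheme "M1",
#' independent normals under "M2". With `truncate_act = TRUE` (the
#' default), activity draws below zero are truncated at zero, since the
#' activity level is a log step count; set it to `FALSE` to sample from
#' the exact Gaussian emission model, as parameter-recovery experiments
#' that rely on model-based standard errors should.
#'
#' @param profile a [participant_profile], `hmm_fit` or [hmm_parameters].
#' @param states integer state vector from [simulate_states()].
#' @param seed integer seed.
#' @param scheme "M1" (use the per-state correlation) or "M2".
#' @param truncate_act clamp negative activity draws at zero.
#' @return data frame with columns `hr`, `act`, `state`.
#' @export
simulate_observations <- function(profile, states, seed = 1, scheme = "M1",
                                  truncate_act = TRUE) {
  p <- get_params(profile)
  scheme <- check_scheme(scheme)
  set.seed(as.integer(seed))
  T_ <- length(states)
  e1 <- rnorm(T_); e2 <- rnorm(T_)
  rho <- if (scheme == "M1") p$rho else c(0, 0)
  r <- rho[states]
  hr <- p$mu_hr[states] + sqrt(p$sigma2_hr[states]) * e1
  act <- p$mu_act[states] +
    sqrt(p$sigma2_act[states]) * (r * e1 + sqrt(1 - r^2) * e2)
  if (truncate_act) act <- pmax(act, 0)
  data.frame(hr = hr, act = act, state = states)
}

#' Convert a simulated minute series to device export format
#'
#' Emulates what the tracker reports: heart rate rounded to integer bpm
#' every minute, and per-minute steps reconstructed as
#' `max(0, round(exp(act) - 1))` then summed into aligned 15-minute bins.
#'
#' @param sim data frame from [simulate_observations()].
#' @param start_time POSIXct (or parseable string) of the first minute;
#'   must fall on a 15-minute boundary.
#' @param tz timezone.
#' @return a `raw_recording`.
#' @export
to_device_format <- function(sim, start_time = "2018-01-01 00:00:00",
                             tz = "UTC") {
  t0 <- as.POSIXct(start_time, tz = tz)
  if (as.integer(format(t0, "%M")) %% 15L != 0L)
    stop("start_time must fall on a 15-minute boundary")
  T_ <- nrow(sim)
  if (T_ %% 15L != 0L) {
    warning("series length not a multiple of 15; dropping trailing ",
            T_ %% 15L, " minutes")
    sim <- sim[seq_len(T_ - T_ %% 15L), , drop = FALSE]
    T_ <- nrow(sim)
  }
  times <- t0 + 60 * (seq_len(T_) - 1)
  # trackers only report physiologically plausible bpm
  hr <- data.frame(time = times, bpm = pmin(pmax(round(sim$hr), 21), 249))
  step_min <- pmax(0, round(exp(sim$act) - 1))
  bin <- rep(seq_len(T_ / 15L), each = 15L)
  steps15 <- data.frame(
    time = t0 + 900 * (seq_len(T_ / 15L) - 1),
    steps = as.numeric(tapply(step_min, bin, sum)))
  raw_recording(hr = hr, steps15 = steps15, participant_id = "synthetic")
}

#' Inject heart-rate missingness and nonwear days
#'
#' Deletes heart-rate minutes in geometric-length runs until the realized
#' missing fraction is within 0.1 percentage points of the target, and
#' converts randomly chosen whole days to nonwear (steps zeroed, heart
#' rate deleted).
#'
#' @param rec a `raw_recording`.
#' @param missing_rate target missing fraction of heart-rate minutes.
#' @param missing_run_mean mean run length of a missing stretch.
#' @param nonwear_prob per-day probability of a nonwear day.
#' @param seed integer seed.
#' @return the modified `raw_recording`, with attribute `nonwear_days`
#'   (the dates converted).
#' @export
inject_missingness <- function(rec, missing_rate = 0.0064,
                               missing_run_mean = 5, nonwear_prob = 0,
                               seed = 1) {
  stopifnot(inherits(rec, "raw_recording"))
  if (missing_rate >= 1) stop("target missing rate must be below 1")
  set.seed(as.integer(seed))
  tz <- attr(rec$hr$time, "tzone") %||% "UTC"
  n <- nrow(rec$hr)
  drop <- rep(FALSE, n)
  if (missing_rate > 0) {
    target <- missing_rate * n
    while (sum(drop) < target - 0.001 * n) {
      len <- 1L + rgeom(1, 1 / missing_run_mean)
      at <- sample.int(n, 1)
      drop[at:min(n, at + len - 1L)] <- TRUE
    }
  }
  nonwear_days <- as.Date(character(0))
  if (nonwear_prob > 0) {
    days <- unique(as.Date(rec$hr$time, tz = tz))
    sel <- runif(length(days)) < nonwear_prob
    nonwear_days <- days[sel]
    if (length(nonwear_days)) {
      drop <- drop | as.Date(rec$hr$time, tz = tz) %in% nonwear_days
      zero <- as.Date(rec$steps15$time, tz = tz) %in% nonwear_days
      rec$steps15$steps[zero] <- 0
    }
  }
  rec$hr <- rec$hr[!drop, , drop = FALSE]
  attr(rec, "nonwear_days") <- nonwear_days
  rec
}

#' Simulate a full device-format recording
#'
#' End-to-end generator: hidden states, emissions, device rounding and
#' binning, heart-rate missingness and nonwear days. The truth states are
#' returned alongside so decoded labels can be checked minute by minute.
#'
#' @param profile a [participant_profile].
#' @param seed integer seed (sub-seeds are derived for each stage).
#' @param start_time first minute of the recording (15-minute boundary).
#' @param tz timezone.
#' @return list with `recording` (a `raw_recording`), `truth` (data frame
#'   `time`, `state`, `label`) and `profile`.
#' @export
simulate_recording <- function(profile, seed = 1,
                               start_time = "2018-01-01 00:00:00",
                               tz = "UTC") {
  stopifnot(inherits(profile, "participant_profile"))
  T_ <- profile$n_days * 1440L
  z <- simulate_states(profile, T_, seed = seed)
  sim <- simulate_observations(profile, z, seed = seed + 1L)
  rec <- to_device_format(sim, start_time = start_time, tz = tz)
  rec <- inject_missingness(rec, missing_rate = profile$missing_rate,
                            missing_run_mean = profile$missing_run_mean,
                            nonwear_prob = profile$nonwear_prob,
                            seed = seed + 2L)
  truth <- data.frame(time = as.POSIXct(start_time, tz = tz) +
                        60 * (seq_len(T_) - 1),
                      state = z,
                      label = c("sleep", "wake")[z])
  list(recording = rec, truth = truth, profile = profile)
}
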