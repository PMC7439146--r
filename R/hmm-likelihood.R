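#' State-conditional log emission densities
#'
#' Builds the T x 2 matrix of log emission densities used by the forward,
#' backward and Viterbi recursions, applying the missing-data likelihood
#' rule: a minute with both channels missing contributes density 1 (log
#' density 0) in every state; a minute with one channel missing
#' contributes the observed channel's marginal normal density. The
#' univariate schemes use their single channel only and ignore the other
#' entirely.
#'
#' @param params an [hmm_parameters] object.
#' @param scheme emission scheme, see [count_free_parameters()].
#' @param hr,act numeric vectors of equal length; `NA` marks missing.
#' @return T x 2 matrix of log densities.
#' @export
emission_logdens <- function(params, scheme, hr, act) {
  scheme <- check_scheme(scheme)
  validate_hmm_parameters(params)
  if (length(hr) != length(act))
    stop("hr and act must have equal length")
  if (any(is.infinite(hr)) || any(is.infinite(act)) ||
      any(is.nan(hr)) || any(is.nan(act)))
    stop("non-finite observation values (use NA for missing)")
  T_ <- length(hr)
  if (scheme == "HR_ONLY") act <- rep(NA_real_, T_)
  if (scheme == "ACT_ONLY") hr <- rep(NA_real_, T_)

  ld <- matrix(0, T_, 2)
  hr_obs <- !is.na(hr)
  act_obs <- !is.na(act)
  for (i in 1:2) {
    out <- numeric(T_)
    lh <- rep(0, T_); la <- rep(0, T_)
    lh[hr_obs] <- dnorm(hr[hr_obs], params$mu_hr[i],
                        sqrt(params$sigma2_hr[i]), log = TRUE)
    la[act_obs] <- dnorm(act[act_obs], params$mu_act[i],
                         sqrt(params$sigma2_act[i]), log = TRUE)
    if (scheme == "M1" && params$rho[i] != 0) {
      both <- hr_obs & act_obs
      out <- lh + la  # covers one-channel-missing minutes (marginals)
      if (any(both)) {
        r <- params$rho[i]
        z1 <- (hr[both] - params$mu_hr[i]) / sqrt(params$sigma2_hr[i])
        z2 <- (act[both] - params$mu_act[i]) / sqrt(params$sigma2_act[i])
        out[both] <- -log(2 * pi) -
          0.5 * log(params$sigma2_hr[i] * params$sigma2_act[i] * (1 - r^2)) -
          (z1^2 - 2 * r * z1 * z2 + z2^2) / (2 * (1 - r^2))
      }
    } else {
      out <- lh + la  # zero-correlation joint density factorizes
    }
    ld[, i] <- out
  }
  ld
}

extract_channels <- function(series) {
  if (is.list(series) && !is.data.frame(series))
    series <- as.data.frame(series)
  if (!all(c("hr", "act") %in% names(series)))
    stop("series must contain columns `hr` and `act`")
  list(hr = as.numeric(series$hr), act = as.numeric(series$act))
}

#' Forward-algorithm log likelihood
#'
#' Evaluates the HMM log likelihood, the log of the sum over all hidden
#' state paths of initial x emission x transition probabilities, by a
#' log-space forward recursion. Numerically stable for series of 1e5+
#' minutes.
#'
#' @param params an [hmm_parameters] object.
#' @param scheme emission scheme.
#' @param series a data frame with columns `hr` and `act` (an
#'   [epoch_series] works), `NA` marking missing values.
#' @return the log likelihood (scalar).
#' @export
forward_loglik <- function(params, scheme, series) {
  ch <- extract_channels(series)
  if (length(ch$hr) == 0L) stop("series is empty")
  ld <- emission_logdens(params, scheme, ch$hr, ch$act)
  forward_cpp(ld, params$pi, params$Gamma)
}

#' Most probable hidden-state path (Viterbi)
#'
#' Finds the state sequence maximizing the conditional probability of the
#' whole path given all observations, using a log-space dynamic program.
#' Missing minutes use the missing-data emission rule, so the path is
#' defined at every minute. Ties are broken toward the lower state index.
#'
#' @inheritParams forward_loglik
#' @param posterior if `TRUE`, also compute smoothed per-minute state
#'   probabilities (forward-backward).
#' @return an object of class `state_path`: list with `states` (integer
#'   vector, 1 = lower-heart-rate state), and optionally `posterior`
#'   (T x 2 matrix).
#' @export
viterbi_decode <- function(params, scheme, series, posterior = FALSE) {
  if (inherits(params, "hmm_fit")) {
    if (missing(series)) series <- scheme
    scheme <- params$scheme
    params <- params$parameters
  }
  ch <- extract_channels(series)
  if (length(ch$hr) == 0L) stop("series is empty")
  ld <- emission_logdens(params, scheme, ch$hr, ch$act)
  st <- viterbi_cpp(ld, log(params$pi), log(params$Gamma))
  out <- list(states = st)
  if (posterior) {
    fb <- fb_cpp(ld, params$pi, params$Gamma)
    out$posterior <- fb$gamma
  }
  structure(out, class = "state_path")
}

#' Ordinary normal pseudo-residuals
#'
#' Goodness-of-fit diagnostic: for each observed channel value, the model's
#' conditional mixture CDF given all *other* observations is evaluated at
#' the value and mapped through the standard-normal quantile function. If
#' the data were generated by the fitted model, the pseudo-residuals are
#' standard normal; heavy tails or skew in their QQ plot flag emission
#' misfit. Residuals are computed per channel because the probability
#' integral transform is scalar.
#'
#' @inheritParams forward_loglik
#' @return object of class `pseudo_residuals`: data frame with columns
#'   `hr` and `act` (NA where the channel is missing), with attributes
#'   `n_clipped` (CDF values clipped away from 0/1 at eps = 1e-12) and
#'   `ks` (Kolmogorov-Smirnov statistics against the standard normal).
#' @export
pseudo_residuals <- function(params, scheme, series) {
  if (inherits(params, "hmm_fit")) {
    if (missing(series)) series <- scheme
    scheme <- params$scheme
    params <- params$parameters
  }
  scheme <- check_scheme(scheme)
  ch <- extract_channels(series)
  ld <- emission_logdens(params, scheme, ch$hr, ch$act)
  fb <- fb_cpp(ld, params$pi, params$Gamma, want_log_ab = TRUE)
  # P(state i at t | all observations except x_t): drop minute t's own
  # emission from the smoothing weights.
  lw <- fb$log_alpha - ld + fb$log_beta
  w <- exp(lw - apply(lw, 1, max))
  w <- w / rowSums(w)

  eps <- 1e-12
  n_clipped <- 0L
  mix_resid <- function(x, mu, s2) {
    u <- rep(NA_real_, length(x))
    obs <- !is.na(x)
    if (!any(obs)) return(list(u = u, clipped = 0L))
    Fx <- w[obs, 1] * pnorm(x[obs], mu[1], sqrt(s2[1])) +
          w[obs, 2] * pnorm(x[obs], mu[2], sqrt(s2[2]))
    clipped <- sum(Fx < eps | Fx > 1 - eps)
    Fx <- pmin(pmax(Fx, eps), 1 - eps)
    u[obs] <- qnorm(Fx)
    list(u = u, clipped = clipped)
  }

  out <- data.frame(hr = NA_real_, act = NA_real_,
                    row.names = NULL)[rep(1, length(ch$hr)), , drop = FALSE]
  rownames(out) <- NULL
  ks <- c(hr = NA_real_, act = NA_real_)
  if (scheme != "ACT_ONLY") {
    r <- mix_resid(ch$hr, params$mu_hr, params$sigma2_hr)
    out$hr <- r$u; n_clipped <- n_clipped + r$clipped
    if (sum(!is.na(r$u)) > 1)
      ks["hr"] <- suppressWarnings(ks.test(r$u[!is.na(r$u)], "pnorm"))$statistic
  }
  if (scheme != "HR_ONLY") {
    r <- mix_resid(ch$act, params$mu_act, params$sigma2_act)
    out$act <- r$u; n_clipped <- n_clipped + r$clipped
    if (sum(!is.na(r$u)) > 1)
      ks["act"] <- suppressWarnings(ks.test(r$u[!is.na(r$u)], "pnorm"))$statistic
  }
  structure(out, n_clipped = n_clipped, ks = ks,
            class = c("pseudo_residuals", "data.frame"))
}
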