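#' Two-state HMM parameter set
#'
#' Container for the parameters of the two-state sleep/wake hidden Markov
#' model: initial distribution, transition matrix and per-state Gaussian
#' emission parameters for the heart-rate channel (bpm) and the activity
#' channel (log of 1-minute steps + 1). The per-state correlation `rho`
#' couples the two channels under the joint bivariate-normal emission
#' scheme ("M1"); it is ignored (fixed at 0) under conditional
#' independence ("M2") and under the univariate schemes.
#'
#' States are indexed 1 and 2. Throughout the package the canonical order
#' after fitting is ascending mean heart rate, so state 1 is the resting
#' (sleep) state and state 2 the active (wake) state.
#'
#' @param pi length-2 initial state distribution (sums to 1).
#' @param Gamma 2x2 transition probability matrix, rows summing to 1;
#'   `Gamma[i, j]` is P(state j at t+1 | state i at t).
#' @param mu_hr,sigma2_hr per-state mean and variance of heart rate (bpm,
#'   bpm^2).
#' @param mu_act,sigma2_act per-state mean and variance of activity level.
#' @param rho per-state heart-rate/activity correlation, in (-1, 1).
#' @return an object of class `hmm_parameters`.
#' @export
hmm_parameters <- function(pi, Gamma, mu_hr, sigma2_hr, mu_act, sigma2_act,
                           rho = c(0, 0)) {
  p <- structure(
    list(pi = as.numeric(pi), Gamma = matrix(as.numeric(Gamma), 2, 2),
         mu_hr = as.numeric(mu_hr), sigma2_hr = as.numeric(sigma2_hr),
         mu_act = as.numeric(mu_act), sigma2_act = as.numeric(sigma2_act),
         rho = as.numeric(rho)),
    class = "hmm_parameters")
  validate_hmm_parameters(p)
  p
}

validate_hmm_parameters <- function(p) {
  stopifnot(inherits(p, "hmm_parameters"))
  if (length(p$pi) != 2L || any(p$pi < 0) || abs(sum(p$pi) - 1) > 1e-8)
    stop("`pi` must be a length-2 probability vector summing to 1")
  if (any(p$Gamma < 0) || any(abs(rowSums(p$Gamma) - 1) > 1e-8))
    stop("`Gamma` rows must be probability vectors summing to 1")
  for (nm in c("mu_hr", "sigma2_hr", "mu_act", "sigma2_act", "rho"))
    if (length(p[[nm]]) != 2L || any(!is.finite(p[[nm]])))
      stop("`", nm, "` must be a finite length-2 vector")
  if (any(p$sigma2_hr <= 0) || any(p$sigma2_act <= 0))
    stop("emission variances must be positive")
  if (any(abs(p$rho) >= 1))
    stop("`rho` must lie in (-1, 1)")
  invisible(p)
}

#' @export
print.hmm_parameters <- function(x, ...) {
  cat("Two-state HMM parameters\n")
  cat("  pi:    ", sprintf("%.4f", x$pi), "\n")
  cat("  Gamma: ", sprintf("%.4f", x$Gamma[1, ]), "\n")
  cat("         ", sprintf("%.4f", x$Gamma[2, ]), "\n")
  tab <- rbind(mu_hr = x$mu_hr, sigma2_hr = x$sigma2_hr,
               mu_act = x$mu_act, sigma2_act = x$sigma2_act, rho = x$rho)
  colnames(tab) <- c("state1", "state2")
  print(round(tab, 4))
  invisible(x)
}

.schemes <- c("M1", "M2", "HR_ONLY", "ACT_ONLY")

check_scheme <- function(scheme) {
  scheme <- toupper(scheme)
  if (!scheme %in% .schemes)
    stop("unknown model scheme: ", scheme,
         " (expected one of ", paste(.schemes, collapse = ", "), ")")
  scheme
}

#' Free-parameter count of an emission scheme
#'
#' Two states always contribute 2 free transition probabilities (one per
#' row of the transition matrix) and 1 free initial probability. Emission
#' parameters per state: 5 under the joint bivariate-normal scheme
#' ("M1": two means, two variances, one correlation), 4 under conditional
#' independence ("M2"), 2 for the univariate single-channel models.
#' Hence df(M1) = 13, df(M2) = 11, df(HR_ONLY) = df(ACT_ONLY) = 7.
#'
#' @param scheme one of "M1", "M2", "HR_ONLY", "ACT_ONLY".
#' @return integer free-parameter count.
#' @export
count_free_parameters <- function(scheme) {
  scheme <- check_scheme(scheme)
  emis <- switch(scheme, M1 = 5L, M2 = 4L, HR_ONLY = 2L, ACT_ONLY = 2L)
  2L * emis + 2L + 1L
}

#' Akaike and Bayesian information criteria
#'
#' @param log_likelihood maximized log likelihood.
#' @param df free-parameter count.
#' @param T_effective number of observations entering the likelihood.
#' @return named numeric vector `c(AIC, BIC)` with
#'   AIC = -2 log L + 2 df and BIC = -2 log L + df log T.
#' @export
information_criteria <- function(log_likelihood, df, T_effective) {
  stopifnot(T_effective >= 1, df >= 0)
  c(AIC = -2 * log_likelihood + 2 * df,
    BIC = -2 * log_likelihood + df * log(T_effective))
}
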