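.var_floor <- 1e-6
.rho_max <- 0.999
.prob_floor <- 1e-12

#' Fit a two-state sleep/wake HMM by Baum-Welch EM
#'
#' Maximum-likelihood estimation of the two-state hidden Markov model over
#' the minute-level (heart rate, activity) series. The E-step uses the
#' scaled forward-backward recursions with the missing-data likelihood
#' (fully missing minutes contribute density 1; one-channel-missing
#' minutes contribute the observed channel's marginal). The M-step uses
#' closed-form Gaussian updates; partially missing bivariate observations
#' enter through their exact conditional moments, so the log likelihood is
#' non-decreasing across iterations.
#'
#' The first restart is initialized deterministically by splitting minutes
#' at the median of the activity level (heart rate for the `HR_ONLY`
#' scheme) and computing moments in the two halves; further restarts
#' perturb the initial state means by a 0.5-SD Gaussian jitter. The best
#' restart by final log likelihood is returned. After fitting, states are
#' reordered so state 1 has the lower mean heart rate (lower mean activity
#' for `ACT_ONLY`); with the usual physiology state 1 is sleep/rest and
#' state 2 wake.
#'
#' @param series data frame with numeric columns `hr` and `act`
#'   (an [epoch_series] works); `NA` marks missing values.
#' @param scheme "M1" (joint bivariate normal), "M2" (conditional
#'   independence), "HR_ONLY" or "ACT_ONLY".
#' @param n_restarts number of EM starts (default 5).
#' @param seed integer seed controlling restart jitter.
#' @param tol relative log-likelihood change declaring convergence.
#' @param max_iter maximum EM iterations per restart.
#' @param init optional [hmm_parameters] used as an additional first
#'   initialization (e.g. a participant-level fit when refitting single
#'   days).
#' @return an object of class `hmm_fit`: list with `parameters`
#'   ([hmm_parameters]), `scheme`, `log_likelihood`, `df`, `AIC`, `BIC`,
#'   `T_effective`, `iterations`, `converged`, `occupancy` (posterior
#'   minutes per state) and `restart_log` (per-restart summary).
#' @export
fit_hmm <- function(series, scheme = "M1", n_restarts = 5, seed = 1,
                    tol = 1e-8, max_iter = 500, init = NULL) {
  scheme <- check_scheme(scheme)
  ch <- extract_channels(series)
  hr <- ch$hr; act <- ch$act
  if (scheme == "HR_ONLY") act <- rep(NA_real_, length(hr))
  if (scheme == "ACT_ONLY") hr <- rep(NA_real_, length(act))
  n_obs <- sum(!is.na(hr) | !is.na(act))
  if (n_obs < 100)
    stop("need at least 100 non-missing minutes to fit (got ", n_obs, ")")

  set.seed(as.integer(seed))
  inits <- list(init_median_split(hr, act, scheme))
  if (!is.null(init)) inits <- c(list(init), inits)
  while (length(inits) < n_restarts) {
    p <- inits[[1 + (!is.null(init))]]
    sd_hr <- sqrt(mean(p$sigma2_hr)); sd_act <- sqrt(mean(p$sigma2_act))
    q <- p
    q$mu_hr <- p$mu_hr + rnorm(2, 0, 0.5 * sd_hr)
    q$mu_act <- p$mu_act + rnorm(2, 0, 0.5 * sd_act)
    inits <- c(inits, list(q))
  }
  inits <- inits[seq_len(max(n_restarts, length(inits)))]

  best <- NULL
  restart_log <- vector("list", length(inits))
  for (r in seq_along(inits)) {
    run <- em_run(hr, act, scheme, inits[[r]], tol, max_iter)
    restart_log[[r]] <- list(restart = r, log_likelihood = run$loglik,
                             iterations = run$iterations,
                             converged = run$converged,
                             min_occupancy_share = min(run$occupancy) /
                               length(hr),
                             monotone_violations = run$monotone_violations)
    if (min(run$occupancy) / length(hr) < 0.001)
      restart_log[[r]]$degenerate <- TRUE
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }

  if (!best$converged)
    warning("EM did not converge within ", max_iter, " iterations")

  # canonical state order: ascending mean of the labeling channel
  key <- if (scheme == "ACT_ONLY") best$params$mu_act else best$params$mu_hr
  ord <- order(key)
  best$params <- permute_states(best$params, ord)
  best$occupancy <- best$occupancy[ord]

  df <- count_free_parameters(scheme)
  ic <- information_criteria(best$loglik, df, n_obs)
  structure(list(parameters = best$params, scheme = scheme,
                 log_likelihood = best$loglik, df = df,
                 AIC = unname(ic["AIC"]), BIC = unname(ic["BIC"]),
                 T_effective = n_obs, iterations = best$iterations,
                 converged = best$converged, occupancy = best$occupancy,
                 loglik_trace = best$trace, restart_log = restart_log),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat("Two-state sleep/wake HMM fit (scheme ", x$scheme, ")\n", sep = "")
  cat(sprintf("  log L = %.1f  df = %d  AIC = %.1f  BIC = %.1f  T = %d\n",
              x$log_likelihood, x$df, x$AIC, x$BIC, x$T_effective))
  cat(sprintf("  %d iterations, converged: %s\n", x$iterations, x$converged))
  print(x$parameters)
  invisible(x)
}

permute_states <- function(p, ord) {
  p$pi <- p$pi[ord]
  p$Gamma <- p$Gamma[ord, ord, drop = FALSE]
  for (nm in c("mu_hr", "sigma2_hr", "mu_act", "sigma2_act", "rho"))
    p[[nm]] <- p[[nm]][ord]
  p
}

init_median_split <- function(hr, act, scheme) {
  v <- if (scheme == "HR_ONLY") hr else act
  v_obs <- v[!is.na(v)]
  thr <- median(v_obs)
  low <- !is.na(v) & v <= thr
  high <- !is.na(v) & v > thr
  if (sum(high) < 10 || sum(low) < 10) {
    thr <- mean(v_obs)
    low <- !is.na(v) & v <= thr
    high <- !is.na(v) & v > thr
  }
  grp <- function(x, sel, fallback_shift) {
    xo <- x[sel & !is.na(x)]
    if (length(xo) >= 2) c(mean(xo), max(var(xo), .var_floor))
    else {
      all_o <- x[!is.na(x)]
      if (length(all_o) < 2) c(0, 1)
      else c(mean(all_o) + fallback_shift * sd(all_o), max(var(all_o), .var_floor))
    }
  }
  h1 <- grp(hr, low, -0.5); h2 <- grp(hr, high, 0.5)
  a1 <- grp(act, low, -0.5); a2 <- grp(act, high, 0.5)
  rho <- c(0, 0)
  if (scheme == "M1") {
    for (i in 1:2) {
      sel <- if (i == 1) low else high
      cc <- sel & !is.na(hr) & !is.na(act)
      if (sum(cc) >= 3) {
        r <- suppressWarnings(cor(hr[cc], act[cc]))
        if (is.finite(r)) rho[i] <- max(min(r, 0.9), -0.9)
      }
    }
  }
  hmm_parameters(pi = c(0.5, 0.5),
                 Gamma = matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2, byrow = TRUE),
                 mu_hr = c(h1[1], h2[1]), sigma2_hr = c(h1[2], h2[2]),
                 mu_act = c(a1[1], a2[1]), sigma2_act = c(a1[2], a2[2]),
                 rho = rho)
}

em_run <- function(hr, act, scheme, params, tol, max_iter) {
  hr_obs <- !is.na(hr); act_obs <- !is.na(act)
  bo <- hr_obs & act_obs; ho <- hr_obs & !act_obs; ao <- !hr_obs & act_obs
  no <- !hr_obs & !act_obs
  T_ <- length(hr)

  trace <- numeric(0)
  converged <- FALSE
  monotone_violations <- 0L
  ll_prev <- -Inf
  occupancy <- c(NA_real_, NA_real_)
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    ld <- emission_logdens(params, scheme, hr, act)
    fb <- fb_cpp(ld, params$pi, params$Gamma)
    ll <- fb$loglik
    trace <- c(trace, ll)
    if (ll < ll_prev - 1e-8 * (1 + abs(ll_prev)))
      monotone_violations <- monotone_violations + 1L
    occupancy <- colSums(fb$gamma)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < tol * (abs(ll_prev) + 1e-3)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    params <- m_step(params, scheme, fb, hr, act, bo, ho, ao, no)
  }
  # report the likelihood at the returned parameters
  ll_final <- forward_cpp(emission_logdens(params, scheme, hr, act),
                          params$pi, params$Gamma)
  list(params = params, loglik = ll_final, iterations = it,
       converged = converged, occupancy = occupancy, trace = trace,
       monotone_violations = monotone_violations)
}

m_step <- function(params, scheme, fb, hr, act, bo, ho, ao, no) {
  g <- fb$gamma
  new <- params
  for (i in 1:2) {
    gi <- g[, i]
    N <- sum(gi)
    m1 <- params$mu_hr[i]; v1 <- params$sigma2_hr[i]
    m2 <- params$mu_act[i]; v2 <- params$sigma2_act[i]
    r <- if (scheme == "M1") params$rho[i] else 0

    E1 <- E11 <- E2 <- E22 <- E12 <- numeric(length(hr))
    hob <- bo | ho; aob <- bo | ao
    E1[hob] <- hr[hob]; E11[hob] <- hr[hob]^2
    E2[aob] <- act[aob]; E22[aob] <- act[aob]^2
    E12[bo] <- hr[bo] * act[bo]
    if (any(ao)) {  # heart rate missing: conditional moments given activity
      cm <- m1 + r * sqrt(v1 / v2) * (act[ao] - m2)
      E1[ao] <- cm; E11[ao] <- cm^2 + v1 * (1 - r^2); E12[ao] <- cm * act[ao]
    }
    if (any(ho)) {  # activity missing
      cm <- m2 + r * sqrt(v2 / v1) * (hr[ho] - m1)
      E2[ho] <- cm; E22[ho] <- cm^2 + v2 * (1 - r^2); E12[ho] <- hr[ho] * cm
    }
    if (any(no)) {  # fully missing: prior moments
      E1[no] <- m1; E11[no] <- m1^2 + v1
      E2[no] <- m2; E22[no] <- m2^2 + v2
      E12[no] <- r * sqrt(v1 * v2) + m1 * m2
    }

    mu1 <- sum(gi * E1) / N; mu2 <- sum(gi * E2) / N
    V11 <- max(sum(gi * E11) / N - mu1^2, .var_floor)
    V22 <- max(sum(gi * E22) / N - mu2^2, .var_floor)
    V12 <- sum(gi * E12) / N - mu1 * mu2

    new$mu_hr[i] <- mu1; new$sigma2_hr[i] <- V11
    new$mu_act[i] <- mu2; new$sigma2_act[i] <- V22
    new$rho[i] <- if (scheme == "M1")
      max(min(V12 / sqrt(V11 * V22), .rho_max), -.rho_max) else 0
  }

  Gn <- fb$xi_sum
  rs <- rowSums(Gn)
  for (i in 1:2) {
    if (rs[i] > 0) Gn[i, ] <- Gn[i, ] / rs[i] else Gn[i, ] <- params$Gamma[i, ]
  }
  Gn <- pmax(Gn, .prob_floor)
  Gn <- Gn / rowSums(Gn)
  pin <- pmax(g[1, ], .prob_floor)
  new$Gamma <- Gn
  new$pi <- pin / sum(pin)
  new
}

#' Select among fitted models by information criterion
#'
#' Compares fits of different emission schemes on the same series and
#' returns the winner by AIC (the default) or BIC. When the two criteria
#' disagree, both rankings are reported via a message and attached as the
#' `rankings` attribute. Ties are broken toward fewer free parameters.
#'
#' @param fits list of `hmm_fit` objects on the same series.
#' @param prefer "AIC" or "BIC".
#' @return the selected `hmm_fit`, with attribute `rankings`.
#' @export
select_model <- function(fits, prefer = c("AIC", "BIC")) {
  prefer <- match.arg(prefer)
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "hmm_fit")))
  if (length(fits) == 1L) return(fits[[1]])
  Ts <- vapply(fits, function(f) f$T_effective, numeric(1))
  if (length(unique(Ts)) != 1L)
    stop("fits were computed on series of different lengths")
  aic <- vapply(fits, function(f) f$AIC, numeric(1))
  bic <- vapply(fits, function(f) f$BIC, numeric(1))
  df <- vapply(fits, function(f) f$df, numeric(1))
  pick <- function(crit) order(crit, df)[1]  # parsimony tie-break
  i_aic <- pick(aic); i_bic <- pick(bic)
  if (i_aic != i_bic)
    message("AIC and BIC disagree (AIC -> ", fits[[i_aic]]$scheme,
            ", BIC -> ", fits[[i_bic]]$scheme, "); using ", prefer)
  chosen <- fits[[if (prefer == "AIC") i_aic else i_bic]]
  attr(chosen, "rankings") <- data.frame(
    scheme = vapply(fits, function(f) f$scheme, character(1)),
    df = df, AIC = aic, BIC = bic)
  chosen
}
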