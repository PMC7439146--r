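# Independent brute-force oracles for the HMM recursions, written without
# reference to the package's forward/Viterbi code paths: densities are
# recomputed from the closed-form normal formulas and the likelihood is an
# explicit sum over all 2^T state paths.

oracle_density <- function(p, scheme, hr_t, act_t, state) {
  d1 <- function(x, mu, s2) exp(-(x - mu)^2 / (2 * s2)) / sqrt(2 * pi * s2)
  if (scheme == "HR_ONLY") act_t <- NA_real_
  if (scheme == "ACT_ONLY") hr_t <- NA_real_
  if (is.na(hr_t) && is.na(act_t)) return(1)
  if (is.na(act_t)) return(d1(hr_t, p$mu_hr[state], p$sigma2_hr[state]))
  if (is.na(hr_t)) return(d1(act_t, p$mu_act[state], p$sigma2_act[state]))
  if (scheme == "M1") {
    r <- p$rho[state]
    s1 <- sqrt(p$sigma2_hr[state]); s2 <- sqrt(p$sigma2_act[state])
    z1 <- (hr_t - p$mu_hr[state]) / s1
    z2 <- (act_t - p$mu_act[state]) / s2
    q <- (z1^2 - 2 * r * z1 * z2 + z2^2) / (1 - r^2)
    exp(-q / 2) / (2 * pi * s1 * s2 * sqrt(1 - r^2))
  } else {
    d1(hr_t, p$mu_hr[state], p$sigma2_hr[state]) *
      d1(act_t, p$mu_act[state], p$sigma2_act[state])
  }
}

all_paths <- function(T_) {
  as.matrix(expand.grid(rep(list(1:2), T_)))[, T_:1, drop = FALSE]
}

path_logprob <- function(p, scheme, hr, act, path) {
  T_ <- length(hr)
  lp <- log(p$pi[path[1]]) +
    log(oracle_density(p, scheme, hr[1], act[1], path[1]))
  if (T_ > 1) for (t in 2:T_) {
    lp <- lp + log(p$Gamma[path[t - 1], path[t]]) +
      log(oracle_density(p, scheme, hr[t], act[t], path[t]))
  }
  lp
}

brute_loglik <- function(p, scheme, hr, act) {
  paths <- all_paths(length(hr))
  lps <- apply(paths, 1, function(pt) path_logprob(p, scheme, hr, act, pt))
  m <- max(lps)
  m + log(sum(exp(lps - m)))
}

# all state paths attaining the maximum joint probability (within tol)
brute_viterbi_set <- function(p, scheme, hr, act, tol = 1e-9) {
  paths <- all_paths(length(hr))
  lps <- apply(paths, 1, function(pt) path_logprob(p, scheme, hr, act, pt))
  paths[lps >= max(lps) - tol, , drop = FALSE]
}

random_params <- function(allow_rho = TRUE) {
  g <- matrix(runif(4, 0.05, 0.95), 2, 2)
  g <- g / rowSums(g)
  pi <- runif(2, 0.05, 0.95)
  hmm_parameters(pi = pi / sum(pi), Gamma = g,
                 mu_hr = sort(runif(2, 50, 120)),
                 sigma2_hr = runif(2, 20, 300),
                 mu_act = sort(runif(2, 0, 3)),
                 sigma2_act = runif(2, 0.05, 1.5),
                 rho = if (allow_rho) runif(2, -0.8, 0.8) else c(0, 0))
}

# random observation pair with missingness
random_obs <- function(T_, miss_prob = 0.2) {
  hr <- rnorm(T_, 80, 15)
  act <- abs(rnorm(T_, 1.5, 1))
  hr[runif(T_) < miss_prob] <- NA
  act[runif(T_) < miss_prob] <- NA
  list(hr = hr, act = act)
}

# a minimal device recording spanning full calendar days
make_recording <- function(n_days = 3, tz = "UTC",
                           start = "2018-01-01 00:00:00",
                           hr_value = 70, steps_per_bin = 20) {
  t0 <- as.POSIXct(start, tz = tz)
  T_ <- n_days * 1440L
  hr <- data.frame(time = t0 + 60 * (seq_len(T_) - 1),
                   bpm = rep(hr_value, T_))
  nb <- T_ / 15L
  steps <- data.frame(time = t0 + 900 * (seq_len(nb) - 1),
                      steps = rep(steps_per_bin, nb))
  raw_recording(hr = hr, steps15 = steps, participant_id = "test")
}
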