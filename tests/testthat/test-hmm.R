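test_that("free-parameter counting follows the scheme", {
  expect_identical(count_free_parameters("M1"), 13L)
  expect_identical(count_free_parameters("M2"), 11L)
  expect_identical(count_free_parameters("HR_ONLY"), 7L)
  expect_identical(count_free_parameters("ACT_ONLY"), 7L)
  expect_error(count_free_parameters("M3"), "unknown")
})

test_that("information criteria arithmetic", {
  expect_equal(unname(information_criteria(0, 0, 10)), c(0, 0))
  ic <- information_criteria(-100, 5, 1000)
  expect_equal(unname(ic["AIC"]), 210)
  expect_equal(unname(ic["BIC"]), 200 + 5 * log(1000))
})

test_that("emission densities: factorization, missingness, known values", {
  p <- hmm_parameters(pi = c(.5, .5), Gamma = matrix(.5, 2, 2),
                      mu_hr = c(60, 100), sigma2_hr = c(25, 100),
                      mu_act = c(0.2, 2), sigma2_act = c(0.1, 1),
                      rho = c(0, 0))
  hr <- c(70, NA, 80, NA)
  act <- c(1, 0.5, NA, NA)
  expect_equal(emission_logdens(p, "M1", hr, act),
               emission_logdens(p, "M2", hr, act))
  ld <- emission_logdens(p, "M2", hr, act)
  expect_equal(ld[4, ], c(0, 0))             # both missing -> density 1
  # one channel missing -> marginal of the observed channel
  expect_equal(ld[2, 1], dnorm(0.5, 0.2, sqrt(0.1), log = TRUE))
  expect_equal(ld[3, 2], dnorm(80, 100, 10, log = TRUE))
  # at the state mean with unit variances and rho = 0: log(1/(2*pi))
  q <- hmm_parameters(pi = c(.5, .5), Gamma = matrix(.5, 2, 2),
                      mu_hr = c(60, 100), sigma2_hr = c(1, 1),
                      mu_act = c(0, 2), sigma2_act = c(1, 1))
  expect_equal(emission_logdens(q, "M1", 60, 0)[1, 1], log(1 / (2 * pi)))
  expect_error(emission_logdens(p, "M1", Inf, 1), "non-finite")
})

test_that("correlated bivariate emission matches the closed-form oracle", {
  set.seed(11)
  for (k in 1:20) {
    p <- random_params()
    hr <- rnorm(1, 80, 20); act <- rnorm(1, 1.5, 1)
    ld <- emission_logdens(p, "M1", hr, act)
    for (i in 1:2)
      expect_equal(ld[1, i], log(oracle_density(p, "M1", hr, act, i)),
                   tolerance = 1e-12)
  }
})

test_that("forward log likelihood: degenerate cases", {
  p <- random_params()
  # all-missing observations: only transition/initial mass remains
  s <- data.frame(hr = rep(NA_real_, 3), act = rep(NA_real_, 3))
  expect_equal(forward_loglik(p, "M1", s), 0, tolerance = 1e-12)
  # T = 1 closed form
  s1 <- data.frame(hr = 75, act = 1.2)
  manual <- log(p$pi[1] * oracle_density(p, "M1", 75, 1.2, 1) +
                p$pi[2] * oracle_density(p, "M1", 75, 1.2, 2))
  expect_equal(forward_loglik(p, "M1", s1), manual, tolerance = 1e-12)
})

test_that("forward likelihood and Viterbi agree with 2^T enumeration", {
  set.seed(21)
  for (k in 1:40) {
    T_ <- sample(2:8, 1)
    scheme <- sample(c("M1", "M2", "HR_ONLY", "ACT_ONLY"), 1)
    p <- random_params()
    obs <- random_obs(T_)
    s <- data.frame(hr = obs$hr, act = obs$act)
    expect_equal(forward_loglik(p, scheme, s),
                 brute_loglik(p, scheme, obs$hr, obs$act),
                 tolerance = 1e-10)
    vit <- viterbi_decode(p, scheme, s)$states
    best <- brute_viterbi_set(p, scheme, obs$hr, obs$act)
    expect_true(any(apply(best, 1, function(b) all(b == vit))))
  }
})

test_that("all-missing series decodes to the most probable Markov path", {
  p <- hmm_parameters(pi = c(0.9, 0.1),
                      Gamma = matrix(c(.8, .2, .3, .7), 2, 2, byrow = TRUE),
                      mu_hr = c(60, 100), sigma2_hr = c(25, 100),
                      mu_act = c(0, 2), sigma2_act = c(0.5, 1))
  s <- data.frame(hr = rep(NA_real_, 6), act = rep(NA_real_, 6))
  vit <- viterbi_decode(p, "M1", s)$states
  best <- brute_viterbi_set(p, "M1", s$hr, s$act)
  expect_true(any(apply(best, 1, function(b) all(b == vit))))
  expect_equal(vit, rep(1L, 6))  # staying in the likeliest start state wins
})

test_that("with strong separation Viterbi matches per-minute density argmax", {
  p <- hmm_parameters(pi = c(.5, .5),
                      Gamma = matrix(c(.95, .05, .05, .95), 2, 2),
                      mu_hr = c(60, 120), sigma2_hr = c(1, 1),
                      mu_act = c(0, 3), sigma2_act = c(0.01, 0.01))
  z <- simulate_states(p, 500, seed = 5)
  sim <- simulate_observations(p, z, seed = 6)
  vit <- viterbi_decode(p, "M1", sim)$states
  ld <- emission_logdens(p, "M1", sim$hr, sim$act)
  expect_equal(vit, as.integer(apply(ld, 1, which.max)))
  expect_gt(mean(vit == z), 0.999)
})

test_that("EM recovers well-separated states and is monotone", {
  p <- hmm_parameters(pi = c(.5, .5),
                      Gamma = matrix(c(.97, .03, .03, .97), 2, 2),
                      mu_hr = c(60, 120), sigma2_hr = c(1, 1),
                      mu_act = c(0.1, 2), sigma2_act = c(0.2, 0.5))
  z <- simulate_states(p, 4000, seed = 31)
  sim <- simulate_observations(p, z, seed = 32, truncate_act = FALSE)
  fit <- fit_hmm(sim, scheme = "M1", n_restarts = 3, seed = 1)
  expect_true(fit$converged)
  # log likelihood non-decreasing along the EM trace
  expect_true(all(diff(fit$loglik_trace) >
                  -1e-8 * (1 + abs(fit$log_likelihood))))
  # canonical order: state 1 has the lower mean heart rate
  expect_lt(fit$parameters$mu_hr[1], fit$parameters$mu_hr[2])
  expect_equal(fit$parameters$mu_hr, c(60, 120), tolerance = 0.05)
  # decoded occupancy matches generating states almost perfectly
  vit <- viterbi_decode(fit, sim)$states
  expect_gt(mean(vit == z), 0.999)
  # probability estimates stay row-stochastic and positive
  expect_true(all(fit$parameters$Gamma > 0))
  expect_equal(rowSums(fit$parameters$Gamma), c(1, 1), tolerance = 1e-12)
  expect_equal(sum(fit$parameters$pi), 1, tolerance = 1e-12)
  # FitResult invariants
  expect_equal(fit$AIC, -2 * fit$log_likelihood + 2 * 13)
  expect_equal(fit$BIC, -2 * fit$log_likelihood + 13 * log(fit$T_effective))
  expect_equal(fit$df, count_free_parameters("M1"))
})

test_that("refitting from the truth barely moves the likelihood", {
  p <- example_profiles()$older_adult_1$params
  z <- simulate_states(p, 20000, seed = 41)
  sim <- simulate_observations(p, z, seed = 42, truncate_act = FALSE)
  ll_true <- forward_loglik(p, "M1", sim)
  fit <- suppressWarnings(fit_hmm(sim, scheme = "M1", n_restarts = 1,
                                  seed = 1, init = p, max_iter = 1))
  # a single EM iteration from the truth improves by < 0.1% of |logL|
  expect_lt(abs(fit$log_likelihood - ll_true), 0.001 * abs(ll_true))
  expect_gte(fit$log_likelihood, ll_true - 1e-6)
})

test_that("EM handles missing data without fabricating likelihood", {
  p <- example_profiles()$older_adult_1$params
  z <- simulate_states(p, 8000, seed = 51)
  sim <- simulate_observations(p, z, seed = 52)
  sim$hr[sample.int(8000, 400)] <- NA   # ~5% missing heart rate
  sim$act[sample.int(8000, 100)] <- NA
  fit <- fit_hmm(sim, scheme = "M1", n_restarts = 2, seed = 2)
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_trace) >
                  -1e-8 * (1 + abs(fit$log_likelihood))))
  expect_equal(fit$parameters$mu_hr, c(74.39, 110.21), tolerance = 0.05)
  # T_effective counts minutes with at least one observed channel
  expect_equal(fit$T_effective,
               sum(!is.na(sim$hr) | !is.na(sim$act)))
})

test_that("fit_hmm input validation", {
  expect_error(fit_hmm(data.frame(hr = rnorm(50), act = rnorm(50))),
               "at least 100")
  expect_error(fit_hmm(data.frame(hr = rnorm(200), act = rnorm(200)),
                       scheme = "bogus"), "unknown")
})

test_that("model selection by AIC with parsimony tie-break", {
  f <- function(scheme, ll, T_ = 1000) {
    df <- count_free_parameters(scheme)
    ic <- information_criteria(ll, df, T_)
    structure(list(scheme = scheme, log_likelihood = ll, df = df,
                   AIC = unname(ic["AIC"]), BIC = unname(ic["BIC"]),
                   T_effective = T_), class = "hmm_fit")
  }
  a <- f("M1", -419428.3, 86400)
  b <- f("M2", -424798.5, 86400)
  expect_identical(select_model(list(a, b))$scheme, "M1")
  expect_identical(select_model(list(b, a))$scheme, "M1")
  # equal AIC: prefer fewer free parameters
  c1 <- f("M1", -1000)   # AIC = 2000 + 26
  c2 <- f("M2", -1002)   # AIC = 2004 + 22, equal
  expect_equal(c1$AIC, c2$AIC)
  expect_identical(select_model(list(c1, c2))$scheme, "M2")
  # single fit passes through; mismatched lengths error
  expect_identical(select_model(list(a)), a)
  expect_error(select_model(list(a, f("M2", -100, 500))), "different")
  # AIC/BIC disagreement is reported and the preference honoured
  d1 <- f("M1", -996.5)   # AIC 2019, BIC worse (df 13)
  d2 <- f("M2", -1000)    # AIC 2022, BIC better (df 11)
  expect_message(sel <- select_model(list(d1, d2)), "disagree")
  expect_identical(sel$scheme, "M1")
  expect_message(sel2 <- select_model(list(d1, d2), prefer = "BIC"))
  expect_identical(sel2$scheme, "M2")
})

test_that("pseudo-residuals reduce to the identity for a degenerate model", {
  # both states standard normal on each channel: the mixture CDF is the
  # plain normal CDF, so the residual transform is the identity
  p <- hmm_parameters(pi = c(.5, .5), Gamma = matrix(.5, 2, 2),
                      mu_hr = c(0, 0), sigma2_hr = c(1, 1),
                      mu_act = c(0, 0), sigma2_act = c(1, 1))
  x <- rnorm(50); y <- rnorm(50)
  pr <- pseudo_residuals(p, "M2", data.frame(hr = x, act = y))
  expect_equal(pr$hr, x, tolerance = 1e-9)
  expect_equal(pr$act, y, tolerance = 1e-9)
})

test_that("pseudo-residuals are normal under the model, deviant under misfit", {
  p <- example_profiles()$older_adult_1$params
  crit <- function(n) 1.628 / sqrt(n)   # alpha = 0.01 KS critical value
  ok <- 0L
  for (s in 1:10) {
    z <- simulate_states(p, 2000, seed = 100 + s)
    sim <- simulate_observations(p, z, seed = 200 + s, truncate_act = FALSE)
    pr <- pseudo_residuals(p, "M1", sim)
    ks <- attr(pr, "ks")
    if (ks["hr"] < crit(2000) && ks["act"] < crit(2000)) ok <- ok + 1L
  }
  expect_gte(ok, 9L)

  # 5% gross heart-rate outliers push the residual tails out well beyond
  # what a standard normal would produce
  set.seed(300)
  z <- simulate_states(p, 2000, seed = 300)
  sim <- simulate_observations(p, z, seed = 301, truncate_act = FALSE)
  bad <- sample.int(2000, 100)
  sim$hr[bad] <- sim$hr[bad] + sample(c(-1, 1), 100, TRUE) * 60
  pr <- pseudo_residuals(p, "M1", sim)
  n_tail <- sum(abs(pr$hr) > 3, na.rm = TRUE)
  expect_gt(n_tail, 5 * 2000 * 2 * pnorm(-3))  # >5x the normal tail mass
  expect_gt(max(abs(pr$hr), na.rm = TRUE), 3.5)
})
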