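sim_dose_traces <- function(concs, occ, chan, sample_rate_hz = 5,
                            n_tau = 15, seed = NULL) {
  lapply(seq_along(concs), function(i) {
    tau_on <- 1 / (occ$alpha * concs[i] + occ$beta)
    prot <- wash_protocol(60, ceiling(n_tau * tau_on), 60, concs[i])
    simulate_application_trace(prot, occ, chan, sample_rate_hz =
                                 sample_rate_hz,
                               seed = if (is.null(seed)) NULL else seed + i)
  })
}

test_that("dose-response plateaus reproduce the occupancy model", {
  occ <- default_occ(); chan <- noiseless_chan()
  concs <- c(2.4, 12, 24, 48)
  dr <- build_dose_response(sim_dose_traces(concs, occ, chan), concs)
  expect_s3_class(dr, "dose_response")
  # zero efficacy: response identically 1 at every dose
  dr0 <- build_dose_response(
    sim_dose_traces(concs, default_occ(efficacy = 0), chan), concs)
  expect_equal(dr0$response, rep(1, 4), tolerance = 1e-9)
  # 48 uM with kd 80.9 and efficacy 1.99: response = 1 + 1.99 * 0.372
  expect_equal(dr$response[dr$concentration_uM == 48], 1.741,
               tolerance = 1e-3)
  # responses increase with concentration when efficacy > 0
  expect_true(all(diff(dr$response) > 0))
})

test_that("traces without usable epoch metadata are refused", {
  occ <- default_occ(); chan <- noiseless_chan()
  no_ligand <- simulate_application_trace(
    application_protocol(c(20, 20), c("HK", "HK"), c(0, 0)), occ, chan,
    sample_rate_hz = 10)
  good <- simulate_application_trace(wash_protocol(20, 40, 20, 48), occ,
                                     chan, sample_rate_hz = 10)
  expect_error(build_dose_response(list(no_ligand, good), c(12, 48)),
               "no ligand epoch")
  no_basal <- simulate_application_trace(
    application_protocol(c(40, 20), c("HK", "HK"), c(48, 0)), occ, chan,
    sample_rate_hz = 10)
  expect_error(build_dose_response(list(no_basal, good), c(48, 48)),
               "at least 2 distinct")
  expect_error(build_dose_response(list(no_basal, good), c(12, 48)),
               "basal epoch")
})

test_that("Hill fit recovers exact generating parameters", {
  hill <- function(L, emax, ec50, n) 1 + emax * L^n / (L^n + ec50^n)
  # the four-concentration design, n = 1 truth
  L4 <- c(2.4, 12, 24, 48)
  dr <- data.frame(concentration_uM = L4,
                   response = hill(L4, 1.99, 80.9, 1))
  fit <- fit_hill(dr)
  expect_false(fit$degenerate)
  expect_equal(fit$emax, 1.99, tolerance = 1e-6)
  expect_equal(fit$ec50_uM, 80.9, tolerance = 1e-6)
  expect_equal(fit$n, 1, tolerance = 1e-6)
  # a steeper curve on a denser design
  L7 <- c(1, 3, 10, 30, 100, 300, 1000)
  dr7 <- data.frame(concentration_uM = L7,
                    response = hill(L7, 2.5, 40, 1.7))
  fit7 <- fit_hill(dr7)
  expect_equal(fit7$n, 1.7, tolerance = 1e-4)
  expect_equal(fit7$ec50_uM, 40, tolerance = 1e-4)
  # two concentrations: Hill coefficient fixed at 1
  fit2 <- fit_hill(data.frame(concentration_uM = c(10, 100),
                              response = hill(c(10, 100), 2, 50, 1)))
  expect_true(fit2$n_fixed)
  expect_equal(fit2$ec50_uM, 50, tolerance = 1e-6)
  # flat responses: degenerate flag, no parameters
  flat <- fit_hill(data.frame(concentration_uM = L4, response = rep(1, 4)))
  expect_true(flat$degenerate)
  expect_true(is.na(flat$ec50_uM))
})

test_that("simulator dose-response is Hill with n = 1 and EC50 = kd", {
  occ <- default_occ(); chan <- noiseless_chan()
  concs <- c(2.4, 12, 24, 48)
  dr <- build_dose_response(sim_dose_traces(concs, occ, chan), concs)
  fit <- fit_hill(dr)
  expect_equal(fit$n, 1, tolerance = 1e-3)
  expect_equal(fit$ec50_uM, occ$beta / occ$alpha, tolerance = 1e-3)
})

test_that("EC50 is recovered from noisy replicated dose-responses", {
  occ <- default_occ()
  chan <- channel_model(exchange_tau_s = 0)  # default noise retained
  concs <- c(2.4, 12, 24, 48)
  ec50s <- vapply(1:20, function(r) {
    dr <- build_dose_response(
      sim_dose_traces(concs, occ, chan, sample_rate_hz = 2, n_tau = 12,
                      seed = 1000 + 10 * r), concs)
    fit_hill(dr)$ec50_uM
  }, numeric(1))
  truth <- occ$beta / occ$alpha
  expect_lt(abs(median(ec50s) - truth) / truth, 0.15)
})

test_that("Welch test matches its defining formulas", {
  w <- welch_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(w$t_stat, -sqrt(1.5), tolerance = 1e-10)
  expect_equal(w$dof, 4)
  expect_equal(w$p_value, 0.2878641, tolerance = 1e-6)
  expect_equal(w$group_summaries$n, c(3L, 3L))
  # independently coded Welch formulas on unbalanced, heteroscedastic data
  welch_oracle <- function(a, b) {
    va <- sd(a)^2 / length(a); vb <- sd(b)^2 / length(b)
    t <- (mean(a) - mean(b)) / sqrt(va + vb)
    dof <- (va + vb)^2 /
      (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    list(t = t, dof = dof, p = 2 * pt(-abs(t), dof))
  }
  withr::with_seed(21, {
    for (k in 1:10) {
      a <- rnorm(sample(3:9, 1), 0, 1)
      b <- rnorm(sample(3:9, 1), runif(1, -1, 1), runif(1, 0.2, 3))
      w <- welch_t_test(a, b)
      o <- welch_oracle(a, b)
      expect_equal(w$t_stat, o$t, tolerance = 1e-12)
      expect_equal(w$dof, o$dof, tolerance = 1e-12)
      expect_equal(w$p_value, o$p, tolerance = 1e-12)
    }
  })
})

test_that("Welch test is antisymmetric and scale invariant", {
  withr::with_seed(31, {
    a <- rnorm(5); b <- rnorm(7, 0.5, 2)
    w1 <- welch_t_test(a, b); w2 <- welch_t_test(b, a)
    expect_equal(w1$t_stat, -w2$t_stat)
    expect_equal(w1$p_value, w2$p_value)
    w3 <- welch_t_test(3.7 * a, 3.7 * b)
    expect_equal(w3$t_stat, w1$t_stat, tolerance = 1e-12)
    expect_equal(w3$p_value, w1$p_value, tolerance = 1e-12)
  })
  expect_error(welch_t_test(1, c(1, 2)), "insufficient data")
  expect_error(welch_t_test(c(1, 1), c(2, 2)), "zero variance")
})
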