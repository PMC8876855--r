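test_that("noiseless application trace follows the closed-form occupancy", {
  occ <- default_occ()   # alpha 7.82e-5, beta 6.33e-3 -> kd 80.9 uM
  chan <- noiseless_chan()
  conc <- 48
  tau_on <- 1 / (occ$alpha * conc + occ$beta)    # 99.17 s
  tau_off <- 1 / occ$beta                        # 157.98 s
  expect_equal(tau_on, 99.17, tolerance = 1e-4)
  expect_equal(tau_off, 158.0, tolerance = 1e-3)
  prot <- wash_protocol(50, ceiling(15 * tau_on), ceiling(15 * tau_off), conc)
  tr <- simulate_application_trace(prot, occ, chan, sample_rate_hz = 10)
  basal <- tr$current_uA[tr$time_s <= 50][10L]
  p <- occupancy_from_trace(tr, occ, basal)
  p_eq <- conc / (conc + occ$beta / occ$alpha)
  expect_equal(p_eq, 0.372, tolerance = 1e-3)
  # equilibrium occupancy matches L/(L + kd) to < 1e-6 relative
  t_app_end <- prot$end_s[2L]
  p_end <- p[which.min(abs(tr$time_s - t_app_end))]
  expect_equal(p_end, p_eq, tolerance = 1e-6)
  # full wash-in time course matches the closed form pointwise
  sel <- tr$time_s >= 50 & tr$time_s <= t_app_end
  t_rel <- tr$time_s[sel] - 50
  expect_lt(max(abs(p[sel] - p_eq * (1 - exp(-t_rel / tau_on)))), 1e-9)
  # wash-out decays with time constant 1/beta from the wash-out start
  sel2 <- tr$time_s >= t_app_end
  t_rel2 <- tr$time_s[sel2] - t_app_end
  expect_lt(max(abs(p[sel2] - p_end * exp(-t_rel2 / tau_off))), 1e-9)
})

test_that("simulated kinetics agree with an independent ODE integration", {
  skip_if_not_installed("deSolve")
  occ <- occupancy_model(alpha = 3e-4, beta = 4e-3, efficacy = 1.5)
  chan <- noiseless_chan(exchange_tau_s = 2)
  prot <- wash_protocol(20, 150, 200, 24)
  tr <- simulate_application_trace(prot, occ, chan, sample_rate_hz = 100)
  lig_target <- function(t) {
    i <- findInterval(t + 1e-9, prot$start_s)
    prot$ligand_uM[pmax(i, 1L)]
  }
  rhs <- function(t, y, parms) {
    dL <- (lig_target(t) - y[1L]) / chan$exchange_tau_s
    dp <- occ$alpha * y[1L] * (1 - y[2L]) - occ$beta * y[2L]
    list(c(dL, dp))
  }
  sol <- deSolve::ode(c(L = 0, p = 0), times = tr$time_s, func = rhs,
                      parms = NULL, rtol = 1e-10, atol = 1e-12)
  basal <- tr$current_uA[5L]
  p_sim <- occupancy_from_trace(tr, occ, basal)
  expect_lt(max(abs(p_sim - sol[, "p"])), 1e-4)
})

test_that("simulation is seed-deterministic and validates inputs", {
  occ <- default_occ(); chan <- channel_model()
  prot <- wash_protocol(5, 10, 10)
  a <- simulate_application_trace(prot, occ, chan, sample_rate_hz = 100,
                                  seed = 7)
  b <- simulate_application_trace(prot, occ, chan, sample_rate_hz = 100,
                                  seed = 7)
  c <- simulate_application_trace(prot, occ, chan, sample_rate_hz = 100,
                                  seed = 8)
  expect_identical(a$current_uA, b$current_uA)
  expect_false(identical(a$current_uA, c$current_uA))
  expect_error(simulate_application_trace(prot, occ, chan, seed = -1),
               "non-negative")
  expect_error(simulate_application_trace(prot[0, ], occ, chan),
               "at least one epoch")
})

test_that("null ligand or zero efficacy leaves the basal current unchanged", {
  chan <- noiseless_chan()
  basal_only <- application_protocol(c(20, 20), c("HK", "HK"), c(0, 0))
  tr0 <- simulate_application_trace(basal_only, default_occ(), chan,
                                    sample_rate_hz = 20)
  expect_equal(diff(range(tr0$current_uA)), 0)
  tr_eff0 <- simulate_application_trace(
    wash_protocol(20, 10, 10), default_occ(efficacy = 0), chan,
    sample_rate_hz = 20)
  expect_equal(unique(tr_eff0$current_uA), tr0$current_uA[1L])
})

test_that("occupancy stays within [0, 1] across random valid parameters", {
  withr::with_seed(99, {
    for (k in 1:10) {
      occ <- occupancy_model(alpha = 10^runif(1, -5, -2),
                             beta = 10^runif(1, -3, -1),
                             efficacy = runif(1, 0, 3))
      chan <- noiseless_chan(exchange_tau_s = runif(1, 0, 5))
      prot <- wash_protocol(10, 200, 200, runif(1, 1, 500))
      tr <- simulate_application_trace(prot, occ, chan, sample_rate_hz = 5)
      p <- occupancy_from_trace(tr, occ, tr$current_uA[1L])
      expect_gte(min(p), -1e-12)
      expect_lte(max(p), 1 + 1e-12)
    }
  })
})

test_that("ND96 to HK exchange develops the basal inward current", {
  chan <- noiseless_chan(exchange_tau_s = 1)
  prot <- application_protocol(c(20, 40), c("ND96", "HK"), c(0, 0))
  tr <- simulate_application_trace(prot, default_occ(), chan,
                                   sample_rate_hz = 20)
  i_nd96 <- tr$current_uA[tr$time_s < 19][1L]
  i_hk <- tail(tr$current_uA, 1L)
  # small outward current in low-K bath; large inward current in high K
  expect_gt(i_nd96, 0)
  expect_lt(i_hk, -0.5)
})

test_that("ramp pairs share a reversal and scale by 1 + efficacy*occupancy", {
  occ <- default_occ()   # efficacy 1.99
  chan <- noiseless_chan()
  # zero occupancy: identical curves
  pair0 <- simulate_ramp_pair(occ, chan, occupancy = 0)
  expect_equal(pair0$ligand$current_uA, pair0$basal$current_uA)
  # efficacy * occupancy = 0.741: ligand = 1.741 x basal at every voltage
  pair <- simulate_ramp_pair(occ, chan, occupancy = 0.741 / occ$efficacy)
  expect_equal(pair$ligand$current_uA, 1.741 * pair$basal$current_uA,
               tolerance = 1e-12)
  # symmetric 96/96 K+: both curves cross zero at 0 mV
  expect_lt(abs(reversal_potential(pair$basal)), 0.01)
  expect_lt(abs(reversal_potential(pair$ligand)), 0.01)
  expect_error(simulate_ramp_pair(occ, chan, occupancy = 1.2), "\\[0, 1\\]")
  expect_error(simulate_ramp_pair(occ, chan, occupancy = -0.1), "\\[0, 1\\]")
})

test_that("Kv step traces scale with the block fraction", {
  chan <- channel_model()
  ctrl <- simulate_kv_step(0, chan, seed = 3)
  same <- simulate_kv_step(0, chan, seed = 3)
  expect_identical(ctrl$current_uA, same$current_uA)
  # noiseless peak ratio equals 1 - block_fraction
  chan0 <- noiseless_chan()
  c0 <- simulate_kv_step(0, chan0)
  c135 <- simulate_kv_step(0.135, chan0)
  expect_equal(max(c135$current_uA) / max(c0$current_uA), 0.865,
               tolerance = 1e-12)
  # full block: flat zero current
  full <- simulate_kv_step(1, chan0)
  expect_equal(max(abs(full$current_uA)), 0)
  expect_error(simulate_kv_step(1.5, chan), "\\[0, 1\\]")
  # activating then deactivating outward current
  expect_gt(max(c0$current_uA[c0$time_s < 0.5]), 0.9)
  expect_lt(tail(c0$current_uA, 1L), 0.05)
})
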