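#' Build an application protocol (epoch table)
#'
#' Convenience constructor for the timed sequence of bath-solution/ligand
#' epochs that drives [simulate_application_trace()]. A typical GIRK
#' experiment is ND96 -> HK (basal current develops) -> HK + ligand
#' (wash-in) -> HK (wash-out).
#'
#' @param durations_s epoch durations in seconds (> 0).
#' @param solutions character vector of bath labels (`"ND96"`, `"HK"`, or
#'   custom labels if `kout_mM` is supplied).
#' @param ligand_uM ligand concentration per epoch, micromolar (>= 0).
#' @param kout_mM optional external K+ per epoch, mM; when `NULL` it is
#'   looked up from the solution label (ND96 = 2 mM, HK = 96 mM).
#' @return data frame with columns `start_s`, `end_s`, `solution`,
#'   `ligand_uM`, `kout_mM`.
#' @export
#' @examples
#' application_protocol(c(30, 60, 120, 180), c("ND96", "HK", "HK", "HK"),
#'                      c(0, 0, 48, 0))
application_protocol <- function(durations_s, solutions, ligand_uM,
                                 kout_mM = NULL) {
  k <- length(durations_s)
  if (k == 0L) stop("protocol must contain at least one epoch", call. = FALSE)
  if (length(solutions) != k || length(ligand_uM) != k)
    stop("durations_s, solutions and ligand_uM must have equal length",
         call. = FALSE)
  if (any(!is.finite(durations_s)) || any(durations_s <= 0))
    stop("all epoch durations must be finite and > 0", call. = FALSE)
  if (any(ligand_uM < 0)) stop("ligand_uM must be >= 0", call. = FALSE)
  ends <- cumsum(as.numeric(durations_s))
  data.frame(start_s = c(0, head(ends, -1L)), end_s = ends,
             solution = as.character(solutions),
             ligand_uM = as.numeric(ligand_uM),
             kout_mM = solution_kout(as.character(solutions), kout_mM))
}

# vectorized Nernst (inputs pre-validated)
nernst_vec <- function(kout_mM, kin_mM, temperature_K) {
  1000 * 8.314462618 * temperature_K / 96485.33212 * log(kout_mM / kin_mM)
}

# exact first-order relaxation of x toward a piecewise-constant target,
# sampled on `time`; init = x at the first sample
filter_first_order <- function(target, time, tau, init) {
  if (tau <= 0) return(target)
  out <- numeric(length(target))
  runs <- rle(target)
  x0 <- init
  pos <- 1L
  for (k in seq_along(runs$lengths)) {
    idx <- pos:(pos + runs$lengths[k] - 1L)
    tg <- runs$values[k]
    out[idx] <- tg + (x0 - tg) * exp(-(time[idx] - time[idx[1L]]) / tau)
    x0 <- out[idx[length(idx)]]
    pos <- pos + runs$lengths[k]
  }
  out
}

#' Simulate a TEVC ligand-application recording
#'
#' Generates a voltage-clamp current trace at a fixed holding potential
#' driven by an epoch protocol. Ligand concentration and external K+ are
#' passed through a first-order solution-exchange filter (time constant
#' `chan$exchange_tau_s`); channel occupancy follows the bimolecular scheme
#' dp/dt = alpha*L(t)*(1 - p) - beta*p (integrated with the exact
#' per-sample exponential update, so the noiseless output matches the
#' closed-form solution); the current is the rectified chord-conductance
#' current scaled by (1 + efficacy * p(t)), plus Gaussian noise. Occupancy
#' starts at 0 (no ligand pre-bound).
#'
#' @param protocol epoch table from [application_protocol()] (or any data
#'   frame with those columns).
#' @param occ an [occupancy_model()].
#' @param chan a [channel_model()] (its `kout_mM` is overridden per epoch by
#'   the protocol's solutions).
#' @param holding_mV holding potential, mV (default -90, the standard GIRK
#'   protocol).
#' @param sample_rate_hz sampling rate, Hz (default 1000). Epoch durations
#'   must be integer multiples of the sampling interval.
#' @param seed non-negative integer seed for the noise generator; identical
#'   seed and inputs give a bit-identical trace. `NULL` uses the ambient RNG.
#' @return A [tevc_trace()] with the protocol as its epoch table.
#' @export
simulate_application_trace <- function(protocol, occ, chan, holding_mV = -90,
                                       sample_rate_hz = 1000, seed = NULL) {
  stopifnot(inherits(occ, "occupancy_model"), inherits(chan, "channel_model"))
  check_seed(seed)
  check_number(holding_mV, "holding_mV")
  check_number(sample_rate_hz, "sample_rate_hz", positive = TRUE)
  protocol <- as.data.frame(protocol)
  if (nrow(protocol) == 0L)
    stop("protocol must contain at least one epoch", call. = FALSE)
  if (is.null(protocol$kout_mM))
    protocol$kout_mM <- solution_kout(protocol$solution)
  dt <- 1 / sample_rate_hz
  total <- protocol$end_s[nrow(protocol)] - protocol$start_s[1L]
  m <- round(total * sample_rate_hz)
  if (m < 1L || abs(m * dt - total) > .EPOCH_TOL)
    stop("protocol duration must be a positive integer number of samples",
         call. = FALSE)
  time <- protocol$start_s[1L] + (0:m) * dt
  # epoch membership: [start, end) except the final sample -> last epoch
  idx <- findInterval(time + .EPOCH_TOL / 2, protocol$start_s)
  L_target <- protocol$ligand_uM[idx]
  K_target <- protocol$kout_mM[idx]
  L <- filter_first_order(L_target, time, chan$exchange_tau_s, L_target[1L])
  K <- filter_first_order(K_target, time, chan$exchange_tau_s, K_target[1L])

  n <- length(time)
  a <- occ$alpha * L + occ$beta
  pinf <- occ$alpha * L / a
  step <- exp(-a * dt)
  p <- numeric(n)
  for (i in seq_len(n - 1L))
    p[i + 1L] <- pinf[i] + (p[i] - pinf[i]) * step[i]

  e_rev <- nernst_vec(K, chan$kin_mM, chan$temperature_K)
  g <- rectified_conductance(chan, holding_mV)
  current <- g * (holding_mV - e_rev) / 1000 * (1 + occ$efficacy * p)
  if (chan$noise_sd_uA > 0)
    current <- current +
      with_optional_seed(seed, rnorm(n, 0, chan$noise_sd_uA))
  tevc_trace(time, current, holding_mV, sample_rate_hz,
             protocol[, c("start_s", "end_s", "solution", "ligand_uM")])
}

#' Simulate a basal/ligand voltage-ramp I-V pair
#'
#' Emulates the 1-s voltage ramp protocol (-150 to +60 mV) applied before
#' and during ligand application at a fixed channel occupancy. Both curves
#' share the same reversal potential (set by the K+ gradient in `chan`);
#' the ligand curve is the basal conductance scaled by
#' (1 + efficacy * occupancy).
#'
#' @inheritParams simulate_application_trace
#' @param occupancy fractional channel occupancy in \[0, 1\] at which the
#'   ligand ramp is taken.
#' @param v_start_mV,v_end_mV ramp limits, mV.
#' @param ramp_duration_s ramp duration, s.
#' @return list with elements `basal` and `ligand`, each an [iv_curve()].
#' @export
simulate_ramp_pair <- function(occ, chan, occupancy, seed = NULL,
                               v_start_mV = -150, v_end_mV = 60,
                               ramp_duration_s = 1, sample_rate_hz = 1000) {
  stopifnot(inherits(occ, "occupancy_model"), inherits(chan, "channel_model"))
  check_seed(seed)
  check_number(occupancy, "occupancy")
  if (occupancy < 0 || occupancy > 1)
    stop("occupancy must lie in [0, 1] (got ", occupancy, ")", call. = FALSE)
  n <- round(ramp_duration_s * sample_rate_hz) + 1L
  v <- seq(v_start_mV, v_end_mV, length.out = n)
  e_rev <- nernst_potential(chan$kout_mM, chan$kin_mM, chan$temperature_K)
  i_basal <- rectified_conductance(chan, v) * (v - e_rev) / 1000
  i_ligand <- i_basal * (1 + occ$efficacy * occupancy)
  if (chan$noise_sd_uA > 0) {
    noise <- with_optional_seed(seed, rnorm(2L * n, 0, chan$noise_sd_uA))
    i_basal <- i_basal + noise[seq_len(n)]
    i_ligand <- i_ligand + noise[n + seq_len(n)]
  }
  list(basal = iv_curve(v, i_basal, label = "basal"),
       ligand = iv_curve(v, i_ligand, label = "ligand"))
}

#' Simulate a voltage-gated K+ (Kv) step recording
#'
#' Emulates the Kv selectivity-screen protocol: a 500 ms depolarization to
#' 0 mV (mono-exponentially activating outward current) followed by a
#' 500 ms pulse to -50 mV (deactivating tail), from a -90 mV holding
#' potential in low-K bath (ND96). Peak current is scaled by
#' (1 - block_fraction); gating is a single-exponential stand-in since only
#' peak block is quantified downstream.
#'
#' @inheritParams simulate_application_trace
#' @param block_fraction fraction of current blocked, in \[0, 1\].
#' @param peak_uA unblocked steady-state outward current at 0 mV, uA.
#' @param tau_act_s,tau_deact_s activation/deactivation time constants, s.
#' @param step_duration_s duration of each of the two voltage steps, s.
#' @return A [tevc_trace()] with epochs `step_0mV` and `tail_-50mV`.
#' @export
simulate_kv_step <- function(block_fraction, chan, seed = NULL, peak_uA = 1,
                             tau_act_s = 0.010, tau_deact_s = 0.015,
                             step_duration_s = 0.5, sample_rate_hz = 1000) {
  stopifnot(inherits(chan, "channel_model"))
  check_seed(seed)
  check_number(block_fraction, "block_fraction")
  if (block_fraction < 0 || block_fraction > 1)
    stop("block_fraction must lie in [0, 1] (got ", block_fraction, ")",
         call. = FALSE)
  check_number(peak_uA, "peak_uA", positive = TRUE)
  dt <- 1 / sample_rate_hz
  m <- round(step_duration_s * sample_rate_hz)
  time <- (0:(2L * m)) * dt
  e_rev <- nernst_potential(solution_kout("ND96"), chan$kin_mM,
                            chan$temperature_K)
  scale <- 1 - block_fraction
  act <- 1 - exp(-time[seq_len(m)] / tau_act_s)
  act_end <- 1 - exp(-step_duration_s / tau_act_s)
  # driving-force ratio between the tail (-50 mV) and test (0 mV) potentials
  drive_ratio <- (-50 - e_rev) / (0 - e_rev)
  tail_t <- time[(m + 1L):(2L * m + 1L)] - step_duration_s
  tail <- act_end * drive_ratio * exp(-tail_t / tau_deact_s)
  current <- peak_uA * scale * c(act, tail)
  if (chan$noise_sd_uA > 0)
    current <- current +
      with_optional_seed(seed, rnorm(length(current), 0, chan$noise_sd_uA))
  epochs <- data.frame(
    start_s = c(0, step_duration_s),
    end_s = c(step_duration_s, 2 * step_duration_s),
    solution = c("step_0mV", "tail_-50mV"), ligand_uM = c(0, 0))
  tevc_trace(time, current, -90, sample_rate_hz, epochs)
}
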