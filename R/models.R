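#' Nernst equilibrium potential for potassium
#'
#' E_K = (R*T/F) * ln([K]_out/[K]_in), returned in millivolts. In the
#' high-potassium bath used for GIRK recordings (96 mM K+ outside against a
#' near-equal intracellular concentration) the K+ reversal potential sits
#' close to 0 mV, which is what makes inward currents large at negative
#' holding potentials.
#'
#' @param kout_mM external K+ concentration, mM (> 0).
#' @param kin_mM internal K+ concentration, mM (> 0).
#' @param temperature_K absolute temperature, kelvin (default 295.15 K,
#'   i.e. 22 degrees C, standard room-temperature oocyte recording).
#' @return Equilibrium potential in millivolts.
#' @export
#' @examples
#' nernst_potential(96, 96)            # symmetric K+: 0 mV
#' nernst_potential(2, 96, 295.15)     # low-K bath: about -98.4 mV
nernst_potential <- function(kout_mM, kin_mM, temperature_K = 295.15) {
  check_number(kout_mM, "kout_mM", positive = TRUE)
  check_number(kin_mM, "kin_mM", positive = TRUE)
  check_number(temperature_K, "temperature_K", positive = TRUE)
  R <- 8.314462618   # J mol^-1 K^-1 (CODATA)
  Faraday <- 96485.33212  # C mol^-1
  1000 * R * temperature_K / Faraday * log(kout_mM / kin_mM)
}

#' Ligand-occupancy model (bimolecular binding scheme)
#'
#' Single-site reversible binding C + L <=> C:L. Occupancy p(t) obeys
#' dp/dt = alpha*L*(1 - p) - beta*p, so the approach to equilibrium is
#' mono-exponential with observed rate alpha*L + beta, equilibrium occupancy
#' L/(L + beta/alpha), and affinity kd = beta/alpha. Response is linear in
#' occupancy: current is scaled by (1 + efficacy * p).
#'
#' @param alpha second-order association rate constant, uM^-1 s^-1 (> 0).
#' @param beta first-order dissociation rate constant, s^-1 (> 0).
#' @param efficacy maximal fractional current increase at full occupancy
#'   (dimensionless, >= 0). The default 1.99 together with the default
#'   affinity (kd = beta/alpha = 80.9 uM) gives about a 74% enhancement at
#'   48 uM ligand, the scale reported for GIRK1/2 activation.
#' @param linear_coupling logical; occupancy-to-response coupling is linear
#'   (the only mode implemented; kept explicit because EC50 = kd relies on it).
#' @return An object of class `occupancy_model`.
#' @export
occupancy_model <- function(alpha = 7.82e-5, beta = 6.33e-3,
                            efficacy = 1.99, linear_coupling = TRUE) {
  check_number(alpha, "alpha", positive = TRUE)
  check_number(beta, "beta", positive = TRUE)
  check_number(efficacy, "efficacy", nonneg = TRUE)
  if (!isTRUE(linear_coupling))
    stop("only linear occupancy-response coupling is implemented",
         call. = FALSE)
  structure(list(alpha = alpha, beta = beta, efficacy = efficacy,
                 linear_coupling = TRUE),
            class = "occupancy_model")
}

#' @export
print.occupancy_model <- function(x, ...) {
  cat(sprintf(paste0(
    "occupancy model: alpha %.3g uM^-1 s^-1, beta %.3g s^-1 ",
    "(kd %.3g uM), efficacy %.3g\n"),
    x$alpha, x$beta, x$beta / x$alpha, x$efficacy))
  invisible(x)
}

#' Inward-rectifier channel model for trace simulation
#'
#' Phenomenological description of the macroscopic GIRK conductance used by
#' the synthetic-data generator. The chord conductance follows a Boltzmann
#' rectification curve g(V) = g_max / (1 + exp((V - rect_vhalf)/rect_slope)),
#' which gives strong inward rectification (large conductance negative to
#' rect_vhalf, small positive to it). This is a descriptive stand-in, not a
#' mechanistic Mg2+/polyamine block model.
#'
#' @param g_max_uS maximal chord conductance, microsiemens (> 0).
#' @param kout_mM,kin_mM external/internal K+, mM (> 0). Defaults are the
#'   symmetric high-K condition (96/96) so ramps reverse at 0 mV.
#' @param temperature_K recording temperature, kelvin.
#' @param rect_vhalf_mV rectification midpoint, mV.
#' @param rect_slope_mV rectification slope factor, mV (> 0).
#' @param noise_sd_uA standard deviation of Gaussian recording noise, uA
#'   (>= 0).
#' @param exchange_tau_s first-order time constant of bath solution
#'   exchange, s (>= 0; 0 = instantaneous exchange).
#' @return An object of class `channel_model`.
#' @export
channel_model <- function(g_max_uS = 10, kout_mM = 96, kin_mM = 96,
                          temperature_K = 295.15, rect_vhalf_mV = -10,
                          rect_slope_mV = 12, noise_sd_uA = 0.005,
                          exchange_tau_s = 2) {
  check_number(g_max_uS, "g_max_uS", positive = TRUE)
  check_number(kout_mM, "kout_mM", positive = TRUE)
  check_number(kin_mM, "kin_mM", positive = TRUE)
  check_number(temperature_K, "temperature_K", positive = TRUE)
  check_number(rect_vhalf_mV, "rect_vhalf_mV")
  check_number(rect_slope_mV, "rect_slope_mV", positive = TRUE)
  check_number(noise_sd_uA, "noise_sd_uA", nonneg = TRUE)
  check_number(exchange_tau_s, "exchange_tau_s", nonneg = TRUE)
  structure(list(g_max_uS = g_max_uS, kout_mM = kout_mM, kin_mM = kin_mM,
                 temperature_K = temperature_K, rect_vhalf_mV = rect_vhalf_mV,
                 rect_slope_mV = rect_slope_mV, noise_sd_uA = noise_sd_uA,
                 exchange_tau_s = exchange_tau_s),
            class = "channel_model")
}

#' @export
print.channel_model <- function(x, ...) {
  cat(sprintf(paste0(
    "channel model: g_max %.3g uS, K+ %g/%g mM (E_K %.2f mV), ",
    "rectification V1/2 %g mV slope %g mV,\n  noise sd %g uA, ",
    "exchange tau %g s, T %g K\n"),
    x$g_max_uS, x$kout_mM, x$kin_mM,
    nernst_potential(x$kout_mM, x$kin_mM, x$temperature_K),
    x$rect_vhalf_mV, x$rect_slope_mV, x$noise_sd_uA, x$exchange_tau_s,
    x$temperature_K))
  invisible(x)
}

# Boltzmann chord-conductance curve, uS
rectified_conductance <- function(chan, v_mV) {
  chan$g_max_uS / (1 + exp((v_mV - chan$rect_vhalf_mV) / chan$rect_slope_mV))
}

# external K+ of the named bath solutions, mM (ND96 / high-K recipes)
.SOLUTION_KOUT <- c(ND96 = 2, HK = 96)

solution_kout <- function(solution, kout_mM = NULL) {
  if (!is.null(kout_mM)) return(as.numeric(kout_mM))
  known <- .SOLUTION_KOUT[solution]
  if (any(is.na(known)))
    stop("unknown bath solution(s): ",
         paste(unique(solution[is.na(known)]), collapse = ", "),
         " (known: ", paste(names(.SOLUTION_KOUT), collapse = ", "),
         "; or supply kout_mM)", call. = FALSE)
  unname(known)
}
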