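#' Fit a single-exponential segment of a trace
#'
#' Least-squares fit of a mono-exponential rise
#' `y(t) = offset + amplitude * (1 - exp(-(t - t0)/tau))` or decay
#' `y(t) = offset + amplitude * exp(-(t - t0)/tau)` over a time window of a
#' recording. `t0` is fixed at the window start (the application onset is
#' protocol-driven and known from the epoch table, so it is not a free
#' parameter). This is the workhorse for wash-in/wash-out kinetics under
#' the bimolecular binding scheme, where the approach to equilibrium is
#' mono-exponential with observed rate alpha*L + beta.
#'
#' Initialization: offset from the first (rise) or last (decay) decile mean,
#' amplitude from the difference of decile means, tau = window/5, with tau
#' bounded in \[sampling interval, 100 x window length\].
#'
#' @param trace a [tevc_trace()].
#' @param window numeric length-2, `(start_s, end_s)` within the trace
#'   extent, containing at least 10 samples.
#' @param direction `"rise"` or `"decay"`.
#' @return An object of class `kinetic_fit`: list with fields `amplitude`
#'   (uA, signed), `tau` (s), `offset` (uA), `rms_residual` (uA), `window`,
#'   `direction`, `converged` (logical) and `note` (diagnostics; e.g.
#'   `"degenerate amplitude"` for a flat segment).
#' @export
fit_single_exponential <- function(trace, window,
                                   direction = c("rise", "decay")) {
  validate_trace(trace)
  direction <- match.arg(direction)
  if (!is.numeric(window) || length(window) != 2L || window[2L] <= window[1L])
    stop("window must be (start_s, end_s) with end > start", call. = FALSE)
  n_all <- length(trace$time_s)
  if (window[1L] < trace$time_s[1L] - .EPOCH_TOL ||
      window[2L] > trace$time_s[n_all] + .EPOCH_TOL)
    stop(sprintf("window [%g, %g] s lies outside the trace extent [%g, %g] s",
                 window[1L], window[2L], trace$time_s[1L],
                 trace$time_s[n_all]), call. = FALSE)
  keep <- trace$time_s >= window[1L] - .EPOCH_TOL &
    trace$time_s <= window[2L] + .EPOCH_TOL
  if (sum(keep) < 10L)
    stop("insufficient data: window must contain at least 10 samples",
         call. = FALSE)
  tl <- trace$time_s[keep] - window[1L]   # t0 fixed at window start
  y <- trace$current_uA[keep]
  span <- window[2L] - window[1L]
  dt <- 1 / trace$sample_rate_hz

  dec <- max(1L, floor(length(y) / 10))
  first_dec <- mean(head(y, dec)); last_dec <- mean(tail(y, dec))
  if (direction == "rise") {
    start <- list(offset = first_dec, amplitude = last_dec - first_dec,
                  tau = span / 5)
    form <- y ~ offset + amplitude * (1 - exp(-tl / tau))
  } else {
    start <- list(offset = last_dec, amplitude = first_dec - last_dec,
                  tau = span / 5)
    form <- y ~ offset + amplitude * exp(-tl / tau)
  }

  result <- tryCatch({
    fit <- minpack.lm::nlsLM(
      form, data = list(y = y, tl = tl), start = start,
      lower = c(offset = -Inf, amplitude = -Inf, tau = dt),
      upper = c(offset = Inf, amplitude = Inf, tau = 100 * span),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14))
    cf <- coef(fit)
    list(amplitude = unname(cf["amplitude"]), tau = unname(cf["tau"]),
         offset = unname(cf["offset"]),
         rms_residual = sqrt(mean(residuals(fit)^2)),
         converged = TRUE, note = "")
  }, error = function(e) {
    if (diff(range(y)) <= max(1e-12, 1e-9 * max(abs(y), 1)))
      list(amplitude = 0, offset = mean(y), tau = start$tau,
           rms_residual = sd(y) * sqrt((length(y) - 1) / length(y)),
           converged = TRUE, note = "degenerate amplitude")
    else
      list(amplitude = NA_real_, offset = NA_real_, tau = NA_real_,
           rms_residual = NA_real_, converged = FALSE,
           note = paste("optimizer failed:", conditionMessage(e)))
  })
  if (result$converged && result$note == "" &&
      abs(result$amplitude) <= max(1e-9, 2 * result$rms_residual /
                                     sqrt(length(y))))
    result$note <- "degenerate amplitude"
  structure(c(result[c("amplitude", "tau", "offset", "rms_residual")],
              list(window = as.numeric(window), direction = direction),
              result[c("converged", "note")]),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("single-exponential %s fit over [%g, %g] s\n",
              x$direction, x$window[1L], x$window[2L]))
  if (x$converged)
    cat(sprintf("  amplitude %.4g uA, tau %.4g s, offset %.4g uA, RMS %.3g uA%s\n",
                x$amplitude, x$tau, x$offset, x$rms_residual,
                if (nzchar(x$note)) paste0("  [", x$note, "]") else ""))
  else cat("  NOT converged:", x$note, "\n")
  invisible(x)
}

#' Rate constants of the bimolecular binding scheme
#'
#' Constructor enforcing the scheme's identities: `kd = beta/alpha` exactly,
#' and `ec50 = kd` (linear occupancy-response coupling). Printed to 3
#' significant figures.
#'
#' @param k_on apparent first-order association rate, s^-1 (`alpha * L`).
#' @param k_off first-order dissociation rate, s^-1 (`= beta`).
#' @param alpha second-order association rate constant, uM^-1 s^-1.
#' @param beta first-order dissociation rate constant, s^-1.
#' @param ligand_uM ligand concentration the apparent rates refer to, uM
#'   (`NA` when constructed from alpha/beta alone).
#' @return An object of class `rate_constants` with fields `k_on`, `k_off`,
#'   `alpha`, `beta`, `k_d`, `ec50`, `ligand_uM`.
#' @export
rate_constants <- function(k_on, k_off, alpha, beta, ligand_uM = NA_real_) {
  check_number(alpha, "alpha", positive = TRUE)
  check_number(beta, "beta", positive = TRUE)
  check_number(k_on, "k_on", positive = TRUE)
  check_number(k_off, "k_off", positive = TRUE)
  kd <- beta / alpha
  structure(list(k_on = k_on, k_off = k_off, alpha = alpha, beta = beta,
                 k_d = kd, ec50 = kd, ligand_uM = ligand_uM),
            class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  if (is.finite(x$ligand_uM))
    cat(sprintf("bimolecular rate constants at %g uM ligand:\n", x$ligand_uM))
  else cat("bimolecular rate constants:\n")
  cat(sprintf("  k_on  %.3g s^-1   k_off %.3g s^-1\n", x$k_on, x$k_off))
  cat(sprintf("  alpha %.3g uM^-1 s^-1   beta %.3g s^-1\n", x$alpha, x$beta))
  cat(sprintf("  kd = beta/alpha = %.3g uM  (EC50 = kd = %.3g uM)\n",
              x$k_d, x$ec50))
  invisible(x)
}

#' Derive rate constants from wash-in/wash-out time constants
#'
#' Inverts the bimolecular scheme relations: the wash-out time constant
#' gives the dissociation rate (`k_off = beta = 1/tau_off`); the wash-in
#' time constant gives the observed rate (`1/tau_on = k_on + k_off`), so
#' `k_on = 1/tau_on - k_off`; the second-order association rate constant is
#' `alpha = k_on / L`; and the affinity is `kd = beta/alpha = EC50`.
#' Because `k_on > 0` whenever ligand is present, `tau_on < tau_off` is
#' required; equality or reversal means no detectable association.
#'
#' @param tau_on wash-in time constant, s (> 0).
#' @param tau_off wash-out time constant, s (> 0).
#' @param ligand_uM ligand concentration during wash-in, uM (> 0).
#' @return A [rate_constants()] object.
#' @export
#' @examples
#' derive_rate_constants(tau_on = 99.17, tau_off = 157.98, ligand_uM = 48)
derive_rate_constants <- function(tau_on, tau_off, ligand_uM) {
  check_number(tau_on, "tau_on", positive = TRUE)
  check_number(tau_off, "tau_off", positive = TRUE)
  check_number(ligand_uM, "ligand_uM", positive = TRUE)
  k_off <- 1 / tau_off
  if (tau_on >= tau_off)
    stop("no detectable association: tau_on (", tau_on,
         " s) must be smaller than tau_off (", tau_off, " s)", call. = FALSE)
  k_on <- 1 / tau_on - k_off
  alpha <- k_on / ligand_uM
  rate_constants(k_on = k_on, k_off = k_off, alpha = alpha, beta = k_off,
                 ligand_uM = ligand_uM)
}

#' Affinity from the second- and first-order rate constants
#'
#' `kd = beta / alpha`; under linear occupancy-response coupling the
#' half-maximal effective concentration equals the affinity, `EC50 = kd`.
#'
#' @param alpha second-order association rate constant, uM^-1 s^-1 (> 0).
#' @param beta first-order dissociation rate constant, s^-1 (> 0).
#' @return list with `k_d` and `ec50`, both in uM.
#' @export
#' @examples
#' kd_from_rates(7.82e-5, 6.33e-3)  # kd = 80.9 uM to 3 significant figures
kd_from_rates <- function(alpha, beta) {
  check_number(alpha, "alpha", positive = TRUE)
  check_number(beta, "beta", positive = TRUE)
  kd <- beta / alpha
  list(k_d = kd, ec50 = kd)
}

#' Percent change between two current magnitudes
#'
#' `100 * (amp_test - amp_control) / amp_control`. Positive values denote
#' enhancement, negative values block. Inputs are magnitudes (the sign
#' convention for inward current is handled upstream).
#'
#' @param amp_control control current magnitude, uA (> 0).
#' @param amp_test test current magnitude, uA (>= 0).
#' @return Percent change (numeric scalar).
#' @export
#' @examples
#' percent_change(1.000, 1.741)  #  +74.1 (enhancement)
#' percent_change(1.000, 0.865)  #  -13.5 (block)
percent_change <- function(amp_control, amp_test) {
  check_number(amp_control, "amp_control")
  check_number(amp_test, "amp_test", nonneg = TRUE)
  if (amp_control <= 0)
    stop("amp_control must be > 0 (magnitude)", call. = FALSE)
  100 * (amp_test - amp_control) / amp_control
}
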