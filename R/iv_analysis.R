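#' Ramp current-voltage curve
#'
#' Voltage-current pairs from a voltage ramp. Voltage must be strictly
#' increasing with at least 3 points.
#'
#' @param voltage_mV numeric, strictly increasing, millivolts.
#' @param current_uA numeric, microamperes, same length.
#' @param label free-text label (e.g. `"basal"`, `"ligand"`).
#' @return An object of class `iv_curve`: a data frame with columns
#'   `voltage_mV` and `current_uA` and a `label` attribute.
#' @export
iv_curve <- function(voltage_mV, current_uA, label = "") {
  voltage_mV <- as.numeric(voltage_mV)
  current_uA <- as.numeric(current_uA)
  if (length(voltage_mV) != length(current_uA))
    stop("voltage and current must have equal length", call. = FALSE)
  if (length(voltage_mV) < 3L)
    stop("an I-V curve needs at least 3 points", call. = FALSE)
  if (any(diff(voltage_mV) <= 0))
    stop("voltage must be strictly increasing", call. = FALSE)
  structure(data.frame(voltage_mV = voltage_mV, current_uA = current_uA),
            label = as.character(label), class = c("iv_curve", "data.frame"))
}

#' Reversal potential of an I-V curve
#'
#' Finds the zero-current crossing by linear interpolation between the
#' bracketing samples. When the curve crosses zero more than once (noise
#' near the reversal), the crossing nearest 0 mV is returned, matching the
#' high-K recording condition where the K+ reversal is expected near 0 mV.
#'
#' @param iv an [iv_curve()].
#' @return Reversal potential in millivolts.
#' @export
#' @examples
#' iv <- iv_curve(-5:5, 0.5 * (-5:5))
#' reversal_potential(iv)  # 0
reversal_potential <- function(iv) {
  stopifnot(inherits(iv, "iv_curve"))
  v <- iv$voltage_mV; i <- iv$current_uA
  cross_v <- numeric()
  exact <- which(i == 0)
  if (length(exact)) cross_v <- v[exact]
  j <- which(i[-length(i)] * i[-1L] < 0)
  if (length(j)) {
    # linear interpolation inside each bracketing pair
    vz <- v[j] - i[j] * (v[j + 1L] - v[j]) / (i[j + 1L] - i[j])
    cross_v <- c(cross_v, vz)
  }
  if (!length(cross_v))
    stop("no reversal in range: current does not change sign", call. = FALSE)
  cross_v[which.min(abs(cross_v))]
}

#' Chord conductance along an I-V curve
#'
#' g(V) = I(V) / (V - E_rev), converted to microsiemens
#' (uA/mV = 1000 uS). Points closer than 1 mV to the reversal potential are
#' masked as `NA` (the chord is undefined there).
#'
#' @param iv an [iv_curve()].
#' @param e_rev_mV reversal potential, mV (e.g. from [reversal_potential()]).
#' @return data frame with columns `voltage_mV` and `conductance_uS`.
#' @export
chord_conductance <- function(iv, e_rev_mV) {
  stopifnot(inherits(iv, "iv_curve"))
  check_number(e_rev_mV, "e_rev_mV")
  if (nrow(iv) == 0L) stop("empty I-V curve", call. = FALSE)
  dv <- iv$voltage_mV - e_rev_mV
  g <- ifelse(abs(dv) < 1, NA_real_, iv$current_uA / dv * 1000)
  data.frame(voltage_mV = iv$voltage_mV, conductance_uS = g)
}

#' Inward-rectification ratio curve (basal over ligand)
#'
#' Interpolates a basal and a ligand ramp curve onto a common 1 mV grid and
#' returns the pointwise ratio I_basal / I_ligand over the inward limb
#' (default -140 to -30 mV). For a ligand that scales conductance uniformly
#' the ratio is flat (constant < 1 for an activator); a voltage-dependent
#' ratio would indicate altered rectification.
#'
#' @param iv_basal,iv_ligand [iv_curve()] objects covering
#'   \[`v_min_mV`, `v_max_mV`\].
#' @param v_min_mV,v_max_mV analysis window, mV.
#' @return An object of class `rectification_curve`: data frame with
#'   columns `voltage_mV` (ascending 1 mV grid) and `ratio` (> 0).
#' @export
rectification_curve <- function(iv_basal, iv_ligand,
                                v_min_mV = -140, v_max_mV = -30) {
  stopifnot(inherits(iv_basal, "iv_curve"), inherits(iv_ligand, "iv_curve"))
  if (v_max_mV <= v_min_mV)
    stop("v_max_mV must exceed v_min_mV", call. = FALSE)
  for (iv in list(iv_basal, iv_ligand))
    if (min(iv$voltage_mV) > v_min_mV || max(iv$voltage_mV) < v_max_mV)
      stop(sprintf("I-V curve does not cover [%g, %g] mV", v_min_mV, v_max_mV),
           call. = FALSE)
  grid <- seq(v_min_mV, v_max_mV, by = 1)
  ib <- approx(iv_basal$voltage_mV, iv_basal$current_uA, xout = grid)$y
  il <- approx(iv_ligand$voltage_mV, iv_ligand$current_uA, xout = grid)$y
  if (any(il == 0) || any(il[-length(il)] * il[-1L] < 0))
    stop("ligand current crosses zero inside the analysis window; ",
         "ratio undefined", call. = FALSE)
  ratio <- ib / il
  if (any(ratio <= 0))
    stop("non-positive basal/ligand current ratio in the analysis window; ",
         "currents must share sign over the inward limb", call. = FALSE)
  structure(data.frame(voltage_mV = grid, ratio = ratio),
            class = c("rectification_curve", "data.frame"))
}
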