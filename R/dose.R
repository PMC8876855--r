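#' Build a concentration-response table from application traces
#'
#' For each trace the response is the ratio of ligand-evoked to basal
#' current magnitude, `|I_ligand| / |I_basal|`, taken from epoch-wise
#' plateau means. The plateau is the mean of the last `plateau_frac`
#' (default 20%) of the samples in each epoch, which avoids
#' solution-exchange transients. The basal epoch is the zero-ligand epoch
#' immediately preceding the ligand epoch (same bath, ligand added), the
#' ligand epoch is the epoch with the largest ligand concentration.
#'
#' @param traces list of [tevc_trace()] objects.
#' @param concentrations_uM ligand concentration per trace, uM (same
#'   length as `traces`); replicates at the same concentration allowed.
#' @param plateau_frac fraction of each epoch used for the plateau mean.
#' @return An object of class `dose_response`: data frame with columns
#'   `concentration_uM` and `response` (one row per trace, responses > 0,
#'   sorted by concentration).
#' @export
build_dose_response <- function(traces, concentrations_uM,
                                plateau_frac = 0.2) {
  if (length(traces) != length(concentrations_uM))
    stop("traces and concentrations_uM must have equal length", call. = FALSE)
  if (length(unique(concentrations_uM)) < 2L)
    stop("at least 2 distinct concentrations are required", call. = FALSE)
  if (any(concentrations_uM <= 0))
    stop("concentrations must be > 0", call. = FALSE)
  if (plateau_frac <= 0 || plateau_frac > 1)
    stop("plateau_frac must lie in (0, 1]", call. = FALSE)
  resp <- vapply(traces, function(tr) {
    validate_trace(tr)
    ep <- tr$epochs
    i_lig <- which.max(ep$ligand_uM)
    if (ep$ligand_uM[i_lig] <= 0)
      stop("metadata error: trace has no ligand epoch", call. = FALSE)
    prev <- which(seq_len(nrow(ep)) < i_lig & ep$ligand_uM == 0)
    if (!length(prev))
      stop("metadata error: no zero-ligand basal epoch precedes the ligand ",
           "epoch", call. = FALSE)
    i_bas <- max(prev)
    plateau <- function(i) {
      s <- epoch_samples(tr, i)
      start <- s$time_s[length(s$time_s)] -
        plateau_frac * (s$time_s[length(s$time_s)] - s$time_s[1L])
      mean(s$current_uA[s$time_s >= start])
    }
    abs(plateau(i_lig)) / abs(plateau(i_bas))
  }, numeric(1))
  o <- order(concentrations_uM)
  structure(data.frame(concentration_uM = as.numeric(concentrations_uM)[o],
                       response = resp[o]),
            class = c("dose_response", "data.frame"))
}

#' Fit a Hill concentration-response model
#'
#' Fits `response = 1 + Emax * L^n / (L^n + EC50^n)` by bounded
#' least squares. Responses are normalized current ratios
#' (`|I_ligand|/|I_basal|`, >= 1 for an activator). With fewer than 3
#' distinct concentrations the Hill coefficient is fixed at `n = 1` and
#' only `Emax` and `EC50` are fitted. A two-stage strategy is used: a
#' double-reciprocal linearization seeds an `n = 1` fit, which in turn
#' seeds the full three-parameter fit; bounds are `n` in \[0.2, 5\] and
#' `EC50` in \[min dose/100, max dose x 100\] (four-point curves are
#' under-determined, so bounded fits with explicit flags are preferred
#' over silent divergence). For a binding scheme with linear
#' occupancy-response coupling the true curve has `n = 1` and `EC50 = kd`.
#'
#' @param dr a [build_dose_response()] table (or any data frame with
#'   columns `concentration_uM` and `response`).
#' @return An object of class `hill_fit`: list with `emax`, `ec50_uM`,
#'   `n`, `degenerate` (flag: responses flat, no parameters reported),
#'   `rms_residual` and `n_fixed` (TRUE when the Hill coefficient was not
#'   fitted).
#' @export
fit_hill <- function(dr) {
  dr <- as.data.frame(dr)
  stopifnot(all(c("concentration_uM", "response") %in% names(dr)))
  L <- dr$concentration_uM; y <- dr$response
  if (any(L <= 0) || any(y <= 0))
    stop("concentrations and responses must be > 0", call. = FALSE)
  if (diff(range(y)) < 1e-8)
    return(structure(list(emax = NA_real_, ec50_uM = NA_real_, n = NA_real_,
                          degenerate = TRUE, rms_residual = NA_real_,
                          n_fixed = NA),
                     class = "hill_fit"))
  lo_ec <- min(L) / 100; hi_ec <- max(L) * 100
  # stage 0: double-reciprocal linearization of the n = 1 curve for starts
  ok <- y > 1 + 1e-9
  if (sum(ok) >= 2L) {
    fit0 <- stats::lm(I(1 / (y[ok] - 1)) ~ I(1 / L[ok]))
    emax0 <- 1 / coef(fit0)[[1L]]
    ec500 <- coef(fit0)[[2L]] * emax0
    if (!is.finite(emax0) || emax0 <= 0) emax0 <- max(y) - 1
    if (!is.finite(ec500) || ec500 <= lo_ec || ec500 >= hi_ec)
      ec500 <- exp(mean(log(range(L))))
  } else {
    emax0 <- max(max(y) - 1, 1e-3)
    ec500 <- exp(mean(log(range(L))))
  }
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                     ptol = 1e-14)
  # stage 1: n fixed at 1
  f1 <- minpack.lm::nlsLM(
    y ~ 1 + emax * L / (L + ec50), data = list(y = y, L = L),
    start = list(emax = emax0, ec50 = ec500),
    lower = c(emax = 0, ec50 = lo_ec), upper = c(emax = 100, ec50 = hi_ec),
    control = ctrl)
  c1 <- coef(f1)
  if (length(unique(L)) < 3L)
    return(structure(list(emax = unname(c1["emax"]),
                          ec50_uM = unname(c1["ec50"]), n = 1,
                          degenerate = FALSE,
                          rms_residual = sqrt(mean(residuals(f1)^2)),
                          n_fixed = TRUE),
                     class = "hill_fit"))
  # stage 2: free Hill coefficient
  f2 <- minpack.lm::nlsLM(
    y ~ 1 + emax * L^n / (L^n + ec50^n), data = list(y = y, L = L),
    start = list(emax = unname(c1["emax"]), ec50 = unname(c1["ec50"]), n = 1),
    lower = c(emax = 0, ec50 = lo_ec, n = 0.2),
    upper = c(emax = 100, ec50 = hi_ec, n = 5),
    control = ctrl)
  c2 <- coef(f2)
  structure(list(emax = unname(c2["emax"]), ec50_uM = unname(c2["ec50"]),
                 n = unname(c2["n"]), degenerate = FALSE,
                 rms_residual = sqrt(mean(residuals(f2)^2)), n_fixed = FALSE),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("Hill fit: degenerate (flat responses), no parameters reported\n")
  } else {
    cat(sprintf("Hill fit: Emax %.4g, EC50 %.4g uM, n %.3g%s (RMS %.3g)\n",
                x$emax, x$ec50_uM, x$n,
                if (isTRUE(x$n_fixed)) " [fixed]" else "", x$rms_residual))
  }
  invisible(x)
}

#' Welch's unpaired two-sample t-test
#'
#' Parametric unpaired t-test with Welch's correction:
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite
#' degrees of freedom and a two-tailed p-value from Student's t
#' distribution. Computed via [stats::t.test()] with `var.equal = FALSE`,
#' repackaged with explicit group summaries.
#'
#' @param group_a,group_b numeric vectors, each with at least 2 values and
#'   not both of zero variance.
#' @return An object of class `welch_result`: list with `t_stat`, `dof`,
#'   `p_value` and `group_summaries` (data frame: `n`, `mean`, `sd`).
#' @export
#' @examples
#' welch_t_test(c(1, 2, 3), c(2, 3, 4))
welch_t_test <- function(group_a, group_b) {
  for (g in list(group_a, group_b)) {
    if (!is.numeric(g) || length(g) < 2L)
      stop("insufficient data: each group needs at least 2 values",
           call. = FALSE)
    if (any(!is.finite(g)))
      stop("groups must contain only finite values", call. = FALSE)
  }
  if (sd(group_a) == 0 && sd(group_b) == 0)
    stop("degenerate input: both groups have zero variance", call. = FALSE)
  ht <- t.test(group_a, group_b, var.equal = FALSE)
  structure(list(
    t_stat = unname(ht$statistic), dof = unname(ht$parameter),
    p_value = ht$p.value,
    group_summaries = data.frame(
      group = c("a", "b"),
      n = c(length(group_a), length(group_b)),
      mean = c(mean(group_a), mean(group_b)),
      sd = c(sd(group_a), sd(group_b)))),
    class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch's t-test: t = %.4f, df = %.4g, two-tailed p = %.4g\n",
              x$t_stat, x$dof, x$p_value))
  print(x$group_summaries, row.names = FALSE)
  invisible(x)
}
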