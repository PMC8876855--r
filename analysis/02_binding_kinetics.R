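#!/usr/bin/env Rscript
# Wash-in/wash-out kinetics of the 48 uM application recording: fit single
# exponentials over the application and wash-out epochs, derive the
# bimolecular rate constants and the affinity, and compare with the
# worked example kd = beta/alpha at the reference rate constants.

suppressPackageStartupMessages(library(girktools))

path <- "results/application_48uM.csv"
if (!file.exists(path))
  stop("run analysis/01_simulate_recordings.R first", call. = FALSE)
tr <- read_trace(path)
print(tr)

ep <- tr$epochs
i_app <- which.max(ep$ligand_uM)
conc <- ep$ligand_uM[i_app]

fit_on <- fit_single_exponential(tr, c(ep$start_s[i_app], ep$end_s[i_app]),
                                 "rise")
fit_off <- fit_single_exponential(tr, c(ep$start_s[i_app + 1L],
                                        ep$end_s[i_app + 1L]), "decay")
print(fit_on); print(fit_off)

rc <- derive_rate_constants(fit_on$tau, fit_off$tau, ligand_uM = conc)
print(rc)

# ligand-evoked enhancement from the plateau magnitudes (last 20% of the
# basal and application epochs)
plateau <- function(trace, i) {
  t1 <- trace$epochs$end_s[i]
  t0 <- t1 - 0.2 * (t1 - trace$epochs$start_s[i])
  mean(trace$current_uA[trace$time_s >= t0 & trace$time_s <= t1])
}
enh <- percent_change(abs(plateau(tr, i_app - 1L)), abs(plateau(tr, i_app)))
message(sprintf("current enhancement at %g uM: %.1f%%", conc, enh))

ref <- kd_from_rates(7.82e-5, 6.33e-3)
message(sprintf(
  "reference worked example: kd = beta/alpha = %.3g uM (recovered %.3g uM)",
  signif(ref$k_d, 3), signif(rc$k_d, 3)))

utils::write.csv(
  data.frame(quantity = c("tau_on_s", "tau_off_s", "k_on_s1", "k_off_s1",
                          "alpha_uM1s1", "beta_s1", "kd_uM", "ec50_uM",
                          "enhancement_pct"),
             value = signif(c(fit_on$tau, fit_off$tau, rc$k_on, rc$k_off,
                              rc$alpha, rc$beta, rc$k_d, rc$ec50, enh), 4)),
  "results/kinetics_48uM.csv", row.names = FALSE)
message("wrote results/kinetics_48uM.csv")
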