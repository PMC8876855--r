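#!/usr/bin/env Rscript
# Generate the synthetic TEVC data set used by the downstream analyses:
# a 48 uM ligand application/wash-out recording at -90 mV in high-K bath,
# a basal/ligand voltage-ramp pair, and a Kv step-protocol trace.
# Ground-truth generator parameters are written next to each file.

suppressPackageStartupMessages(library(girktools))
dir.create("results", showWarnings = FALSE)

occ <- occupancy_model()   # alpha 7.82e-5 uM^-1 s^-1, beta 6.33e-3 s^-1
chan <- channel_model()    # g_max 10 uS, 96/96 mM K+, noise 5 nA, exchange 2 s
print(occ); print(chan)

# --- application recording: ND96 -> HK (basal) -> +48 uM -> wash-out -----
prot <- application_protocol(
  durations_s = c(30, 120, 800, 1300),
  solutions = c("ND96", "HK", "HK", "HK"),
  ligand_uM = c(0, 0, 48, 0))
tr <- simulate_application_trace(prot, occ, chan, holding_mV = -90,
                                 sample_rate_hz = 10, seed = 101)
write_trace(tr, "results/application_48uM.csv")
yaml::write_yaml(list(alpha = occ$alpha, beta = occ$beta,
                      efficacy = occ$efficacy, ligand_uM = 48, seed = 101,
                      sample_rate_hz = 10),
                 "results/application_48uM.truth.yaml")
message("wrote results/application_48uM.csv (+ sidecars): ",
        length(tr$time_s), " samples")

# --- ramp pair at the 48 uM equilibrium occupancy ------------------------
occ_eq <- 48 / (48 + occ$beta / occ$alpha)
pair <- simulate_ramp_pair(occ, chan, occupancy = occ_eq, seed = 102)
utils::write.csv(
  data.frame(voltage_mV = pair$basal$voltage_mV,
             basal_uA = pair$basal$current_uA,
             ligand_uA = pair$ligand$current_uA),
  "results/ramp_pair_48uM.csv", row.names = FALSE)
message(sprintf("wrote results/ramp_pair_48uM.csv (occupancy %.3f)", occ_eq))

# --- Kv step family: control and 13.5% blocked ---------------------------
for (bf in c(0, 0.135)) {
  kv <- simulate_kv_step(bf, chan, seed = 103)
  write_trace(kv, sprintf("results/kv_step_block%03.0f.csv", 1000 * bf))
}
message("wrote results/kv_step_block000.csv and kv_step_block135.csv")
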