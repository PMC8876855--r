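# shared fixtures: generator settings used across the suite

# paper-scale binding parameters: kd = beta/alpha = 80.9 uM
default_occ <- function(...) occupancy_model(...)

noiseless_chan <- function(exchange_tau_s = 0, ...) {
  channel_model(noise_sd_uA = 0, exchange_tau_s = exchange_tau_s, ...)
}

# basal HK epoch, ligand application, wash-out (durations in seconds)
wash_protocol <- function(t_basal = 50, t_app = 600, t_wash = 800,
                          conc_uM = 48) {
  application_protocol(c(t_basal, t_app, t_wash), c("HK", "HK", "HK"),
                       c(0, conc_uM, 0))
}

synthetic_kunitz <- function() {
  read_fasta(system.file("extdata", "synthetic_kunitz59.fasta",
                         package = "girktools"), n_disulfides = 3)[[1L]]
}

# occupancy time course implied by a noiseless trace (inverts the linear
# occupancy-response coupling)
occupancy_from_trace <- function(trace, occ, basal_uA) {
  (trace$current_uA / basal_uA - 1) / occ$efficacy
}

# monoisotopic atomic masses for the from-scratch composition oracle
ATOM_MONO <- c(C = 12, H = 1.00782503207, N = 14.0030740052,
               O = 15.9949146221, S = 31.97207069)

# independent elemental-composition mass: atom counts per residue summed
# against atomic masses, plus one water
composition_mass <- function(residues) {
  tab <- mass_table()$residues
  rownames(tab) <- tab$residue
  letters_ <- strsplit(residues, "")[[1L]]
  atoms <- colSums(tab[letters_, c("C", "H", "N", "O", "S"), drop = FALSE])
  atoms["H"] <- atoms["H"] + 2
  atoms["O"] <- atoms["O"] + 1
  sum(atoms * ATOM_MONO[names(atoms)])
}

random_peptide <- function(n) {
  paste(sample(mass_table()$residues$residue, n, replace = TRUE),
        collapse = "")
}
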