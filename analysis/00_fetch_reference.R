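#!/usr/bin/env Rscript
# Optional, network-requiring helper: download the UniProt entry for the
# mature venom Kunitz peptide (accession P0DN15) and report its computed
# masses. Everything else in this repository runs fully offline; when the
# download is unavailable the workflow falls back to the bundled synthetic
# Kunitz-scale stand-in (inst/extdata/synthetic_kunitz59.fasta).

suppressPackageStartupMessages(library(girktools))

url <- "https://rest.uniprot.org/uniprotkb/P0DN15.fasta"
dest <- file.path("results", "P0DN15.fasta")
dir.create("results", showWarnings = FALSE)

ok <- tryCatch({
  suppressWarnings(download.file(url, dest, quiet = TRUE))
  file.exists(dest) && file.size(dest) > 0
}, error = function(e) FALSE, warning = function(w) FALSE)

if (!ok) {
  message("UniProt is not reachable from this machine; skipping. ",
          "Analyses use the bundled synthetic stand-in instead.")
  quit(status = 0)
}

pep <- read_fasta(dest, n_disulfides = 3)[[1L]]
message(sprintf("fetched %d-residue sequence", nchar(pep$residues)))
message(sprintf("monoisotopic mass (3 disulfides): %.2f Da",
                peptide_mass(pep, "monoisotopic")))
message(sprintf("average mass      (3 disulfides): %.1f Da",
                peptide_mass(pep, "average")))
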