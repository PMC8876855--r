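#' Mass-spectrometry peak list
#'
#' A minimal centroided peak list: ascending m/z (Thomson) with non-negative
#' intensities. Input order is normalized by sorting on m/z.
#'
#' @param mz numeric vector of m/z values (Th).
#' @param intensity numeric vector of intensities (arbitrary units, >= 0).
#' @return An object of class `peak_list`: a data frame with columns `mz`
#'   and `intensity`, sorted ascending by `mz`. May have zero rows.
#' @export
#' @examples
#' peak_list(c(200.0, 100.0), c(3, 5))
peak_list <- function(mz = numeric(), intensity = numeric()) {
  mz <- as.numeric(mz); intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length", call. = FALSE)
  if (any(!is.finite(mz)) || any(!is.finite(intensity)))
    stop("mz and intensity must be finite", call. = FALSE)
  if (any(mz <= 0)) stop("mz values must be > 0", call. = FALSE)
  if (any(intensity < 0))
    stop("negative intensity is not allowed", call. = FALSE)
  o <- order(mz)
  structure(data.frame(mz = mz[o], intensity = intensity[o]),
            class = c("peak_list", "data.frame"))
}

#' Read and write two-column peak lists
#'
#' Plain-text peak lists with one peak per line, m/z then intensity,
#' separated by whitespace and/or a comma. Blank lines and lines starting
#' with `#` are ignored. An empty file yields a valid empty [peak_list()].
#'
#' @param path file path.
#' @return `read_peaklist()` returns a [peak_list()]; `write_peaklist()`
#'   returns `path` invisibly.
#' @export
read_peaklist <- function(path) {
  if (!file.exists(path)) stop("peak list not found: ", path, call. = FALSE)
  ln <- trimws(readLines(path, warn = FALSE))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (!length(ln)) return(peak_list())
  parts <- strsplit(ln, "[,[:space:]]+")
  ncol_bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(ncol_bad))
    stop(sprintf("peak list format error at line %d: expected 2 columns",
                 ncol_bad[1L]), call. = FALSE)
  m <- suppressWarnings(vapply(parts, function(p) as.numeric(p[1L]), 1.0))
  i <- suppressWarnings(vapply(parts, function(p) as.numeric(p[2L]), 1.0))
  if (any(is.na(m)) || any(is.na(i)))
    stop("peak list contains non-numeric values", call. = FALSE)
  peak_list(m, i)
}

#' @rdname read_peaklist
#' @param peaks a [peak_list()].
#' @export
write_peaklist <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_list"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(peaks))
    writeLines(sprintf("%.15g %.15g", peaks$mz, peaks$intensity), con)
  invisible(path)
}

#' Read peptide sequences from FASTA
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] returning validated
#' [peptide_sequence()] objects. Disulfide counts and modifications are not
#' part of FASTA; supply them here (applied to every record).
#'
#' @param path FASTA file path.
#' @param n_disulfides number of disulfide bridges to annotate on each
#'   record (default 0).
#' @return Named list of [peptide_sequence()] objects.
#' @export
read_fasta <- function(path, n_disulfides = 0) {
  if (!file.exists(path)) stop("FASTA not found: ", path, call. = FALSE)
  aa <- Biostrings::readAAStringSet(path)
  out <- lapply(as.character(aa), peptide_sequence,
                n_disulfides = n_disulfides)
  names(out) <- names(aa)
  out
}

#' @rdname read_fasta
#' @param seqs named list of [peptide_sequence()] objects (or a single one).
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "peptide_sequence")) seqs <- list(peptide = seqs)
  stopifnot(all(vapply(seqs, inherits, TRUE, "peptide_sequence")))
  nm <- names(seqs)
  if (is.null(nm)) nm <- paste0("peptide", seq_along(seqs))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", nm[i]), con)
    writeLines(seqs[[i]]$residues, con)
  }
  invisible(path)
}
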