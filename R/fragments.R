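#' Theoretical backbone fragment-ion ladders
#'
#' Computes b/y (collision-induced) and c/z (in-source decay / ETD-type)
#' fragment ions for every backbone cleavage site (index 1..len-1) at
#' charges 1..`max_charge`. Conventions: `c = b + NH3`; z ions are reported
#' as the z+1 radical (z-dot) species standard for MALDI-ISD spectra
#' (switchable to classical z via `zdot = FALSE`). m/z is
#' `(neutral + charge * proton) / charge`.
#'
#' When the peptide carries disulfide bridges, a backbone cleavage that
#' potentially severs a bridged cysteine pair (cysteines on both sides of
#' the cut) yields a fragment whose mass depends on the unknown bridge
#' topology; such ions are flagged `crosslink_ambiguous` and their m/z is
#' `NA` rather than a guessed value.
#'
#' @param seq a [peptide_sequence()] of length >= 2.
#' @param series character subset of `c("b", "y", "c", "z")`.
#' @param max_charge maximal charge state (>= 1).
#' @param zdot logical; report z+1 (z-dot) ions (default `TRUE`).
#' @return data frame with columns `series`, `index`, `charge`, `mz`,
#'   `crosslink_ambiguous`; exactly `len - 1` rows per series per charge.
#' @export
#' @examples
#' fragment_ions(peptide_sequence("GG"), series = "b")  # b1 = 58.0287 Th
fragment_ions <- function(seq, series = c("b", "y", "c", "z"),
                          max_charge = 1, zdot = TRUE) {
  stopifnot(inherits(seq, "peptide_sequence"))
  series <- match.arg(series, several.ok = TRUE)
  check_number(max_charge, "max_charge", positive = TRUE)
  letters_ <- strsplit(seq$residues, "")[[1L]]
  n <- length(letters_)
  if (n < 2L)
    stop("no fragments: sequence must contain at least 2 residues",
         call. = FALSE)
  res <- residue_masses(seq, "monoisotopic")
  prefix <- cumsum(res)[-n]          # b/c index i: residues 1..i
  suffix <- cumsum(rev(res))[-n]     # y/z index j: last j residues
  # cleavage at site i severs a potential bridge if Cys occur on both sides
  cys_prefix <- cumsum(letters_ == "C")[-n]
  n_cys <- sum(letters_ == "C")
  ambiguous <- seq$n_disulfides > 0 &
    cys_prefix > 0 & (n_cys - cys_prefix) > 0
  # y/z index j corresponds to backbone site n - j
  ambiguous_ct <- rev(ambiguous)

  neutral <- list(
    b = prefix + seq$nterm_mod,
    c = prefix + seq$nterm_mod + .MASS$nh3_mono,
    y = suffix + .MASS$water_mono + seq$cterm_mod,
    z = suffix + .MASS$water_mono + seq$cterm_mod - .MASS$nh3_mono +
      if (zdot) .MASS$h_mono else 0)

  out <- do.call(rbind, lapply(series, function(s) {
    amb <- if (s %in% c("b", "c")) ambiguous else ambiguous_ct
    do.call(rbind, lapply(seq_len(max_charge), function(z) {
      mz <- (neutral[[s]] + z * .MASS$proton) / z
      mz[amb] <- NA_real_
      data.frame(series = s, index = seq_len(n - 1L), charge = z, mz = mz,
                 crosslink_ambiguous = amb)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to lysine (K) or arginine (R) except when the next
#' residue is proline (the Keil rule), and enumerates products with up to
#' `missed_cleavages` internal missed sites. Products are returned as
#' [peptide_sequence()] objects with `n_disulfides = 0` (digestion follows
#' reduction/alkylation in the standard workflow); fixed modifications are
#' inherited and terminal modifications stay on the original termini.
#' Concatenating the zero-missed-cleavage products reconstructs the input.
#'
#' @param seq a [peptide_sequence()].
#' @param missed_cleavages 0, 1 or 2.
#' @return list of [peptide_sequence()] products, N- to C-terminal order,
#'   fully cleaved products first, then products with 1, 2, ... missed
#'   sites.
#' @export
#' @examples
#' sapply(tryptic_digest(peptide_sequence("AKRPC")), `[[`, "residues")
tryptic_digest <- function(seq, missed_cleavages = 0) {
  stopifnot(inherits(seq, "peptide_sequence"))
  if (!missed_cleavages %in% 0:2)
    stop("missed_cleavages must be 0, 1 or 2", call. = FALSE)
  letters_ <- strsplit(seq$residues, "")[[1L]]
  n <- length(letters_)
  sites <- which(letters_[-n] %in% c("K", "R") & letters_[-1L] != "P")
  bounds <- c(0L, sites, n)          # fragment k spans bounds[k]+1..bounds[k+1]
  n_frag <- length(bounds) - 1L
  out <- list()
  for (mc in 0:missed_cleavages) {
    for (k in seq_len(n_frag - mc)) {
      from <- bounds[k] + 1L
      to <- bounds[k + mc + 1L]
      out[[length(out) + 1L]] <- peptide_sequence(
        paste(letters_[from:to], collapse = ""),
        n_disulfides = 0, fixed_mods = seq$fixed_mods,
        nterm_mod = if (from == 1L) seq$nterm_mod else 0,
        cterm_mod = if (to == n) seq$cterm_mod else 0)
    }
  }
  out
}

#' Match observed peaks against a theoretical fragment ladder
#'
#' Greedy nearest-match within a tolerance: theoretical ions are processed
#' in order of ascending m/z and each observed peak is used at most once.
#' The tolerance is relative (`tol_ppm`) by default; an absolute dalton
#' tolerance (`tol_da`) can be used instead for low-resolution
#' (MALDI linear mode) spectra. Ions with undefined m/z
#' (crosslink-ambiguous) are excluded from matching but still count in the
#' denominator of nothing: coverage is per backbone cleavage site.
#'
#' @param theoretical data frame from [fragment_ions()].
#' @param observed a [peak_list()].
#' @param tol_ppm relative matching tolerance, parts per million (> 0).
#' @param tol_da optional absolute tolerance in Da; overrides `tol_ppm`.
#' @return An object of class `peak_match`: list with `matches` (data
#'   frame: `series`, `index`, `charge`, `mz_theoretical`, `mz_observed`,
#'   `ppm_error`), `n_matched`, `n_theoretical` (ions with defined m/z),
#'   `coverage` (fraction of the `len - 1` backbone sites supported by at
#'   least one matched ion) and `n_sites`.
#' @export
match_peaks <- function(theoretical, observed, tol_ppm = 10, tol_da = NULL) {
  stopifnot(is.data.frame(theoretical),
            all(c("series", "index", "charge", "mz") %in% names(theoretical)),
            inherits(observed, "peak_list"))
  if (is.null(tol_da)) check_number(tol_ppm, "tol_ppm", positive = TRUE)
  else check_number(tol_da, "tol_da", positive = TRUE)
  n_sites <- if (nrow(theoretical)) max(theoretical$index) else 0L
  theo <- theoretical[!is.na(theoretical$mz), , drop = FALSE]
  theo <- theo[order(theo$mz), , drop = FALSE]
  used <- rep(FALSE, nrow(observed))
  hit <- integer(nrow(theo))
  for (i in seq_len(nrow(theo))) {
    tol <- if (is.null(tol_da)) theo$mz[i] * tol_ppm * 1e-6 else tol_da
    d <- abs(observed$mz - theo$mz[i])
    d[used] <- Inf
    j <- if (nrow(observed)) which.min(d) else integer()
    hit[i] <- if (length(j) && d[j] <= tol) {
      used[j] <- TRUE; j
    } else NA_integer_
  }
  ok <- !is.na(hit)
  matches <- data.frame(
    series = theo$series[ok], index = theo$index[ok],
    charge = theo$charge[ok], mz_theoretical = theo$mz[ok],
    mz_observed = observed$mz[hit[ok]],
    ppm_error = (observed$mz[hit[ok]] - theo$mz[ok]) / theo$mz[ok] * 1e6)
  # backbone site i (counted from the N-terminus) is evidenced by an
  # N-terminal ion (b/c) of index i or a C-terminal ion (y/z) of index n - i
  site <- ifelse(matches$series %in% c("b", "c"), matches$index,
                 n_sites + 1L - matches$index)
  covered <- unique(site)
  structure(list(matches = matches, n_matched = sum(ok),
                 n_theoretical = nrow(theo),
                 coverage = if (n_sites) length(covered) / n_sites else 0,
                 n_sites = n_sites),
            class = "peak_match")
}

#' @export
print.peak_match <- function(x, ...) {
  cat(sprintf(
    "peak match: %d / %d theoretical ions matched, site coverage %.1f%% (%d sites)\n",
    x$n_matched, x$n_theoretical, 100 * x$coverage, x$n_sites))
  if (x$n_matched)
    cat(sprintf("  |ppm error| median %.2f, max %.2f\n",
                median(abs(x$matches$ppm_error)),
                max(abs(x$matches$ppm_error))))
  invisible(x)
}
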