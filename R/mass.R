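# Residue masses (peptide-bond residues, i.e. amino acid minus water), Da.
# Monoisotopic values are the standard proteomics constants derived from
# IUPAC/CODATA atomic masses; average values use standard atomic weights.
.AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

.AA_AVG <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)

# elemental composition of each residue (C, H, N, O, S atom counts); used
# for documentation and by independent verification code paths
.AA_FORMULA <- matrix(c(
  # C  H  N  O  S
    2, 3, 1, 1, 0,  # G
    3, 5, 1, 1, 0,  # A
    3, 5, 1, 2, 0,  # S
    5, 7, 1, 1, 0,  # P
    5, 9, 1, 1, 0,  # V
    4, 7, 1, 2, 0,  # T
    3, 5, 1, 1, 1,  # C
    6, 11, 1, 1, 0, # L
    6, 11, 1, 1, 0, # I
    4, 6, 2, 2, 0,  # N
    4, 5, 1, 3, 0,  # D
    5, 8, 2, 2, 0,  # Q
    6, 12, 2, 1, 0, # K
    5, 7, 1, 3, 0,  # E
    5, 9, 1, 1, 1,  # M
    6, 7, 3, 1, 0,  # H
    9, 9, 1, 1, 0,  # F
    6, 12, 4, 1, 0, # R
    9, 9, 1, 2, 0,  # Y
    11, 10, 2, 1, 0 # W
  ), ncol = 5, byrow = TRUE,
  dimnames = list(names(.AA_MONO), c("C", "H", "N", "O", "S")))

# shared mass constants, Da
.MASS <- list(
  proton = 1.00727646688,
  h_mono = 1.00782503207, h_avg = 1.00794,
  water_mono = 18.0105646863, water_avg = 18.01528,
  nh3_mono = 17.02654910, nh3_avg = 17.03052,
  carbamidomethyl = 57.02146)

#' Amino-acid mass table
#'
#' Per-residue monoisotopic and average masses (Da) for the 20 canonical
#' residues, plus the shared constants (water, proton, NH3, hydrogen). The
#' table is a snapshot of the standard values; it cannot be altered at
#' runtime.
#'
#' @return list with `residues` (data frame: `residue`, `monoisotopic`,
#'   `average`, and C/H/N/O/S atom counts) and `constants` (named list of
#'   Da values).
#' @export
mass_table <- function() {
  list(residues = data.frame(residue = names(.AA_MONO),
                             monoisotopic = unname(.AA_MONO),
                             average = unname(.AA_AVG),
                             .AA_FORMULA, row.names = NULL),
       constants = .MASS)
}

#' Peptide sequence with disulfides and modifications
#'
#' @param residues one-letter amino-acid string (20 canonical letters).
#' @param n_disulfides number of disulfide bridges (>= 0, at most
#'   `floor(#Cys / 2)`). Each bridge removes two hydrogens from the mass.
#' @param fixed_mods named numeric vector of fixed modifications: residue
#'   letter -> mass delta in Da, applied at every occurrence (e.g.
#'   `c(C = 57.02146)` for carbamidomethylation). A modified cysteine
#'   cannot also form a disulfide, so cysteine fixed modifications are
#'   rejected when `n_disulfides > 0`.
#' @param nterm_mod,cterm_mod terminal mass deltas in Da (default 0 = free
#'   termini).
#' @return An object of class `peptide_sequence`.
#' @seealso [peptide_mass()], [fragment_ions()], [tryptic_digest()]
#' @export
#' @examples
#' peptide_sequence("GCCG", n_disulfides = 1)
peptide_sequence <- function(residues, n_disulfides = 0, fixed_mods = NULL,
                             nterm_mod = 0, cterm_mod = 0) {
  if (!is.character(residues) || length(residues) != 1L || !nzchar(residues))
    stop("residues must be a non-empty one-letter string", call. = FALSE)
  residues <- toupper(residues)
  letters_ <- strsplit(residues, "")[[1L]]
  bad <- setdiff(unique(letters_), names(.AA_MONO))
  if (length(bad))
    stop("unknown residue letter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  check_number(n_disulfides, "n_disulfides", nonneg = TRUE)
  if (n_disulfides != trunc(n_disulfides))
    stop("n_disulfides must be an integer count", call. = FALSE)
  n_cys <- sum(letters_ == "C")
  if (n_disulfides > floor(n_cys / 2))
    stop(sprintf(
      "n_disulfides (%d) exceeds the available cysteine pairs (%d Cys)",
      n_disulfides, n_cys), call. = FALSE)
  if (!is.null(fixed_mods)) {
    if (is.null(names(fixed_mods)) || !is.numeric(fixed_mods))
      stop("fixed_mods must be a named numeric vector", call. = FALSE)
    bad <- setdiff(names(fixed_mods), names(.AA_MONO))
    if (length(bad))
      stop("fixed_mods on unknown residue(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    if ("C" %in% names(fixed_mods) && n_disulfides > 0)
      stop("a cysteine fixed modification is incompatible with disulfide ",
           "bridges; reduce (n_disulfides = 0) before alkylating",
           call. = FALSE)
  }
  check_number(nterm_mod, "nterm_mod"); check_number(cterm_mod, "cterm_mod")
  structure(list(residues = residues, n_disulfides = as.integer(n_disulfides),
                 fixed_mods = fixed_mods, nterm_mod = nterm_mod,
                 cterm_mod = cterm_mod),
            class = "peptide_sequence")
}

#' @export
print.peptide_sequence <- function(x, ...) {
  cat(sprintf("peptide: %d residues, %d disulfide bridge(s)\n",
              nchar(x$residues), x$n_disulfides))
  cat(" ", x$residues, "\n")
  if (!is.null(x$fixed_mods))
    cat(sprintf("  fixed mods: %s\n",
                paste(sprintf("%s%+.5f", names(x$fixed_mods), x$fixed_mods),
                      collapse = ", ")))
  if (x$nterm_mod != 0 || x$cterm_mod != 0)
    cat(sprintf("  terminal mods: N %+.5f, C %+.5f Da\n",
                x$nterm_mod, x$cterm_mod))
  invisible(x)
}

# per-position residue masses including fixed modifications
residue_masses <- function(seq, kind = c("monoisotopic", "average")) {
  kind <- match.arg(kind)
  tab <- if (kind == "monoisotopic") .AA_MONO else .AA_AVG
  letters_ <- strsplit(seq$residues, "")[[1L]]
  m <- unname(tab[letters_])
  if (!is.null(seq$fixed_mods))
    for (res in names(seq$fixed_mods))
      m[letters_ == res] <- m[letters_ == res] + seq$fixed_mods[[res]]
  m
}

#' Neutral mass of a peptide
#'
#' Sum of residue masses plus one water (the intact-chain termini), plus
#' terminal and fixed modifications, minus two hydrogens per disulfide
#' bridge.
#'
#' @param seq a [peptide_sequence()].
#' @param kind `"monoisotopic"` or `"average"`.
#' @return Neutral mass in daltons.
#' @export
#' @examples
#' peptide_mass(peptide_sequence("G"))    # 75.0320 Da
#' peptide_mass(peptide_sequence("GG"))   # 132.0535 Da
peptide_mass <- function(seq, kind = c("monoisotopic", "average")) {
  stopifnot(inherits(seq, "peptide_sequence"))
  kind <- match.arg(kind)
  water <- if (kind == "monoisotopic") .MASS$water_mono else .MASS$water_avg
  h <- if (kind == "monoisotopic") .MASS$h_mono else .MASS$h_avg
  sum(residue_masses(seq, kind)) + water + seq$nterm_mod + seq$cterm_mod -
    2 * h * seq$n_disulfides
}

#' Reduce and alkylate a peptide
#'
#' Models the standard reduce-and-alkylate sample preparation: disulfide
#' bridges are opened (`n_disulfides` set to 0, restoring the two
#' hydrogens per bridge) and every cysteine is carbamidomethylated
#' (+57.02146 Da).
#'
#' @param seq a [peptide_sequence()].
#' @return A modified [peptide_sequence()].
#' @export
reduce_alkylate <- function(seq) {
  stopifnot(inherits(seq, "peptide_sequence"))
  mods <- seq$fixed_mods
  if (!is.null(mods) && "C" %in% names(mods))
    stop("cysteines already carry a fixed modification", call. = FALSE)
  mods <- c(mods, c(C = .MASS$carbamidomethyl))
  peptide_sequence(seq$residues, n_disulfides = 0, fixed_mods = mods,
                   nterm_mod = seq$nterm_mod, cterm_mod = seq$cterm_mod)
}
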