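# Sequence-level protein properties: molecular weight, 280 nm extinction,
# concentration conversion, Henderson-Hasselbalch net charge and pI.

# average residue (amino-acid minus water) masses, Da
.RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.WATER_MASS <- 18.01524

#' Protein sequence
#'
#' @param id Identifier text.
#' @param residues One-letter amino-acid string (the 20 standard letters),
#'   length >= 1. Lower case is accepted and upcased.
#' @return An object of class `"protein_sequence"` with elements `id` and
#'   `residues`.
#' @export
protein_sequence <- function(id, residues) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  residues <- toupper(gsub("[[:space:]]", "", residues))
  if (nchar(residues) < 1L) stop("protein_sequence: empty sequence")
  letters_seq <- strsplit(residues, "")[[1]]
  bad <- setdiff(unique(letters_seq), names(.RESIDUE_MASS))
  if (length(bad))
    stop("protein_sequence: non-standard residue letter(s): ",
         paste(bad, collapse = ", "))
  structure(list(id = id, residues = residues), class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("Protein sequence %s: %d residues\n", x$id, nchar(x$residues)))
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A list of [protein_sequence()] objects, named by FASTA id.
#' @export
read_protein_fasta <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             set.attributes = FALSE)
  out <- lapply(names(seqs), function(nm) protein_sequence(nm, seqs[[nm]]))
  names(out) <- names(seqs)
  out
}

.aa_counts <- function(seq) {
  stopifnot(inherits(seq, "protein_sequence"))
  tab <- table(strsplit(seq$residues, "")[[1]])
  counts <- stats::setNames(rep(0L, length(.RESIDUE_MASS)),
                            names(.RESIDUE_MASS))
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Molecular weight of a protein
#'
#' Sum of average residue masses plus one water (equivalently, the free
#' amino-acid masses minus one water per peptide bond).
#'
#' @param seq A [protein_sequence()].
#' @return Molecular weight (Da).
#' @examples
#' molecular_weight(protein_sequence("gly", "G"))  # 75.07, free glycine
#' @export
molecular_weight <- function(seq) {
  counts <- .aa_counts(seq)
  sum(counts * .RESIDUE_MASS) + .WATER_MASS
}

#' Molar extinction coefficient and E_1% at 280 nm
#'
#' Pace convention (as used by the ExPASy ProtParam tool):
#' `epsilon = 5500 * n_Trp + 1490 * n_Tyr + 125 * n_cystine` (1/(M cm)),
#' with all cysteines reduced by default (`n_cystine = 0`).
#' `E_1%` is the absorbance of a 1 g / 100 mL solution in a 1 cm cell:
#' `10 * epsilon / MW`.
#'
#' @param seq A [protein_sequence()].
#' @param n_cystine Number of disulfide-bonded cystine pairs (default 0).
#' @return List with `epsilon` (1/(M cm)) and `E_1pct` ((g/100 mL)^-1 cm^-1).
#' @export
extinction_280 <- function(seq, n_cystine = 0) {
  counts <- .aa_counts(seq)
  if (n_cystine < 0 || 2 * n_cystine > counts[["C"]])
    stop("extinction_280: n_cystine must be >= 0 and use at most all Cys")
  eps <- 5500 * counts[["W"]] + 1490 * counts[["Y"]] + 125 * n_cystine
  list(epsilon = eps, E_1pct = 10 * eps / molecular_weight(seq))
}

#' Mass concentration to molar concentration
#'
#' @param conc_mg_ml Concentration in mg/mL.
#' @param mw_da Molecular weight in Da (g/mol).
#' @return Concentration in mM.
#' @examples
#' mass_to_molar(7, 16951)   # ~0.4 mM
#' @export
mass_to_molar <- function(conc_mg_ml, mw_da) {
  stopifnot(is.numeric(conc_mg_ml), is.numeric(mw_da))
  if (any(mw_da <= 0)) stop("mass_to_molar: mw_da must be > 0")
  conc_mg_ml / mw_da * 1000
}

#' Default side-chain and terminal pKa values
#'
#' A single documented, overridable table of pKa values used by
#' [net_charge()] and [isoelectric_point()]: the Bjellqvist set used by the
#' ExPASy Compute pI/MW tool (the same convention family as the
#' [extinction_280()] coefficients). Computed charges and the isoelectric
#' point depend on this choice; alternative tables can be passed as a named
#' vector with the same names.
#'
#' @return Named numeric vector with entries `D`, `E`, `H`, `C`, `Y`, `K`,
#'   `R`, `N_term`, `C_term` (pH units).
#' @export
default_pka_set <- function() {
  c(D = 4.05, E = 4.45, H = 5.98, C = 9.0, Y = 10.0,
    K = 10.0, R = 12.0, N_term = 7.5, C_term = 3.55)
}

.check_pka <- function(pka) {
  req <- names(default_pka_set())
  miss <- setdiff(req, names(pka))
  if (length(miss))
    stop("pka set is missing entries: ", paste(miss, collapse = ", "))
  if (any(pka <= 0) || any(pka >= 14))
    stop("pka values must lie in (0, 14)")
  pka
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch titration sum over basic groups (Lys, Arg, His and
#' the N-terminus, each contributing `1 / (1 + 10^(pH - pKa))`) minus acidic
#' groups (Asp, Glu, Cys, Tyr and the C-terminus, each contributing
#' `1 / (1 + 10^(pKa - pH))`).
#'
#' @param seq A [protein_sequence()].
#' @param pH Solution pH (vectorized).
#' @param pka Named pKa vector, see [default_pka_set()].
#' @return Net charge in elementary charges, same length as `pH`.
#' @export
net_charge <- function(seq, pH, pka = default_pka_set()) {
  counts <- .aa_counts(seq)
  pka <- .check_pka(pka)
  stopifnot(is.numeric(pH))
  basic <- c(K = counts[["K"]], R = counts[["R"]], H = counts[["H"]],
             N_term = 1)
  acidic <- c(D = counts[["D"]], E = counts[["E"]], C = counts[["C"]],
              Y = counts[["Y"]], C_term = 1)
  vapply(pH, function(p) {
    pos <- sum(basic / (1 + 10^(p - pka[names(basic)])))
    neg <- sum(acidic / (1 + 10^(pka[names(acidic)] - p)))
    pos - neg
  }, numeric(1))
}

#' Isoelectric point
#'
#' Root of [net_charge()] in pH on [0, 14], found by bisection
#' ([stats::uniroot()]) to 1e-6 pH units.
#'
#' @inheritParams net_charge
#' @return The pI (pH units).
#' @export
isoelectric_point <- function(seq, pka = default_pka_set()) {
  f <- function(p) net_charge(seq, p, pka)
  lo <- f(0); hi <- f(14)
  if (sign(lo) == sign(hi))
    stop("isoelectric_point: net charge does not change sign on [0, 14]")
  stats::uniroot(f, c(0, 14), tol = 1e-8)$root
}
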