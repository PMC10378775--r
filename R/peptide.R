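#' @importFrom stats median quantile rnorm runif rpois sd setNames complete.cases
#' @importFrom utils read.table write.table head modifyList
NULL

## Monoisotopic residue masses (Da) for the 20 standard amino acids.
## These are residue (i.e. dehydrated) masses; a free-acid peptide adds one water.
AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

MASS_H2O     <- 18.0105646
MASS_PROTON  <- 1.00727646
MASS_H       <- 1.00782503
MASS_NH3     <- 17.0265491
MASS_ZN      <- 63.92914        # monoisotopic 64Zn
## C-terminal amidation replaces the terminal OH by NH2
MASS_AMIDE_CORRECTION <- -0.9840156
MASS_PHOSPHO <- 79.9663305

## Zinc adduct bookkeeping: each bound Zn(2+) displaces two protons, so the
## neutral mass shift per zinc is Zn - 2H (charge is carried by protons).
MASS_ZN_ADDUCT <- MASS_ZN - 2 * MASS_H

## Canonical human amyloid-beta 1-16 (the metal-binding domain).
AB16_SEQUENCE <- "DAEFRHDSGYEVHHQK"

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
AA1TO3 <- setNames(names(AA3TO1), unname(AA3TO1))

## Residue types chemically able to chelate Zn(2+) through their side chains.
## Gly and Ala (and similar aliphatic residues) cannot chelate.
DEFAULT_CHELATION_SET <- c("D", "E", "H", "C", "M", "Y")

KNOWN_VARIANTS <- c("WT", "D7H", "isoD7", "pS8", "H6R", "custom")

#' Construct a validated peptide
#'
#' Builds a peptide object in 1-based amyloid-beta numbering, applying a named
#' variant and/or explicit point mutations to the supplied sequence.  The study
#' variants of the metal-binding domain are derived from the canonical human
#' fragment 1-16 (\code{DAEFRHDSGYEVHHQK}): \code{D7H} substitutes His for Asp
#' at position 7 (Taiwan mutation), \code{isoD7} flags isomerization of Asp7 to
#' isoaspartate (isobaric, mass unchanged), \code{H6R} is the English mutation
#' and \code{pS8} phosphorylates Ser8.
#'
#' @param sequence Character scalar of one-letter amino-acid codes.
#' @param variant One of \code{"WT"}, \code{"D7H"}, \code{"isoD7"},
#'   \code{"pS8"}, \code{"H6R"}, \code{"custom"}.
#' @param point_mutations Named character vector mapping 1-based positions to
#'   replacement residues, e.g. \code{c("11" = "A")} for E11A.
#' @param c_terminal_amide Logical; all study peptides are C-terminally
#'   amidated, so the default is \code{TRUE}.
#' @param n_terminal_free Logical; whether the N-terminal amine is free
#'   (unacetylated), default \code{TRUE}.
#' @param numbering_offset Integer added to the 1-based index for display;
#'   0 keeps amyloid-beta numbering with the first residue as 1.
#' @return An object of class \code{peptide}.
#' @examples
#' p <- build_peptide(ab16_sequence(), "D7H")
#' peptide_residue(p, 7)  # "H"
#' @export
build_peptide <- function(sequence, variant = "WT", point_mutations = NULL,
                          c_terminal_amide = TRUE, n_terminal_free = TRUE,
                          numbering_offset = 0L) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("'sequence' must be a non-empty character scalar")
  variant <- match.arg(variant, KNOWN_VARIANTS)
  res <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(res, names(AA_MONO))
  if (length(bad))
    stop("unknown residue code(s): ", paste(unique(bad), collapse = ", "))
  n <- length(res)

  iso_positions <- integer(0)
  phospho_positions <- integer(0)

  ## variant transformations relative to the supplied (canonical) sequence
  if (variant == "D7H") {
    if (n < 7L) stop("variant D7H requires a sequence of length >= 7")
    if (res[7L] == "D") res[7L] <- "H"
    if (res[7L] != "H") stop("variant D7H requires His (or Asp) at position 7")
  } else if (variant == "isoD7") {
    if (n < 7L || res[7L] != "D")
      stop("variant isoD7 requires Asp at position 7")
    iso_positions <- 7L
  } else if (variant == "H6R") {
    if (n < 6L) stop("variant H6R requires a sequence of length >= 6")
    if (res[6L] == "H") res[6L] <- "R"
    if (res[6L] != "R") stop("variant H6R requires Arg (or His) at position 6")
  } else if (variant == "pS8") {
    if (n < 8L || res[8L] != "S")
      stop("variant pS8 requires Ser at position 8")
    phospho_positions <- 8L
  }

  if (!is.null(point_mutations) && length(point_mutations)) {
    pos <- as.integer(names(point_mutations))
    if (anyNA(pos) || any(pos < 1L) || any(pos > n))
      stop("point mutation positions must lie within the sequence")
    repl <- toupper(unlist(point_mutations, use.names = FALSE))
    if (!all(repl %in% names(AA_MONO)))
      stop("unknown replacement residue in 'point_mutations'")
    if (any(pos %in% iso_positions))
      stop("cannot mutate an isomerized position")
    res[pos] <- repl
    mut <- setNames(repl, pos)
  } else {
    mut <- setNames(character(0), character(0))
  }

  structure(list(
    residues = res,
    variant = variant,
    point_mutations = mut,
    iso_positions = iso_positions,
    phospho_positions = phospho_positions,
    c_terminal_amide = isTRUE(c_terminal_amide),
    n_terminal_free = isTRUE(n_terminal_free),
    numbering_offset = as.integer(numbering_offset)
  ), class = "peptide")
}

#' Canonical amyloid-beta 1-16 sequence
#'
#' @return The canonical human metal-binding-domain sequence
#'   \code{"DAEFRHDSGYEVHHQK"}.
#' @export
ab16_sequence <- function() AB16_SEQUENCE

#' Convenience constructor for metal-binding-domain peptides
#'
#' @param variant Variant label passed to [build_peptide()].
#' @param point_mutations Optional point mutations, e.g. \code{c("11" = "A")}.
#' @param ... Further arguments passed to [build_peptide()].
#' @return A \code{peptide}.
#' @examples
#' e11a <- ab16_peptide("D7H", point_mutations = c("11" = "A"))
#' @export
ab16_peptide <- function(variant = "WT", point_mutations = NULL, ...) {
  build_peptide(AB16_SEQUENCE, variant = variant,
                point_mutations = point_mutations, ...)
}

#' @export
print.peptide <- function(x, ...) {
  cat("peptide (", x$variant, "), ", length(x$residues), " residues\n", sep = "")
  cat(" ", paste(x$residues, collapse = ""), "\n", sep = "")
  if (length(x$iso_positions))
    cat("  isoAsp at: ", paste(x$iso_positions, collapse = ", "), "\n", sep = "")
  if (length(x$phospho_positions))
    cat("  phospho at: ", paste(x$phospho_positions, collapse = ", "), "\n", sep = "")
  if (length(x$point_mutations))
    cat("  mutations: ",
        paste(names(x$point_mutations), x$point_mutations, sep = "->",
              collapse = ", "), "\n", sep = "")
  cat("  C-terminal amide: ", x$c_terminal_amide,
      "; free N-terminus: ", x$n_terminal_free, "\n", sep = "")
  invisible(x)
}

#' @export
length.peptide <- function(x) length(x$residues)

#' Residue at a 1-based position
#' @param p A \code{peptide}.
#' @param i Position(s), 1-based.
#' @return One-letter residue code(s).
#' @export
peptide_residue <- function(p, i) {
  stopifnot(inherits(p, "peptide"))
  if (any(i < 1L) || any(i > length(p$residues))) stop("position out of range")
  p$residues[i]
}

#' Monoisotopic mass of a peptide
#'
#' Sum of residue monoisotopic masses plus one water, with the amide
#' correction (OH replaced by NH2, -0.98402 Da) applied when the C-terminus is
#' amidated, and +79.96633 Da per phosphorylated residue.  Isoaspartate is
#' isobaric and leaves the mass unchanged.
#'
#' @param p A \code{peptide}.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass(build_peptide("GG", c_terminal_amide = FALSE)) # 132.05349
#' @export
monoisotopic_mass <- function(p) {
  stopifnot(inherits(p, "peptide"))
  m <- sum(AA_MONO[p$residues]) + MASS_H2O
  if (p$c_terminal_amide) m <- m + MASS_AMIDE_CORRECTION
  m + length(p$phospho_positions) * MASS_PHOSPHO
}

#' Chelation-capable positions of a peptide
#'
#' Positions whose residue type can chelate Zn(2+) through its side chain.
#' The default capable set is Asp, Glu, His, Cys, Met and Tyr; the free
#' N-terminal amine is reported as pseudo-position 0 when present and enabled.
#' Glycine and alanine are never chelation-capable.
#'
#' @param p A \code{peptide}.
#' @param capable_set Character vector of one-letter residue codes counted as
#'   chelation-capable.
#' @param include_nterm Logical; count the free N-terminal amine as
#'   pseudo-position 0 (default \code{TRUE}).
#' @return Sorted integer vector of positions (possibly including 0).
#' @examples
#' chelation_capable_positions(ab16_peptide("D7H"))
#' @export
chelation_capable_positions <- function(p, capable_set = DEFAULT_CHELATION_SET,
                                        include_nterm = TRUE) {
  stopifnot(inherits(p, "peptide"))
  capable_set <- toupper(capable_set)
  if (any(capable_set %in% c("G", "A")))
    stop("glycine and alanine cannot be chelation-capable")
  pos <- which(p$residues %in% capable_set)
  if (include_nterm && p$n_terminal_free) pos <- c(0L, pos)
  sort(as.integer(pos))
}

#' Peptide concentration from absorbance
#'
#' Beer-Lambert conversion using the Tyr10 extinction coefficient of the
#' amyloid-beta metal-binding domain (1450 1/M/cm at 276 nm by default).
#'
#' @param a276 Absorbance at 276 nm (>= 0).
#' @param path_cm Optical path length in cm (> 0).
#' @param epsilon Extinction coefficient in 1/M/cm.
#' @return Molar concentration (M).
#' @examples
#' concentration_from_absorbance(1.45, 1) # 1e-3 M
#' @export
concentration_from_absorbance <- function(a276, path_cm, epsilon = 1450) {
  if (any(a276 < 0)) stop("'a276' must be non-negative")
  if (any(path_cm <= 0)) stop("'path_cm' must be positive")
  if (epsilon <= 0) stop("'epsilon' must be positive")
  a276 / (epsilon * path_cm)
}

#' Read peptides from a FASTA file
#'
#' Sequences are read with \pkg{Biostrings}; variant and modification flags can
#' be supplied per record via \code{config}, a named list keyed by record name
#' with entries \code{variant}, \code{mutations} and \code{c_term_amide}.
#'
#' @param file Path to a FASTA file.
#' @param config Optional named list of per-record options.
#' @return Named list of \code{peptide} objects.
#' @export
read_peptide_fasta <- function(file, config = list()) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("the Biostrings package is required to read FASTA files")
  ss <- Biostrings::readAAStringSet(file)
  out <- lapply(seq_along(ss), function(i) {
    nm <- names(ss)[i]
    cfg <- if (!is.null(config[[nm]])) config[[nm]] else list()
    build_peptide(as.character(ss[[i]]),
                  variant = if (!is.null(cfg$variant)) cfg$variant else "WT",
                  point_mutations = cfg$mutations,
                  c_terminal_amide = if (!is.null(cfg$c_term_amide)) cfg$c_term_amide else TRUE)
  })
  names(out) <- names(ss)
  out
}

#' Write peptides to a FASTA file
#'
#' @param peptides Named list of \code{peptide} objects.
#' @param file Output path.
#' @return Invisibly, \code{file}.
#' @export
write_peptide_fasta <- function(peptides, file) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("the Biostrings package is required to write FASTA files")
  if (inherits(peptides, "peptide")) peptides <- list(peptide = peptides)
  seqs <- vapply(peptides, function(p) paste(p$residues, collapse = ""), "")
  ss <- Biostrings::AAStringSet(seqs)
  names(ss) <- if (!is.null(names(peptides))) names(peptides) else
    paste0("peptide", seq_along(peptides))
  Biostrings::writeXStringSet(ss, file)
  invisible(file)
}
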