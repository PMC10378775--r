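## Neutral-mass offsets per ion series relative to the summed residue masses.
## b: acylium-type N-terminal fragment (no addition); y: C-terminal + water;
## c: b + NH3; z: z-dot radical, y - NH2 (i.e. + 1.99184 over residues);
## internal: b-type double-cleavage fragment (no addition).
series_offset <- function(series, c_terminal_amide) {
  amide <- if (c_terminal_amide) MASS_AMIDE_CORRECTION else 0
  switch(series,
         b = 0,
         y = MASS_H2O + amide,
         c = MASS_NH3,
         z = MASS_H2O - MASS_NH3 + MASS_H + amide,
         internal = 0,
         M = MASS_H2O + amide,
         stop("unknown ion series: ", series))
}

fragment_mz <- function(neutral, charge, n_zinc) {
  (neutral + n_zinc * MASS_ZN_ADDUCT + charge * MASS_PROTON) / charge
}

#' Generate theoretical fragment ions with zinc adducts
#'
#' Enumerates terminal fragments of the requested series (b/y from CID, c/z
#' from ECD) at charges \code{1..max_charge} and zinc counts
#' \code{0..max_zinc}, plus b-type internal fragments (double backbone
#' cleavage) up to \code{max_internal_length}.  The C-terminal amide is
#' applied to y/z and whole-peptide masses.  Each bound zinc shifts the
#' neutral mass by Zn - 2H = 61.91349 Da (charge is carried by protons).
#' A fragment is only generated with \code{k} zinc if its span contains at
#' least \code{k} chelation-capable positions.
#'
#' @param p A [build_peptide()] object.
#' @param series Character vector among \code{"b"}, \code{"y"}, \code{"c"},
#'   \code{"z"}, \code{"internal"}.
#' @param max_internal_length Maximum internal-fragment length (residues).
#' @param max_charge Maximum charge state (>= 1).
#' @param max_zinc Maximum zinc adduct count.
#' @param capable_set Residue types counted as chelation-capable when capping
#'   zinc counts.
#' @return A data frame of class \code{fragment_table} with columns
#'   \code{ion}, \code{series}, \code{start}, \code{end}, \code{charge},
#'   \code{n_zinc}, \code{neutral_mass}, \code{mz}.
#' @examples
#' fr <- generate_fragments(ab16_peptide("D7H"), series = c("b", "y"),
#'                          max_charge = 1, max_zinc = 0)
#' fr[fr$ion == "b2", ]
#' @export
generate_fragments <- function(p, series = c("b", "y", "c", "z", "internal"),
                               max_internal_length = 14L, max_charge = 2L,
                               max_zinc = 3L,
                               capable_set = DEFAULT_CHELATION_SET) {
  stopifnot(inherits(p, "peptide"))
  series <- unique(series)
  if (!length(series)) stop("'series' must not be empty")
  bad <- setdiff(series, c("b", "y", "c", "z", "internal"))
  if (length(bad)) stop("unknown series: ", paste(bad, collapse = ", "))
  if (max_charge < 1L) stop("'max_charge' must be >= 1")
  n <- length(p$residues)
  res_mass <- AA_MONO[p$residues]
  if (length(p$phospho_positions))
    res_mass[p$phospho_positions] <- res_mass[p$phospho_positions] + MASS_PHOSPHO
  csum <- c(0, cumsum(res_mass))
  capable <- p$residues %in% toupper(capable_set)
  ccap <- c(0L, cumsum(capable))

  ion <- ser_v <- character(0)
  iv <- jv <- integer(0)
  neutral_v <- numeric(0)
  add <- function(ions, sers, i, j, neutrals) {
    ion <<- c(ion, ions); ser_v <<- c(ser_v, sers)
    iv <<- c(iv, i); jv <<- c(jv, j); neutral_v <<- c(neutral_v, neutrals)
  }

  for (s in intersect(series, c("b", "c"))) {
    j <- seq_len(n - 1L)
    add(paste0(s, j), rep(s, n - 1L), rep(1L, n - 1L), j,
        csum[j + 1L] - csum[1L] + series_offset(s, FALSE))
  }
  for (s in intersect(series, c("y", "z"))) {
    i <- 2:n
    add(paste0(s, n - i + 1L), rep(s, n - 1L), i, rep(n, n - 1L),
        csum[n + 1L] - csum[i] + series_offset(s, p$c_terminal_amide))
  }
  if ("internal" %in% series && n > 3L) {
    for (i in 2:(n - 1L)) {
      j <- i:min(n - 1L, i + max_internal_length - 1L)
      add(sprintf("in[%d-%d]", i, j), rep("internal", length(j)),
          rep(i, length(j)), j, csum[j + 1L] - csum[i])
    }
  }

  ## expand over charges and admissible zinc counts
  kmax <- pmin(max_zinc, ccap[jv + 1L] - ccap[iv])
  reps <- max_charge * (kmax + 1L)
  idx <- rep(seq_along(ion), reps)
  charge <- unlist(lapply(seq_along(ion), function(r)
    rep(seq_len(max_charge), each = kmax[r] + 1L)), use.names = FALSE)
  nz <- unlist(lapply(seq_along(ion), function(r)
    rep(0:kmax[r], times = max_charge)), use.names = FALSE)
  out <- data.frame(
    ion = ion[idx], series = ser_v[idx], start = iv[idx], end = jv[idx],
    charge = charge, n_zinc = nz,
    neutral_mass = neutral_v[idx] + nz * MASS_ZN_ADDUCT,
    mz = fragment_mz(neutral_v[idx], charge, nz),
    stringsAsFactors = FALSE)
  class(out) <- c("fragment_table", "data.frame")
  out
}

#' Whole-peptide (precursor) m/z
#'
#' @param p A \code{peptide}.
#' @param charge Charge state (protons).
#' @param n_zinc Number of bound zinc ions.
#' @return m/z in Th.
#' @export
precursor_mz <- function(p, charge = 1L, n_zinc = 0L) {
  neutral <- monoisotopic_mass(p)
  fragment_mz(neutral, charge, n_zinc)
}
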