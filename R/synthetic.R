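ground_truth <- function(generator, seed, ...) {
  structure(list(generator = generator, seed = seed, params = list(...)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth from ", x$generator, " (seed ", x$seed, ")\n", sep = "")
  utils::str(x$params, max.level = 1, give.attr = FALSE)
  invisible(x)
}

#' Synthetic ITC titration curve
#'
#' Simulates a titration with [itc_simulate()] and adds i.i.d. Gaussian noise
#' scaled to the largest absolute heat.  The default protocol mirrors the
#' study conditions (20 x 2 uL of 5 mM ligand into 0.3 mM peptide, 0.2 mL
#' cell).
#'
#' @param model An [itc_model()].
#' @param protocol An [itc_protocol()].
#' @param noise_sd_fraction Noise standard deviation as a fraction of the
#'   largest absolute per-injection heat (default 0.02).
#' @param seed RNG seed.
#' @return A list with elements \code{curve} (an \code{itc_curve}) and
#'   \code{truth} (a \code{ground_truth} recording the planted parameters).
#' @examples
#' d7h <- itc_model(N = c(0.35, 1), Ka = c(48e4, 2.3e4), dH = c(-8, -10.3))
#' s <- synth_itc(d7h, itc_protocol(), 0.02, seed = 1)
#' @export
synth_itc <- function(model, protocol = itc_protocol(),
                      noise_sd_fraction = 0.02, seed = 1) {
  stopifnot(inherits(model, "itc_model"))
  if (noise_sd_fraction < 0) stop("'noise_sd_fraction' must be >= 0")
  curve <- itc_simulate(model, protocol)
  set.seed(seed)
  if (noise_sd_fraction > 0) {
    sdv <- noise_sd_fraction * max(abs(curve$heat))
    curve$heat <- curve$heat + stats::rnorm(nrow(curve), 0, sdv)
  }
  list(curve = curve,
       truth = ground_truth("synth_itc", seed, model = model,
                            protocol = protocol,
                            noise_sd_fraction = noise_sd_fraction))
}

#' Synthetic CID/ECD spectra with planted zinc chelators
#'
#' Emits apo (zinc-free) and holo (zinc-carrying) peak lists for a peptide
#' with a planted set of chelating positions.  Chelators are organized into
#' groups that jointly hold one zinc ion each (default: one group per planted
#' position); a fragment carries \code{k} zinc only if its span contains at
#' least \code{k} groups.  Zinc is preferentially retained on the minimal
#' spans covering each group (emitted as 1-Zn internal fragments), backbone
#' cleavages interior to a group are suppressed in holo spectra, and decoy
#' peaks are added at the requested rate.
#'
#' Apo CID/ECD spectra plus one CID and one ECD holo spectrum per precursor
#' zinc count (up to \code{min(max_zinc, number of groups)}) are produced.
#'
#' @param p A [build_peptide()] object.
#' @param planted_chelators Integer positions of the planted chelators; must
#'   be chelation-capable and lie strictly inside the sequence (positions
#'   2..n-1, so every minimal span is expressible as an internal fragment).
#' @param coverage Fraction of the theoretical fragment ladder retained per
#'   spectrum (0 < coverage <= 1).
#' @param decoy_rate Decoy peaks added per real peak (>= 0).
#' @param seed RNG seed.
#' @param groups Optional list of \code{c(start, end)} spans, each holding
#'   one zinc jointly; every group must contain at least one planted position.
#' @param max_zinc Maximum precursor zinc count.
#' @param suppression_prob Probability that a cleavage interior to a group is
#'   suppressed in a holo spectrum (default 1).
#' @return A list with \code{spectra} (list of [peak_list()]) and
#'   \code{truth}.
#' @export
synth_spectra <- function(p, planted_chelators, coverage = 0.9,
                          decoy_rate = 0.05, seed = 1, groups = NULL,
                          max_zinc = 3L, suppression_prob = 1) {
  stopifnot(inherits(p, "peptide"))
  n <- length(p$residues)
  planted <- sort(unique(as.integer(planted_chelators)))
  if (!length(planted)) stop("holo spectra require a non-empty planted set")
  capable <- chelation_capable_positions(p, include_nterm = FALSE)
  if (!all(planted %in% capable))
    stop("planted positions must be chelation-capable side chains")
  if (any(planted < 2L) || any(planted > n - 1L))
    stop("planted positions must lie strictly inside the sequence")
  if (coverage <= 0 || coverage > 1) stop("'coverage' must be in (0, 1]")
  if (decoy_rate < 0) stop("'decoy_rate' must be >= 0")
  if (is.null(groups)) {
    ## default minimal span per planted position: extend to one non-capable
    ## neighbour so the span mass is unique (a lone His/Glu internal fragment
    ## is isobaric with every other His/Glu position and cannot localize)
    groups <- lapply(planted, function(x) {
      if (x - 1L >= 2L && !(x - 1L) %in% capable) c(x - 1L, x)
      else if (x + 1L <= n - 1L && !(x + 1L) %in% capable) c(x, x + 1L)
      else c(x, x)
    })
  }
  groups <- lapply(groups, function(g) as.integer(c(min(g), max(g))))
  for (g in groups) {
    if (g[1] < 2L || g[2] > n - 1L)
      stop("group spans must lie strictly inside the sequence")
    if (!any(planted >= g[1] & planted <= g[2]))
      stop("every group must contain a planted position")
  }
  n_groups <- length(groups)
  set.seed(seed)

  res_mass <- AA_MONO[p$residues]
  if (length(p$phospho_positions))
    res_mass[p$phospho_positions] <- res_mass[p$phospho_positions] + MASS_PHOSPHO
  csum <- c(0, cumsum(res_mass))
  frag_neutral <- function(ser, i, j)
    csum[j + 1L] - csum[i] +
      series_offset(ser, p$c_terminal_amide && j == n && ser %in% c("y", "z"))

  groups_in_span <- function(i, j)
    sum(vapply(groups, function(g) g[1] >= i && g[2] <= j, TRUE))
  interior_site <- function(s)   # cleavage site s = bond s|s+1
    any(vapply(groups, function(g) s >= g[1] && s < g[2], TRUE))

  build_spectrum <- function(activation, k_zinc) {
    ser_pair <- if (activation == "CID") c("b", "y") else c("c", "z")
    mz <- inten <- numeric(0)
    manifest <- list()
    add_peak <- function(m, it, what) {
      mz <<- c(mz, m); inten <<- c(inten, it)
      manifest[[length(manifest) + 1L]] <<- what
    }
    ## terminal ladders
    for (s in ser_pair) {
      nterm <- s %in% c("b", "c")
      for (cl in seq_len(n - 1L)) {      # cleavage site index
        if (k_zinc > 0 && interior_site(cl) &&
            stats::runif(1) < suppression_prob) next
        if (stats::runif(1) > coverage) next
        if (nterm) { i <- 1L; j <- cl } else { i <- cl + 1L; j <- n }
        nz <- if (k_zinc > 0) min(k_zinc, groups_in_span(i, j)) else 0L
        m <- fragment_mz(frag_neutral(s, i, j), 1L, nz)
        add_peak(m, 50, list(series = s, start = i, end = j, n_zinc = nz))
      }
    }
    ## minimal zinc-carrying internal spans, one zinc per group
    if (k_zinc > 0) {
      for (g in groups) {
        if (stats::runif(1) > coverage) next
        m <- fragment_mz(frag_neutral("internal", g[1], g[2]), 1L, 1L)
        add_peak(m, 100, list(series = "internal", start = g[1], end = g[2],
                              n_zinc = 1L))
      }
    }
    ## decoys
    n_decoy <- round(decoy_rate * length(mz))
    if (n_decoy > 0) {
      dm <- stats::runif(n_decoy, 150, 2000)
      for (d in dm) add_peak(d, 5, list(series = "decoy"))
    }
    pl <- peak_list(mz, inten,
                    precursor = list(mz = precursor_mz(p, 3L, k_zinc),
                                     charge = 3L, n_zinc = k_zinc),
                    activation = activation,
                    title = sprintf("synthetic_%s_zn%d", activation, k_zinc))
    attr(pl, "manifest") <- manifest
    pl
  }

  spectra <- list(build_spectrum("CID", 0L), build_spectrum("ECD", 0L))
  for (k in seq_len(min(max_zinc, n_groups))) {
    spectra[[length(spectra) + 1L]] <- build_spectrum("CID", k)
    spectra[[length(spectra) + 1L]] <- build_spectrum("ECD", k)
  }
  list(spectra = spectra,
       truth = ground_truth("synth_spectra", seed, planted = planted,
                            groups = groups, coverage = coverage,
                            decoy_rate = decoy_rate,
                            suppression_prob = suppression_prob))
}

#' Preset synthetic spectra for the Taiwan-mutant monomer
#'
#' The canonical worked example: D7H metal-binding domain with two jointly
#' chelating groups, residues 3-7 (E3/H6/H7) and 11-14 (E11/H13/H14), each
#' holding one shared zinc, with cleavage suppression inside both regions.
#'
#' @param seed RNG seed.
#' @param coverage,decoy_rate Passed to [synth_spectra()].
#' @return As [synth_spectra()].
#' @export
synth_spectra_d7h_preset <- function(seed = 1, coverage = 1, decoy_rate = 0) {
  p <- ab16_peptide("D7H")
  synth_spectra(p, planted_chelators = c(3L, 6L, 7L, 11L, 13L, 14L),
                coverage = coverage, decoy_rate = decoy_rate, seed = seed,
                groups = list(c(3L, 7L), c(11L, 14L)), max_zinc = 2L)
}

## Fixed-width PDB ATOM record writer (multi-model).
format_pdb_model <- function(model_no, atoms, coords) {
  fmt <- "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f"
  body <- sprintf(fmt, seq_len(nrow(atoms)), atoms$elety, atoms$resid,
                  atoms$chain, atoms$resno,
                  coords[, 1], coords[, 2], coords[, 3], 1, 0)
  c(sprintf("MODEL     %4d", model_no), body, "ENDMDL")
}

#' Synthetic multi-chain trajectory with planted contact rates
#'
#' Generates pseudo-atomistic frames with one backbone (CA) and one
#' side-chain centroid (CB) atom per residue.  For every controlled residue
#' pair an independent Bernoulli draw per frame places the side-chain atoms at
#' a distance Uniform(3.2, 4.4) A (contact) or Uniform(6, 12) A (non-contact);
#' all uncontrolled pairs are kept farther than 6 A apart on a coarse grid.
#' The frames are written as a multi-model PDB and read back through
#' [load_trajectory()].
#'
#' @param chains Named list of [build_peptide()] objects (names = chain ids;
#'   defaults to A, B, ...).
#' @param contact_rates Data frame with columns \code{chain_a}, \code{res_a},
#'   \code{chain_b}, \code{res_b}, \code{rate} (rates in [0, 1]).  A residue
#'   may appear in at most one controlled pair; conflicting constraints are
#'   rejected as geometrically unsatisfiable.
#' @param n_frames Number of frames (>= 1).
#' @param seed RNG seed.
#' @param file Output PDB path (default a temporary file).
#' @return A list with \code{trajectory} (a \code{zn_trajectory}),
#'   \code{file} and \code{truth}.
#' @export
synth_trajectory <- function(chains, contact_rates, n_frames = 2000L,
                             seed = 1, file = tempfile(fileext = ".pdb")) {
  if (inherits(chains, "peptide")) chains <- list(A = chains)
  stopifnot(all(vapply(chains, inherits, TRUE, "peptide")))
  if (is.null(names(chains)) || any(!nzchar(names(chains))))
    names(chains) <- LETTERS[seq_along(chains)]
  if (n_frames < 1L) stop("'n_frames' must be >= 1")
  cr <- as.data.frame(contact_rates)
  need <- c("chain_a", "res_a", "chain_b", "res_b", "rate")
  if (!all(need %in% names(cr)))
    stop("'contact_rates' needs columns: ", paste(need, collapse = ", "))
  if (any(cr$rate < 0 | cr$rate > 1)) stop("rates must lie in [0, 1]")
  keys <- c(paste(cr$chain_a, cr$res_a), paste(cr$chain_b, cr$res_b))
  if (anyDuplicated(keys))
    stop("conflicting rate constraints: a residue appears in more than one ",
         "controlled pair (geometrically unsatisfiable)")

  ## atom table: CA + CB per residue of every chain
  atoms <- do.call(rbind, lapply(names(chains), function(ch) {
    pep <- chains[[ch]]
    nres <- length(pep$residues)
    data.frame(elety = rep(c("CA", "CB"), nres),
               resid = rep(AA1TO3[pep$residues], each = 2),
               chain = ch, resno = rep(seq_len(nres), each = 2),
               stringsAsFactors = FALSE)
  }))
  natoms <- nrow(atoms)
  res_key <- paste(atoms$chain, atoms$resno)
  ures <- unique(res_key)

  ## static base geometry: uncontrolled residues on a 50 A grid at y = 0,
  ## controlled pairs in private pockets at y = 100 * pair index
  base <- matrix(0, natoms, 3)
  grid_i <- match(res_key, ures)
  base[, 1] <- 50 * grid_i
  base[atoms$elety == "CA", 3] <- 1.5
  pocket <- integer(natoms)   # pair index per atom (0 = uncontrolled)
  side <- integer(natoms)     # 1 = first member, 2 = second
  for (k in seq_len(nrow(cr))) {
    ia <- which(atoms$chain == cr$chain_a[k] & atoms$resno == cr$res_a[k])
    ib <- which(atoms$chain == cr$chain_b[k] & atoms$resno == cr$res_b[k])
    if (!length(ia) || !length(ib))
      stop("controlled pair ", k, " refers to a residue not in any chain")
    pocket[ia] <- k; side[ia] <- 1L
    pocket[ib] <- k; side[ib] <- 2L
    base[ia, ] <- rep(c(0, 100 * k, 0), each = length(ia))
    base[ib, ] <- rep(c(0, 100 * k, 0), each = length(ib))
    base[ia[atoms$elety[ia] == "CA"], 3] <- 1.5
    base[ib[atoms$elety[ib] == "CA"], 3] <- 1.5
  }

  set.seed(seed)
  lines <- vector("list", n_frames)
  contact_draws <- matrix(FALSE, n_frames, nrow(cr))
  for (f in seq_len(n_frames)) {
    coords <- base
    for (k in seq_len(nrow(cr))) {
      hit <- stats::runif(1) < cr$rate[k]
      contact_draws[f, k] <- hit
      d <- if (hit) stats::runif(1, 3.2, 4.4) else stats::runif(1, 6, 12)
      ib <- which(pocket == k & side == 2L)
      coords[ib, 1] <- coords[ib, 1] + d
    }
    lines[[f]] <- format_pdb_model(f, atoms, coords)
  }
  writeLines(c(unlist(lines), "END"), file)
  traj <- load_trajectory(file)
  list(trajectory = traj, file = file,
       truth = ground_truth("synth_trajectory", seed,
                            contact_rates = cr, n_frames = n_frames,
                            planted_fractions = colMeans(contact_draws)))
}
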