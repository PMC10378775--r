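BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Load a multi-chain, multi-frame trajectory
#'
#' Reads a multi-model PDB (one MODEL per frame) through \pkg{bio3d}.  Several
#' coordinate files may be supplied and are concatenated frame-wise; a
#' topology PDB plus a binary DCD trajectory is also accepted.  Chain and
#' residue indexing can be validated against expected peptide sequences.
#'
#' @param coordinates Path(s) to multi-model PDB file(s), or a DCD file when
#'   \code{topology} is given.
#' @param topology Optional PDB topology for binary trajectories.
#' @param expected_sequences Optional named list of [build_peptide()] objects
#'   (names = chain ids) to validate chain sequences against.
#' @return An object of class \code{zn_trajectory}: a list with \code{atoms}
#'   (data frame: elety, resid, chain, resno), \code{xyz} (frames x 3N
#'   matrix) and \code{n_frames}.
#' @export
load_trajectory <- function(coordinates, topology = NULL,
                            expected_sequences = NULL) {
  if (!is.null(topology)) {
    top <- bio3d::read.pdb(topology, multi = FALSE, verbose = FALSE)
    atoms <- top$atom
    xyz <- do.call(rbind, lapply(coordinates, function(f) {
      if (grepl("\\.dcd$", f, ignore.case = TRUE))
        unclass(bio3d::read.dcd(f, verbose = FALSE))
      else unclass(bio3d::read.pdb(f, multi = TRUE, verbose = FALSE)$xyz)
    }))
  } else {
    pdbs <- lapply(coordinates, bio3d::read.pdb, multi = TRUE, verbose = FALSE)
    atoms <- pdbs[[1]]$atom
    for (p in pdbs[-1]) {
      if (nrow(p$atom) != nrow(atoms))
        stop("atom count mismatch between coordinate files")
    }
    xyz <- do.call(rbind, lapply(pdbs, function(p) unclass(p$xyz)))
  }
  if (ncol(xyz) != 3L * nrow(atoms))
    stop("coordinate dimensions inconsistent with atom table")
  atoms <- atoms[, c("elety", "resid", "chain", "resno")]
  if (!is.null(expected_sequences)) {
    for (ch in names(expected_sequences)) {
      sel <- atoms$chain == ch & !duplicated(paste(atoms$chain, atoms$resno))
      obs <- AA3TO1[atoms$resid[sel][order(atoms$resno[sel])]]
      want <- expected_sequences[[ch]]$residues
      if (length(obs) != length(want) || any(obs != want, na.rm = FALSE) ||
          anyNA(obs))
        stop("chain ", ch, " sequence does not match the expected peptide")
    }
  }
  structure(list(atoms = atoms, xyz = xyz, n_frames = nrow(xyz)),
            class = "zn_trajectory")
}

#' @export
print.zn_trajectory <- function(x, ...) {
  cat("zn_trajectory:", x$n_frames, "frames,", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chain(s)\n")
  invisible(x)
}

#' Contact configuration
#'
#' @param cutoff Contact distance cutoff in Angstrom (default 4.5; a frame is
#'   a contact when the minimum in-scope interatomic distance is strictly
#'   below it).
#' @param atom_scope \code{"sidechain"} (heavy side-chain atoms, default) or
#'   \code{"all"} (all heavy atoms).
#' @return A list of class \code{contact_config}.
#' @export
contact_config <- function(cutoff = 4.5, atom_scope = c("sidechain", "all")) {
  if (cutoff <= 0) stop("'cutoff' must be positive")
  structure(list(cutoff = cutoff, atom_scope = match.arg(atom_scope)),
            class = "contact_config")
}

residue_atom_idx <- function(traj, chain, resno, scope) {
  sel <- traj$atoms$chain == chain & traj$atoms$resno == resno
  if (scope == "sidechain")
    sel <- sel & !(traj$atoms$elety %in% BACKBONE_ATOMS)
  sel <- sel & !grepl("^H", traj$atoms$elety)
  idx <- which(sel)
  if (!length(idx))
    stop("no atoms for chain ", chain, " residue ", resno,
         " under scope '", scope, "'")
  idx
}

## Minimum distance between two atom groups in every frame.
min_dist_frames <- function(xyz, idx_a, idx_b) {
  nf <- nrow(xyz)
  out <- rep(Inf, nf)
  for (ia in idx_a) {
    ax <- xyz[, 3 * ia - 2]; ay <- xyz[, 3 * ia - 1]; az <- xyz[, 3 * ia]
    for (ib in idx_b) {
      d2 <- (ax - xyz[, 3 * ib - 2])^2 + (ay - xyz[, 3 * ib - 1])^2 +
        (az - xyz[, 3 * ib])^2
      out <- pmin(out, d2)
    }
  }
  sqrt(out)
}

#' Contact statistics for one residue pair
#'
#' A frame counts as a contact when the minimum distance between the two
#' residues' in-scope atoms is strictly below the cutoff.
#'
#' @param traj A [load_trajectory()] object.
#' @param a,b Residue selectors: \code{c(chain, resno)} (character chain id,
#'   residue number).
#' @param cfg A [contact_config()].
#' @param stride Frame subsampling stride (default 1 = every frame).
#' @return A one-row data frame of class \code{contact_stats} with the pair,
#'   \code{frames_in_contact}, \code{frames_total} and \code{fraction}.
#' @export
pair_contact_frames <- function(traj, a, b, cfg = contact_config(),
                                stride = 1L) {
  stopifnot(inherits(traj, "zn_trajectory"), inherits(cfg, "contact_config"))
  idx_a <- residue_atom_idx(traj, a[1], as.integer(a[2]), cfg$atom_scope)
  idx_b <- residue_atom_idx(traj, b[1], as.integer(b[2]), cfg$atom_scope)
  frames <- seq(1L, traj$n_frames, by = as.integer(stride))
  d <- min_dist_frames(traj$xyz[frames, , drop = FALSE], idx_a, idx_b)
  n_contact <- sum(d < cfg$cutoff)
  lab_a <- residue_label(traj, a[1], as.integer(a[2]))
  lab_b <- residue_label(traj, b[1], as.integer(b[2]))
  out <- data.frame(chain_a = a[1], res_a = lab_a, chain_b = b[1],
                    res_b = lab_b, pair = paste(lab_a, lab_b, sep = "/"),
                    frames_in_contact = n_contact,
                    frames_total = length(frames),
                    fraction = n_contact / length(frames),
                    cutoff = cfg$cutoff, atom_scope = cfg$atom_scope,
                    stringsAsFactors = FALSE)
  class(out) <- c("contact_stats", "data.frame")
  out
}

residue_label <- function(traj, chain, resno) {
  sel <- which(traj$atoms$chain == chain & traj$atoms$resno == resno)[1]
  one <- AA3TO1[traj$atoms$resid[sel]]
  paste0(if (is.na(one)) "X" else one, resno)
}

#' Census of candidate residue pairs
#'
#' Runs [pair_contact_frames()] for every candidate pair and returns one row
#' per pair in the input order (deterministic).
#'
#' @param traj A trajectory.
#' @param candidate_pairs A list of pairs, each a list/vector of two residue
#'   selectors \code{c(chain, resno)}.
#' @param cfg A [contact_config()].
#' @param stride Frame stride.
#' @return A \code{contact_stats} data frame with one row per pair.
#' @export
interface_census <- function(traj, candidate_pairs, cfg = contact_config(),
                             stride = 1L) {
  if (!length(candidate_pairs)) stop("'candidate_pairs' must be non-empty")
  if (traj$n_frames < 1L) stop("trajectory has no frames")
  out <- do.call(rbind, lapply(candidate_pairs, function(pp)
    pair_contact_frames(traj, pp[[1]], pp[[2]], cfg, stride)))
  rownames(out) <- NULL
  class(out) <- c("contact_stats", "data.frame")
  out
}

#' Feasible zinc-mediated interfaces from a contact census
#'
#' Selects the residue-pair interfaces that can plausibly chelate a shared
#' zinc ion at an oligomer interface.  The low-affinity chelator residues
#' (default E3, H6, H7, H13) are partitioned into two chelating pairs; a
#' partition survives when (i) every pair in it was observed in contact at
#' least once in the census, (ii) it contains no sterically impossible pair
#' (default H6/H13), and (iii) it does not contain a mutually exclusive pair
#' combination (default E3/H7 together with H6/H13).  Each surviving pair
#' becomes a homotypic interface specification; the high-affinity interface
#' (default E11/H14) is always emitted first.
#'
#' @param census A census from [interface_census()], computed at one cutoff.
#' @param low_affinity_residues Character vector of four residue labels.
#' @param high_affinity_pair Label of the high-affinity chelating pair.
#' @param impossible_pairs Character vector of pair labels (\code{"A/B"}) that
#'   cannot co-chelate within one molecule.
#' @param exclusive_sets List of character vectors; the pairs in one vector
#'   cannot all occur in the same partition.
#' @return A data frame of class \code{interface_spec} with columns
#'   \code{name} (e.g. \code{"E3/H6:ZN:E3/H6"}), \code{pair} and
#'   \code{affinity_class}.
#' @export
feasible_interfaces <- function(census,
                                low_affinity_residues = c("E3", "H6", "H7", "H13"),
                                high_affinity_pair = "E11/H14",
                                impossible_pairs = "H6/H13",
                                exclusive_sets = list(c("E3/H7", "H6/H13"))) {
  if (length(unique(census$cutoff)) > 1L)
    stop("census rows were computed at different cutoffs")
  if (!NROW(census)) {
    out <- data.frame(name = character(0), pair = character(0),
                      affinity_class = character(0), stringsAsFactors = FALSE)
    class(out) <- c("interface_spec", "data.frame")
    return(out)
  }
  if (length(low_affinity_residues) != 4L)
    stop("exactly four low-affinity chelator residues are expected")
  pair_lab <- function(a, b) paste(a, b, sep = "/")
  observed <- function(lab) {
    rev_lab <- paste(rev(strsplit(lab, "/")[[1]]), collapse = "/")
    hit <- census$pair %in% c(lab, rev_lab)
    any(hit & census$frames_in_contact > 0)
  }
  r <- low_affinity_residues
  partitions <- list(
    c(pair_lab(r[1], r[2]), pair_lab(r[3], r[4])),
    c(pair_lab(r[1], r[3]), pair_lab(r[2], r[4])),
    c(pair_lab(r[1], r[4]), pair_lab(r[2], r[3])))
  ok_pairs <- character(0)
  for (part in partitions) {
    if (any(part %in% impossible_pairs)) next
    excl <- any(vapply(exclusive_sets, function(s) all(s %in% part), TRUE))
    if (excl) next
    if (!all(vapply(part, observed, TRUE))) next
    ok_pairs <- union(ok_pairs, part)
  }
  pairs <- c(high_affinity_pair, ok_pairs)
  out <- data.frame(
    name = paste0(pairs, ":ZN:", pairs),
    pair = pairs,
    affinity_class = c("high", rep("low", length(ok_pairs))),
    stringsAsFactors = FALSE)
  class(out) <- c("interface_spec", "data.frame")
  out
}

#' Write a contact census as a delimited table
#'
#' @param census A \code{contact_stats} data frame.
#' @param file Output path.
#' @param sep Field separator.
#' @return Invisibly, \code{file}.
#' @export
write_census_table <- function(census, file, sep = "\t") {
  utils::write.table(census, file, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(file)
}
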