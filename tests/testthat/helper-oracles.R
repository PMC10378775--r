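## Independent oracles used by the property suites.  These are deliberately
## implemented from first principles (elemental compositions, dense-grid
## bisection, O(n^2) distance scans) and share no code with the package
## internals they check.

## --- elemental fragment-mass oracle -------------------------------------

ORACLE_ELEMENTS <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
                     O = 15.9949146196, S = 31.97207100,
                     Zn = 63.9291422, P = 30.97376163)

## residue (dehydrated) elemental compositions, columns C H N O S
ORACLE_FORMULAS <- rbind(
  G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0))
colnames(ORACLE_FORMULAS) <- c("C", "H", "N", "O", "S")

oracle_formula_mass <- function(counts) {
  sum(counts * ORACLE_ELEMENTS[names(counts)])
}

## neutral fragment mass by elemental arithmetic
oracle_fragment_neutral <- function(residues, series, n_zinc = 0,
                                    amidated = FALSE) {
  counts <- colSums(ORACLE_FORMULAS[residues, , drop = FALSE])
  counts <- c(counts, Zn = 0)
  add <- function(cc, el, k) { cc[el] <- cc[el] + k; cc }
  if (series %in% c("y", "z", "M")) {
    counts <- add(counts, "H", 2); counts <- add(counts, "O", 1)  # + H2O
    if (amidated) {  # OH -> NH2
      counts <- add(counts, "O", -1); counts <- add(counts, "H", 1)
      counts <- add(counts, "N", 1)
    }
  }
  if (series == "c") { counts <- add(counts, "N", 1); counts <- add(counts, "H", 3) }
  if (series == "z") {  # z-dot: y - NH3 + H
    counts <- add(counts, "N", -1); counts <- add(counts, "H", -2)
  }
  counts <- add(counts, "Zn", n_zinc); counts <- add(counts, "H", -2 * n_zinc)
  oracle_formula_mass(counts)
}

oracle_fragment_mz <- function(residues, series, charge = 1, n_zinc = 0,
                               amidated = FALSE) {
  (oracle_fragment_neutral(residues, series, n_zinc, amidated) +
     charge * 1.007276466) / charge
}

## --- brute-force ITC oracle ----------------------------------------------

## free-ligand concentration by dense grid + bisection on the mass balance
oracle_free_ligand <- function(Xt, Mt, N, Ka, n_grid = 2000, n_bisect = 80) {
  if (Xt <= 0) return(0)
  f <- function(L) L + Mt * sum(N * Ka * L / (1 + Ka * L)) - Xt
  grid <- seq(0, Xt, length.out = n_grid)
  vals <- vapply(grid, f, numeric(1))
  i <- which(vals[-1] >= 0 & vals[-n_grid] <= 0)[1]
  lo <- grid[i]; hi <- grid[i + 1]
  for (b in seq_len(n_bisect)) {
    mid <- (lo + hi) / 2
    if (f(mid) <= 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

## fully independent forward simulation of per-injection molar heats
oracle_itc_heats <- function(N, Ka, dH, cell_ul = 200, cell_mM = 0.3,
                             syringe_mM = 5, inj_ul = rep(2, 20)) {
  v <- cumsum(inj_ul)
  M0 <- cell_mM / 1000; X0 <- syringe_mM / 1000
  Mt <- M0 * (1 - v / (2 * cell_ul)) / (1 + v / (2 * cell_ul))
  Xt <- X0 * (v / cell_ul) / (1 + v / (2 * cell_ul))
  Q <- numeric(length(v))
  for (k in seq_along(v)) {
    L <- oracle_free_ligand(Xt[k], Mt[k], N, Ka)
    Q[k] <- cell_ul * 1e-6 * Mt[k] *
      sum(N * dH * Ka * L / (1 + Ka * L))
  }
  Qp <- c(0, Q[-length(Q)])
  dq <- Q - Qp + (inj_ul / cell_ul) * (Q + Qp) / 2
  dq / (X0 * inj_ul * 1e-6)
}

## --- brute-force contact oracle ------------------------------------------

## frames in contact for two atom groups by an O(n^2) per-frame scan
oracle_contact_frames <- function(traj, idx_a, idx_b, cutoff) {
  hits <- 0L
  for (f in seq_len(traj$n_frames)) {
    row <- traj$xyz[f, ]
    dmin <- Inf
    for (ia in idx_a) {
      pa <- row[(3 * ia - 2):(3 * ia)]
      for (ib in idx_b) {
        pb <- row[(3 * ib - 2):(3 * ib)]
        dmin <- min(dmin, sqrt(sum((pa - pb)^2)))
      }
    }
    if (dmin < cutoff) hits <- hits + 1L
  }
  hits
}

## random test peptide without the variant machinery
random_peptide_seq <- function(n, exclude = character(0)) {
  aa <- setdiff(rownames(ORACLE_FORMULAS), exclude)
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

## brute-force seed enumeration: every pair of free same-type lateral sites
## on the two subunits of a homotypic E11/H14 bridge, dockable from the pool
oracle_seed_count <- function(a, pool) {
  br <- assembly_bridges(a)
  subs <- assembly_subunits(a)
  used <- function(id, site)
    any((br$sub_a == id & br$site_a == site) |
          (br$sub_b == id & br$site_b == site))
  variant_of <- function(id) subs$variant[match(id, subs$id)]
  pool <- pool[pool %in% c("D7H", "isoD7")]  # recruitment rule default on
  count <- 0L
  for (r in seq_len(nrow(br))) {
    if (br$site_a[r] != "E11/H14" || br$site_b[r] != "E11/H14") next
    va <- variant_of(br$sub_a[r]); vb <- variant_of(br$sub_b[r])
    if (va == "WT" || vb == "WT") next
    for (X in c("E3/H6", "H7/H13", "H6/H13")) {
      if (!X %in% interface_sites(va) || !X %in% interface_sites(vb)) next
      if (used(br$sub_a[r], X) || used(br$sub_b[r], X)) next
      if (!any(vapply(pool, function(v) X %in% interface_sites(v), TRUE))) next
      count <- count + 1L
    }
  }
  count
}
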