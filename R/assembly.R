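## Interface-site sets by variant.  The unmodified metal-binding domain has
## two zinc-mediated interface sites; the Taiwan mutant gains H7/H13 and the
## isoaspartate isoform trades E3/H6 for H6/H13.
VARIANT_SITES <- list(
  WT    = c("E11/H14", "E3/H6"),
  D7H   = c("E11/H14", "E3/H6", "H7/H13"),
  isoD7 = c("E11/H14", "H6/H13")
)
HOMOTYPIC_SITES <- c("E11/H14", "E3/H6", "H7/H13", "H6/H13")
## Heterotypic compatibility: the high-affinity EVHH pair can bridge the
## histidine-based sites of modified subunits (heterotrimer wiring).
HETEROTYPIC_PAIRS <- list(c("E11/H14", "H7/H13"), c("E11/H14", "H6/H13"))
EVHH_SITE <- "E11/H14"
MODIFIED_VARIANTS <- c("D7H", "isoD7")

#' Interface sites of a variant
#'
#' @param variant \code{"WT"}, \code{"D7H"} or \code{"isoD7"}.
#' @return Character vector of interface-site labels.
#' @export
interface_sites <- function(variant) {
  if (!variant %in% names(VARIANT_SITES)) stop("unknown variant: ", variant)
  VARIANT_SITES[[variant]]
}

#' Create a free subunit
#'
#' @param variant Peptide variant of the subunit.
#' @return A list of class \code{zn_subunit} with the variant's interface
#'   sites, all free.
#' @examples
#' make_subunit("D7H")  # three interface sites
#' @export
make_subunit <- function(variant) {
  sites <- interface_sites(variant)
  structure(list(variant = variant, sites = sites,
                 site_occupancy = setNames(rep(NA_integer_, length(sites)),
                                           sites)),
            class = "zn_subunit")
}

#' @export
print.zn_subunit <- function(x, ...) {
  cat("zn_subunit (", x$variant, "): sites ",
      paste(x$sites, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Create an empty assembly
#'
#' An assembly is a graph of peptide subunits joined by zinc bridges between
#' interface sites; every bridge carries exactly one zinc ion.
#'
#' @param variants Character vector of subunit variants to start from
#'   (possibly empty).
#' @param recruitment_rule Logical; when \code{TRUE} (default) unmodified (WT)
#'   subunits only participate in bridges through their E11/H14 site and only
#'   with a modified (D7H/isoD7) partner — WT lateral sites are inert.  This
#'   encodes the observation that the unmodified domain stays monomeric with
#'   zinc unless seeded by a modified subunit.
#' @param strict_homotypic Logical; when \code{TRUE}, only same-type site
#'   pairings are allowed (disables the E11/H14 to H7/H13 and E11/H14 to
#'   H6/H13 heterotypic bridges).
#' @return An object of class \code{zn_assembly}.
#' @export
new_assembly <- function(variants = character(0), recruitment_rule = TRUE,
                         strict_homotypic = FALSE) {
  bad <- setdiff(variants, names(VARIANT_SITES))
  if (length(bad)) stop("unknown variant(s): ", paste(bad, collapse = ", "))
  structure(list(
    subunits = data.frame(id = seq_along(variants),
                          variant = as.character(variants),
                          stringsAsFactors = FALSE),
    bridges = data.frame(sub_a = integer(0), site_a = character(0),
                         sub_b = integer(0), site_b = character(0),
                         stringsAsFactors = FALSE),
    recruitment_rule = isTRUE(recruitment_rule),
    strict_homotypic = isTRUE(strict_homotypic),
    metadata = list()),
    class = "zn_assembly")
}

#' Add a subunit to an assembly
#'
#' @param a A \code{zn_assembly}.
#' @param variant Variant of the new subunit.
#' @return The assembly with one more (free) subunit; its id is
#'   \code{nrow(assembly_subunits(a)) + 1}.
#' @export
add_subunit <- function(a, variant) {
  stopifnot(inherits(a, "zn_assembly"))
  if (!variant %in% names(VARIANT_SITES)) stop("unknown variant: ", variant)
  a$subunits <- rbind(a$subunits,
                      data.frame(id = nrow(a$subunits) + 1L, variant = variant,
                                 stringsAsFactors = FALSE))
  a
}

subunit_variant <- function(a, id) {
  i <- match(as.integer(id), a$subunits$id)
  if (is.na(i)) stop("no subunit with id ", id)
  a$subunits$variant[i]
}

site_is_free <- function(a, id, site) {
  !any((a$bridges$sub_a == id & a$bridges$site_a == site) |
         (a$bridges$sub_b == id & a$bridges$site_b == site))
}

sites_compatible <- function(x, y, strict_homotypic = FALSE) {
  if (x == y) return(x %in% HOMOTYPIC_SITES)
  if (strict_homotypic) return(FALSE)
  any(vapply(HETEROTYPIC_PAIRS, function(pp) all(c(x, y) %in% pp), TRUE))
}

## NULL when legal, otherwise a message.
bridge_illegality <- function(a, s1, site1, s2, site2) {
  v1 <- subunit_variant(a, s1); v2 <- subunit_variant(a, s2)
  if (s1 == s2) return("a subunit cannot bridge to itself")
  if (!site1 %in% interface_sites(v1))
    return(paste0("subunit ", s1, " (", v1, ") has no site ", site1))
  if (!site2 %in% interface_sites(v2))
    return(paste0("subunit ", s2, " (", v2, ") has no site ", site2))
  if (!site_is_free(a, s1, site1))
    return(paste0("site ", site1, " of subunit ", s1, " is occupied"))
  if (!site_is_free(a, s2, site2))
    return(paste0("site ", site2, " of subunit ", s2, " is occupied"))
  if (!sites_compatible(site1, site2, a$strict_homotypic))
    return(paste0("incompatible site types: ", site1, " and ", site2))
  if (a$recruitment_rule) {
    for (end in list(list(v = v1, s = site1, pv = v2),
                     list(v = v2, s = site2, pv = v1))) {
      if (end$v == "WT") {
        if (end$s != EVHH_SITE)
          return("lateral sites of unmodified subunits are inert under the recruitment rule")
        if (!end$pv %in% MODIFIED_VARIANTS)
          return("unmodified subunits only bridge to a modified partner under the recruitment rule")
      }
    }
  }
  NULL
}

#' Add a zinc bridge between two subunit sites
#'
#' Validates valence (one bridge per site), site-type compatibility
#' (same-type pairings for the homotypic interfaces; E11/H14 additionally
#' pairs with H7/H13 and H6/H13 unless \code{strict_homotypic}) and the
#' seed-recruitment rule, then records the bridge.  Every bridge accounts for
#' exactly one zinc ion.
#'
#' @param a A \code{zn_assembly}.
#' @param e1,e2 Endpoints \code{c(subunit_id, site_label)}.
#' @return The extended assembly.
#' @examples
#' a <- new_assembly(c("D7H", "D7H"))
#' a <- add_bridge(a, c(1, "E11/H14"), c(2, "E11/H14"))
#' zinc_count(a)  # 1
#' @export
add_bridge <- function(a, e1, e2) {
  stopifnot(inherits(a, "zn_assembly"))
  s1 <- as.integer(e1[[1]]); site1 <- as.character(e1[[2]])
  s2 <- as.integer(e2[[1]]); site2 <- as.character(e2[[2]])
  msg <- bridge_illegality(a, s1, site1, s2, site2)
  if (!is.null(msg)) stop(msg)
  a$bridges <- rbind(a$bridges,
                     data.frame(sub_a = s1, site_a = site1, sub_b = s2,
                                site_b = site2, stringsAsFactors = FALSE))
  a
}

#' Number of zinc ions in an assembly
#'
#' One per bridge, by construction.
#' @param a A \code{zn_assembly}.
#' @return Integer.
#' @export
zinc_count <- function(a) {
  stopifnot(inherits(a, "zn_assembly"))
  nrow(a$bridges)
}

#' @rdname zinc_count
#' @export
assembly_subunits <- function(a) a$subunits

#' @rdname zinc_count
#' @export
assembly_bridges <- function(a) a$bridges

#' Change the variant of one subunit
#'
#' The new variant must support all sites currently engaged by bridges.
#'
#' @param a A \code{zn_assembly}.
#' @param id Subunit id.
#' @param variant New variant.
#' @return The modified assembly.
#' @export
set_subunit_variant <- function(a, id, variant) {
  stopifnot(inherits(a, "zn_assembly"))
  if (!variant %in% names(VARIANT_SITES)) stop("unknown variant: ", variant)
  used <- c(a$bridges$site_a[a$bridges$sub_a == id],
            a$bridges$site_b[a$bridges$sub_b == id])
  if (!all(used %in% interface_sites(variant)))
    stop("existing bridges use sites absent from variant ", variant)
  a$subunits$variant[match(as.integer(id), a$subunits$id)] <- variant
  a
}

is_connected_assembly <- function(a) {
  n <- nrow(a$subunits)
  if (n <= 1L) return(TRUE)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (r in seq_len(nrow(a$bridges))) {
    i <- a$bridges$sub_a[r]; j <- a$bridges$sub_b[r]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n); queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in adj[[cur]]) if (!seen[nb]) { seen[nb] <- TRUE; queue <- c(queue, nb) }
  }
  all(seen)
}

#' Count polymerization seeds
#'
#' A polymerization seed is a docking locus for the polymerization unit (a
#' zinc-bridged E11/H14 dimer): a pair of free, same-type lateral sites on the
#' two subunits of one homotypic E11/H14 dimer, such that a fresh dimer drawn
#' from the variant pool could legally attach there with two zinc bridges.
#' Under the recruitment rule, lateral sites of unmodified subunits are inert
#' and unmodified dimers cannot form, so pools without a modified variant
#' yield no seeds.
#'
#' @param a A \code{zn_assembly}.
#' @param variant_pool Variants available as fresh subunits; defaults to the
#'   variants already present in the assembly.
#' @return Integer seed count.
#' @examples
#' free_seed_count(build_named_assembly("dodecamer"))  # 3
#' @export
free_seed_count <- function(a, variant_pool = NULL) {
  stopifnot(inherits(a, "zn_assembly"))
  if (is.null(variant_pool)) variant_pool <- unique(a$subunits$variant)
  if (!nrow(a$bridges)) return(0L)
  evhh <- a$bridges$site_a == EVHH_SITE & a$bridges$site_b == EVHH_SITE
  if (!any(evhh)) return(0L)
  ## variants usable as fresh docking dimers
  pool_ok <- vapply(variant_pool, function(v) {
    if (a$recruitment_rule && !v %in% MODIFIED_VARIANTS) return(FALSE)
    TRUE
  }, logical(1))
  pool <- variant_pool[pool_ok]
  if (!length(pool)) return(0L)
  count <- 0L
  lateral <- setdiff(HOMOTYPIC_SITES, EVHH_SITE)
  for (r in which(evhh)) {
    sa <- a$bridges$sub_a[r]; sb <- a$bridges$sub_b[r]
    va <- subunit_variant(a, sa); vb <- subunit_variant(a, sb)
    for (X in lateral) {
      if (!X %in% interface_sites(va) || !X %in% interface_sites(vb)) next
      if (!site_is_free(a, sa, X) || !site_is_free(a, sb, X)) next
      ## host sides must be allowed to engage their lateral sites
      if (a$recruitment_rule && (va == "WT" || vb == "WT")) next
      ## a fresh dimer in the pool must carry the matching site type
      if (!any(vapply(pool, function(v) X %in% interface_sites(v), TRUE))) next
      count <- count + 1L
    }
  }
  count
}

#' Can the assembly be extended?
#'
#' @param a A \code{zn_assembly}.
#' @param variant_pool Variants available as fresh subunits.
#' @return \code{TRUE} iff [free_seed_count()] is positive for the pool.
#' @export
can_extend <- function(a, variant_pool = NULL) {
  if (!nrow(a$subunits)) return(FALSE)
  free_seed_count(a, variant_pool) > 0L
}

#' Build a named oligomer topology
#'
#' Constructs the study's oligomer models as assembly graphs:
#' \describe{
#'   \item{dimer_EVHH}{two D7H subunits, one E11/H14:ZN:E11/H14 bridge.}
#'   \item{tetramer_E3H6, tetramer_H7H13}{two EVHH dimers joined by two
#'     bridges of the second interface type.}
#'   \item{octamer}{two tetramer blocks (one E3/H6-joined, one H7/H13-joined)
#'     chained through a single E3/H6 junction.}
#'   \item{dodecamer}{three tetramer blocks (one E3/H6-joined, two
#'     H7/H13-joined) chained through two E3/H6 junctions; this equilibrium
#'     arrangement exposes exactly three polymerization seeds.}
#'   \item{heterotrimer_D7H, heterotrimer_isoD7}{a central modified subunit
#'     bridged through both of its non-E3 sites (E11/H14 plus H7/H13 for D7H,
#'     E11/H14 plus H6/H13 for isoD7) to the E11/H14 sites of two flanking
#'     unmodified subunits.}
#' }
#' In the octamer and dodecamer lattices, junctions between dimer blocks are
#' single zinc bridges; the standalone tetramers use the fully paired
#' two-bridge junction.
#'
#' @param name Topology name.
#' @return A \code{zn_assembly} with \code{metadata$topology} set and, where
#'   applicable, an orientation annotation.
#' @examples
#' dd <- build_named_assembly("dodecamer")
#' free_seed_count(dd)
#' @export
build_named_assembly <- function(name) {
  name <- match.arg(name, c("dimer_EVHH", "tetramer_E3H6", "tetramer_H7H13",
                            "octamer", "dodecamer", "heterotrimer_D7H",
                            "heterotrimer_isoD7"))
  E <- EVHH_SITE
  dimer_pair <- function(a, i, j) add_bridge(a, c(i, E), c(j, E))
  if (name == "dimer_EVHH") {
    a <- new_assembly(rep("D7H", 2))
    a <- dimer_pair(a, 1, 2)
    a$metadata <- list(topology = name, orientation = "antiparallel")
  } else if (name %in% c("tetramer_E3H6", "tetramer_H7H13")) {
    X <- if (name == "tetramer_E3H6") "E3/H6" else "H7/H13"
    a <- new_assembly(rep("D7H", 4))
    a <- dimer_pair(a, 1, 2); a <- dimer_pair(a, 3, 4)
    a <- add_bridge(a, c(1, X), c(3, X))
    a <- add_bridge(a, c(2, X), c(4, X))
    a$metadata <- list(topology = name, orientation = "antiparallel")
  } else if (name == "octamer") {
    a <- new_assembly(rep("D7H", 8))
    for (k in 1:4) a <- dimer_pair(a, 2 * k - 1, 2 * k)
    a <- add_bridge(a, c(2, "E3/H6"), c(3, "E3/H6"))     # block 1 internal
    a <- add_bridge(a, c(4, "E3/H6"), c(5, "E3/H6"))     # junction
    a <- add_bridge(a, c(6, "H7/H13"), c(7, "H7/H13"))   # block 2 internal
    a$metadata <- list(topology = name, orientation = "antiparallel")
  } else if (name == "dodecamer") {
    a <- new_assembly(rep("D7H", 12))
    for (k in 1:6) a <- dimer_pair(a, 2 * k - 1, 2 * k)
    a <- add_bridge(a, c(2, "E3/H6"), c(3, "E3/H6"))     # tetramer 1 internal (E3/H6)
    a <- add_bridge(a, c(4, "E3/H6"), c(5, "E3/H6"))     # junction 1-2
    a <- add_bridge(a, c(6, "H7/H13"), c(7, "H7/H13"))   # tetramer 2 internal (H7/H13)
    a <- add_bridge(a, c(8, "E3/H6"), c(9, "E3/H6"))     # junction 2-3
    a <- add_bridge(a, c(10, "H7/H13"), c(11, "H7/H13")) # tetramer 3 internal (H7/H13)
    a$metadata <- list(topology = name, orientation = "antiparallel")
  } else {
    central <- if (name == "heterotrimer_D7H") "D7H" else "isoD7"
    second <- if (central == "D7H") "H7/H13" else "H6/H13"
    a <- new_assembly(c(central, "WT", "WT"))
    a <- add_bridge(a, c(1, E), c(2, E))
    a <- add_bridge(a, c(1, second), c(3, E))
    a$metadata <- list(topology = name,
                       orientation = if (central == "D7H") "parallel"
                                     else "antiparallel flanker")
  }
  stopifnot(is_connected_assembly(a))
  a
}

#' @export
print.zn_assembly <- function(x, ...) {
  cat("zn_assembly: ", nrow(x$subunits), " subunits, ", nrow(x$bridges),
      " zinc bridge(s)", sep = "")
  if (!is.null(x$metadata$topology)) cat(" [", x$metadata$topology, "]", sep = "")
  cat("\n")
  if (nrow(x$subunits)) {
    tab <- table(x$subunits$variant)
    cat("  variants:", paste(names(tab), tab, sep = ":", collapse = ", "), "\n")
  }
  if (nrow(x$bridges)) {
    lab <- paste0(x$bridges$sub_a, ".", x$bridges$site_a, " -Zn- ",
                  x$bridges$sub_b, ".", x$bridges$site_b)
    cat(paste0("  ", lab, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Serialize an assembly as a simple graph-interchange text
#'
#' Writes a node list (id, variant, per-site occupancy) and an edge list
#' (endpoints with site labels).
#'
#' @param a A \code{zn_assembly}.
#' @param file Output path.
#' @return Invisibly, \code{file}.
#' @export
write_assembly <- function(a, file) {
  stopifnot(inherits(a, "zn_assembly"))
  lines <- c("# zn_assembly", "# subunits: id variant occupied_sites")
  for (i in seq_len(nrow(a$subunits))) {
    id <- a$subunits$id[i]
    used <- c(a$bridges$site_a[a$bridges$sub_a == id],
              a$bridges$site_b[a$bridges$sub_b == id])
    lines <- c(lines, paste(id, a$subunits$variant[i],
                            if (length(used)) paste(used, collapse = ",") else "-"))
  }
  lines <- c(lines, "# bridges: sub_a site_a sub_b site_b")
  for (i in seq_len(nrow(a$bridges)))
    lines <- c(lines, paste(a$bridges$sub_a[i], a$bridges$site_a[i],
                            a$bridges$sub_b[i], a$bridges$site_b[i]))
  writeLines(lines, file)
  invisible(file)
}

#' Convert an assembly to an igraph graph
#'
#' @param a A \code{zn_assembly}.
#' @return An \pkg{igraph} graph with subunit vertices (variant attribute)
#'   and zinc-bridge edges (site attributes).
#' @export
assembly_to_igraph <- function(a) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("the igraph package is required for graph export")
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = a$bridges$sub_a, to = a$bridges$sub_b,
                   site_a = a$bridges$site_a, site_b = a$bridges$site_b),
    directed = FALSE,
    vertices = data.frame(name = a$subunits$id, variant = a$subunits$variant))
  g
}
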