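#' Infer zinc-chelating residues by fragment intersection
#'
#' Localizes the residues that chelate zinc in peptide-Zn(n) complexes from a
#' set of annotated CID/ECD spectra, by intersecting the spans of fragment
#' ions that retain different numbers of zinc ions:
#' \enumerate{
#'   \item collect zinc-carrying assigned spans per zinc count, discarding
#'     assignments whose span contains fewer chelation-capable positions than
#'     retained zinc ions;
#'   \item keep minimal spans: spans with no assigned strict sub-span at the
#'     same zinc count (pooled across spectra);
#'   \item score each chelation-capable position: every minimal span
#'     contributes its spectrum-incidence count divided by the number of
#'     capable positions it contains (so short, localizing spans carry more
#'     weight than coarse multi-zinc spans), and scores are normalized so the
#'     maximum is 1;
#'   \item flag cleavage-suppressed regions: backbone cleavage sites observed
#'     in zinc-free assignments but never in zinc-carrying spectra, which
#'     suggests a zinc bridge across the region;
#'   \item candidates are the capable positions with score at or above the
#'     threshold, plus capable positions interior to suppressed regions.
#' }
#'
#' @param spectra A list of [annotate_spectrum()] results (a single object is
#'   accepted).
#' @param p The peptide.
#' @param threshold Normalized-score threshold for candidacy (default 0.5).
#' @param capable_set Chelation-capable residue types.
#' @param include_nterm Whether the free N-terminal amine counts as a
#'   candidate chelator (pseudo-position 0).
#' @param use_minimal_spans,use_capability_filter,use_suppression Switches for
#'   the individual algorithm steps, for auditability.
#' @return An object of class \code{chelator_report} with elements
#'   \code{candidate_scores} (named numeric, normalized to max 1),
#'   \code{minimal_zinc_spans}, \code{cleavage_suppressed_regions},
#'   \code{final_candidates} (ranked positions) and \code{flagged_empty}.
#' @examples
#' # see the synthetic generator synth_spectra() for a full round trip
#' @export
infer_chelators <- function(spectra, p, threshold = 0.5,
                            capable_set = DEFAULT_CHELATION_SET,
                            include_nterm = TRUE,
                            use_minimal_spans = TRUE,
                            use_capability_filter = TRUE,
                            use_suppression = TRUE) {
  if (inherits(spectra, "annotated_spectrum")) spectra <- list(spectra)
  stopifnot(all(vapply(spectra, inherits, TRUE, "annotated_spectrum")),
            inherits(p, "peptide"))
  capable <- chelation_capable_positions(p, capable_set = capable_set,
                                         include_nterm = include_nterm)
  n <- length(p$residues)

  ## per-spectrum zinc-carrying spans after the capability consistency filter
  span_tab <- list()
  for (s in seq_along(spectra)) {
    a <- spectra[[s]]$assignments
    a <- a[a$n_zinc > 0, , drop = FALSE]
    if (!nrow(a)) next
    if (use_capability_filter) {
      ncap <- vapply(seq_len(nrow(a)), function(r)
        sum(capable >= a$start[r] & capable <= a$end[r]), integer(1))
      a <- a[a$n_zinc <= ncap, , drop = FALSE]
    }
    if (nrow(a))
      span_tab[[length(span_tab) + 1L]] <-
        data.frame(spectrum = s, start = a$start, end = a$end,
                   n_zinc = a$n_zinc)
  }

  if (!length(span_tab)) {
    return(structure(list(
      candidate_scores = setNames(numeric(length(capable)), capable),
      minimal_zinc_spans = data.frame(start = integer(0), end = integer(0),
                                      n_zinc = integer(0)),
      cleavage_suppressed_regions = data.frame(start = integer(0),
                                               end = integer(0)),
      final_candidates = integer(0),
      flagged_empty = TRUE), class = "chelator_report"))
  }
  spans <- do.call(rbind, span_tab)
  ## unique spans (pooled over spectra) with incidence counts
  key <- paste(spans$start, spans$end, spans$n_zinc)
  uspans <- spans[!duplicated(key), c("start", "end", "n_zinc"), drop = FALSE]
  uspans$count <- as.integer(table(key)[paste(uspans$start, uspans$end,
                                              uspans$n_zinc)])
  if (use_minimal_spans) {
    keep <- vapply(seq_len(nrow(uspans)), function(r) {
      same_k <- uspans$n_zinc == uspans$n_zinc[r]
      sub <- same_k & uspans$start >= uspans$start[r] &
        uspans$end <= uspans$end[r] &
        (uspans$start > uspans$start[r] | uspans$end < uspans$end[r])
      !any(sub)
    }, logical(1))
    minimal <- uspans[keep, , drop = FALSE]
  } else minimal <- uspans
  rownames(minimal) <- NULL

  ncap_in <- vapply(seq_len(nrow(minimal)), function(r)
    max(1L, sum(capable >= minimal$start[r] & capable <= minimal$end[r])),
    integer(1))
  scores <- vapply(capable, function(pos) {
    hit <- minimal$start <= pos & minimal$end >= pos
    sum(minimal$count[hit] / ncap_in[hit])
  }, numeric(1))
  if (max(scores) > 0) scores <- scores / max(scores)
  names(scores) <- capable

  ## cleavage suppression: backbone sites cleaved in apo assignments but never
  ## in spectra of zinc-carrying precursors
  suppressed <- data.frame(start = integer(0), end = integer(0))
  if (use_suppression) {
    cleav_sites <- function(a) {
      a <- a[a$series %in% c("b", "y", "c", "z"), , drop = FALSE]
      if (!nrow(a)) return(integer(0))
      ## a terminal fragment spanning [i, j] implies cleavage after j (N-terminal
      ## series) or before i (C-terminal series); site s = bond between s and s+1
      sites <- ifelse(a$series %in% c("b", "c"), a$end, a$start - 1L)
      unique(sites[sites >= 1L & sites < n])
    }
    is_holo <- vapply(spectra, function(x) {
      pz <- x$precursor$n_zinc
      if (!is.null(pz)) pz > 0 else any(x$assignments$n_zinc > 0)
    }, logical(1))
    apo_sites <- unique(unlist(lapply(spectra[!is_holo], function(x)
      cleav_sites(x$assignments))))
    holo_sites <- unique(unlist(lapply(spectra[is_holo], function(x)
      cleav_sites(x$assignments))))
    supp <- sort(setdiff(apo_sites, holo_sites))
    if (length(supp) && any(is_holo)) {
      brk <- c(0, which(diff(supp) > 1L), length(supp))
      reg <- lapply(seq_len(length(brk) - 1L), function(i)
        supp[(brk[i] + 1L):brk[i + 1L]])
      suppressed <- do.call(rbind, lapply(reg, function(r)
        data.frame(start = min(r), end = max(r) + 1L)))
    }
  }

  final <- capable[scores >= threshold & scores > 0]
  if (nrow(suppressed)) {
    for (r in seq_len(nrow(suppressed))) {
      interior <- capable[capable > suppressed$start[r] &
                            capable < suppressed$end[r]]
      final <- union(final, interior)
    }
  }
  final <- final[order(-scores[as.character(final)], final)]

  structure(list(candidate_scores = scores,
                 minimal_zinc_spans = minimal,
                 cleavage_suppressed_regions = suppressed,
                 final_candidates = as.integer(final),
                 flagged_empty = FALSE),
            class = "chelator_report")
}

#' @export
print.chelator_report <- function(x, ...) {
  if (x$flagged_empty) {
    cat("chelator_report: no zinc-carrying assignments (flagged empty)\n")
    return(invisible(x))
  }
  cat("chelator_report\n")
  cat("  candidates (ranked):",
      paste(x$final_candidates, collapse = ", "), "\n")
  cat("  minimal zinc-carrying spans:\n")
  print(x$minimal_zinc_spans)
  if (nrow(x$cleavage_suppressed_regions)) {
    cat("  cleavage-suppressed regions:\n")
    print(x$cleavage_suppressed_regions)
  }
  invisible(x)
}
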