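#' Peak list container
#'
#' @param mz Numeric vector of m/z values (> 0).
#' @param intensity Numeric vector of intensities (>= 0).
#' @param precursor Optional list with elements \code{mz}, \code{charge},
#'   \code{n_zinc} describing the isolated precursor.
#' @param activation \code{"CID"} or \code{"ECD"}.
#' @param title Optional spectrum title.
#' @return A data frame of class \code{peak_list}.
#' @export
peak_list <- function(mz, intensity = rep(1, length(mz)), precursor = NULL,
                      activation = c("CID", "ECD"), title = NULL) {
  activation <- match.arg(activation)
  if (any(mz <= 0)) stop("m/z values must be positive")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (length(mz) != length(intensity))
    stop("'mz' and 'intensity' must have equal length")
  out <- data.frame(mz = mz, intensity = intensity)
  class(out) <- c("peak_list", "data.frame")
  attr(out, "precursor") <- precursor
  attr(out, "activation") <- activation
  attr(out, "title") <- title
  out
}

#' Annotate a peak list against theoretical fragments
#'
#' Each peak is matched against the theoretical fragment table of the peptide
#' within a ppm tolerance.  Ties are broken by preferring fewer zinc adducts,
#' then lower charge, then terminal over internal fragments, then smaller ppm
#' error; each peak retains at most one assignment.  When the precursor zinc
#' count is known, assignments cannot carry more zinc than the precursor.
#'
#' @param peaks A [peak_list()].
#' @param p The [build_peptide()] object the spectrum was acquired from.
#' @param tolerance_ppm Matching tolerance in ppm (default 5, FT-ICR class).
#' @param fragments Optional precomputed [generate_fragments()] table.
#' @param ... Passed to [generate_fragments()] when \code{fragments} is NULL;
#'   by default the series are chosen from the activation (b/y + internal for
#'   CID, c/z + internal for ECD).
#' @return An object of class \code{annotated_spectrum}: a list with elements
#'   \code{assignments} (data frame: peak mz, intensity, ion, series, start,
#'   end, charge, n_zinc, ppm_error), \code{unassigned}, \code{tolerance_ppm},
#'   \code{activation} and \code{precursor}.
#' @export
annotate_spectrum <- function(peaks, p, tolerance_ppm = 5, fragments = NULL,
                              ...) {
  stopifnot(inherits(peaks, "peak_list"), inherits(p, "peptide"))
  if (!nrow(peaks)) stop("'peaks' must be non-empty")
  activation <- attr(peaks, "activation")
  precursor <- attr(peaks, "precursor")
  if (is.null(fragments)) {
    series <- if (identical(activation, "ECD")) c("c", "z", "internal")
              else c("b", "y", "internal")
    fragments <- generate_fragments(p, series = series, ...)
  }
  if (!is.null(precursor$n_zinc))
    fragments <- fragments[fragments$n_zinc <= precursor$n_zinc, , drop = FALSE]

  assign_rows <- vector("list", nrow(peaks))
  taken <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    ppm <- (peaks$mz[i] - fragments$mz) / fragments$mz * 1e6
    cand <- which(abs(ppm) <= tolerance_ppm)
    if (!length(cand)) next
    ord <- order(fragments$n_zinc[cand], fragments$charge[cand],
                 fragments$series[cand] == "internal", abs(ppm[cand]))
    best <- cand[ord[1]]
    taken[i] <- TRUE
    assign_rows[[i]] <- data.frame(
      mz = peaks$mz[i], intensity = peaks$intensity[i],
      ion = fragments$ion[best], series = fragments$series[best],
      start = fragments$start[best], end = fragments$end[best],
      charge = fragments$charge[best], n_zinc = fragments$n_zinc[best],
      ppm_error = ppm[best], stringsAsFactors = FALSE)
  }
  assignments <- if (any(taken)) do.call(rbind, assign_rows[taken]) else
    data.frame(mz = numeric(0), intensity = numeric(0), ion = character(0),
               series = character(0), start = integer(0), end = integer(0),
               charge = integer(0), n_zinc = integer(0),
               ppm_error = numeric(0))
  rownames(assignments) <- NULL
  structure(list(assignments = assignments,
                 unassigned = as.data.frame(peaks)[!taken, , drop = FALSE],
                 tolerance_ppm = tolerance_ppm,
                 activation = activation,
                 precursor = precursor),
            class = "annotated_spectrum")
}

#' @export
print.annotated_spectrum <- function(x, ...) {
  cat("annotated_spectrum (", x$activation, "): ", nrow(x$assignments),
      " assigned, ", nrow(x$unassigned), " unassigned at ", x$tolerance_ppm,
      " ppm\n", sep = "")
  if (!is.null(x$precursor))
    cat("  precursor: z=", x$precursor$charge, ", zinc=", x$precursor$n_zinc,
        "\n", sep = "")
  invisible(x)
}

#' Write an annotated spectrum as a delimited table
#'
#' @param x An \code{annotated_spectrum}.
#' @param file Output path.
#' @param sep Field separator.
#' @return Invisibly, \code{file}.
#' @export
write_annotation_table <- function(x, file, sep = "\t") {
  stopifnot(inherits(x, "annotated_spectrum"))
  utils::write.table(x$assignments, file, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' Read peak lists from an MGF file
#'
#' Minimal Mascot-generic-format reader: BEGIN IONS/END IONS blocks with
#' TITLE, PEPMASS, CHARGE and optional ZINC and ACTIVATION headers, followed
#' by mz/intensity pairs.
#'
#' @param file Path to an MGF file.
#' @return A list of [peak_list()] objects.
#' @export
read_mgf <- function(file) {
  lines <- readLines(file)
  starts <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  if (length(starts) != length(ends)) stop("malformed MGF: unbalanced blocks")
  out <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    block <- lines[(starts[b] + 1L):(ends[b] - 1L)]
    is_hdr <- grepl("^[A-Z]+=", block)
    hdr <- block[is_hdr]
    getv <- function(key) {
      hit <- grep(paste0("^", key, "="), hdr, value = TRUE)
      if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else NULL
    }
    dat <- block[!is_hdr & nzchar(block)]
    m <- do.call(rbind, lapply(strsplit(dat, "[ \t]+"), as.numeric))
    charge <- getv("CHARGE")
    if (!is.null(charge)) charge <- as.integer(sub("[+-]$", "", charge))
    prec <- NULL
    if (!is.null(getv("PEPMASS")))
      prec <- list(mz = as.numeric(strsplit(getv("PEPMASS"), "[ \t]+")[[1]][1]),
                   charge = charge,
                   n_zinc = if (!is.null(getv("ZINC"))) as.integer(getv("ZINC")) else NULL)
    act <- getv("ACTIVATION")
    out[[b]] <- peak_list(m[, 1], m[, 2], precursor = prec,
                          activation = if (!is.null(act)) act else "CID",
                          title = getv("TITLE"))
  }
  out
}

#' Write peak lists to an MGF file
#'
#' @param peak_lists A [peak_list()] or list thereof.
#' @param file Output path.
#' @return Invisibly, \code{file}.
#' @export
write_mgf <- function(peak_lists, file) {
  if (inherits(peak_lists, "peak_list")) peak_lists <- list(peak_lists)
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_along(peak_lists)) {
    pl <- peak_lists[[i]]
    writeLines("BEGIN IONS", con)
    title <- attr(pl, "title")
    writeLines(paste0("TITLE=", if (is.null(title)) paste0("spectrum_", i) else title), con)
    prec <- attr(pl, "precursor")
    if (!is.null(prec)) {
      writeLines(sprintf("PEPMASS=%.6f", prec$mz), con)
      if (!is.null(prec$charge)) writeLines(sprintf("CHARGE=%d+", prec$charge), con)
      if (!is.null(prec$n_zinc)) writeLines(sprintf("ZINC=%d", prec$n_zinc), con)
    }
    writeLines(paste0("ACTIVATION=", attr(pl, "activation")), con)
    writeLines(sprintf("%.6f %.2f", pl$mz, pl$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(file)
}

#' Read a two-column delimited peak table
#'
#' @param file Path to a delimited file with columns mz and intensity
#'   (header optional).
#' @param activation Activation label for the resulting peak list.
#' @param sep Field separator.
#' @return A [peak_list()].
#' @export
read_peak_table <- function(file, activation = "CID", sep = "\t") {
  first <- readLines(file, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  tab <- utils::read.table(file, header = has_header, sep = sep)
  peak_list(tab[[1]], tab[[2]], activation = activation)
}
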