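#' Binding model with one or two independent classes of sites
#'
#' Parameterizes Zn(2+) binding to a peptide as one or two independent classes
#' of sites, each with a stoichiometry N (sites per peptide), an association
#' constant Ka (1/M) and a molar enthalpy change dH (kcal/mol).  This is the
#' standard calorimetric "two independent sets of sites" model.
#'
#' @param N Numeric vector (length 1 or 2) of stoichiometries, N >= 0.
#' @param Ka Numeric vector of association constants (1/M), Ka > 0.
#' @param dH Numeric vector of enthalpies (kcal/mol).
#' @return An object of class \code{itc_model}.
#' @examples
#' # Two-site model for the Taiwan-mutant metal-binding domain
#' itc_model(N = c(0.35, 1), Ka = c(48e4, 2.3e4), dH = c(-8.0, -10.3))
#' @export
itc_model <- function(N, Ka, dH) {
  n <- length(N)
  if (n < 1L || n > 2L) stop("between 1 and 2 site classes are supported")
  if (length(Ka) != n || length(dH) != n)
    stop("'N', 'Ka' and 'dH' must have equal length")
  if (any(!is.finite(N)) || any(N < 0)) stop("N must be finite and >= 0")
  if (any(!is.finite(Ka)) || any(Ka <= 0)) stop("Ka must be finite and > 0")
  if (any(!is.finite(dH))) stop("dH must be finite")
  structure(list(N = as.numeric(N), Ka = as.numeric(Ka), dH = as.numeric(dH)),
            class = "itc_model")
}

#' @export
print.itc_model <- function(x, ...) {
  cat("itc_model with", length(x$N), "independent site class(es)\n")
  print(data.frame(N = x$N, Ka_per_M = x$Ka, dH_kcal_mol = x$dH))
  invisible(x)
}

#' Titration protocol
#'
#' Describes an ITC experiment: ligand (ZnCl2) in the syringe titrated into
#' peptide in the cell.  Defaults mirror the study protocol: 20 injections of
#' 2 uL of 5 mM ligand into 0.3 mM peptide in a 0.2 mL cell at 25 C.
#'
#' @param cell_volume_ul Active cell volume in uL.
#' @param cell_conc_mM Peptide concentration in the cell (mM).
#' @param syringe_conc_mM Ligand concentration in the syringe (mM).
#' @param injection_volumes_ul Vector of injection volumes (uL).
#' @param temperature_C Temperature in degrees Celsius.
#' @return An object of class \code{itc_protocol}.
#' @export
itc_protocol <- function(cell_volume_ul = 200, cell_conc_mM = 0.3,
                         syringe_conc_mM = 5,
                         injection_volumes_ul = rep(2, 20),
                         temperature_C = 25) {
  if (cell_volume_ul <= 0 || cell_conc_mM <= 0 || syringe_conc_mM <= 0)
    stop("volumes and concentrations must be positive")
  if (any(injection_volumes_ul <= 0)) stop("injection volumes must be positive")
  structure(list(cell_volume_ul = cell_volume_ul,
                 cell_conc_mM = cell_conc_mM,
                 syringe_conc_mM = syringe_conc_mM,
                 injection_volumes_ul = as.numeric(injection_volumes_ul),
                 temperature_C = temperature_C),
            class = "itc_protocol")
}

#' @export
print.itc_protocol <- function(x, ...) {
  cat(sprintf("itc_protocol: %d injections (%g uL total) of %g mM ligand into %g mM peptide, %g uL cell, %g C\n",
              length(x$injection_volumes_ul), sum(x$injection_volumes_ul),
              x$syringe_conc_mM, x$cell_conc_mM, x$cell_volume_ul,
              x$temperature_C))
  invisible(x)
}

## Free-ligand concentration from total ligand and macromolecule totals by
## bracketed root finding on the mass balance
##   Xt = L + Mt * sum_i N_i Ka_i L / (1 + Ka_i L),  L in [0, Xt].
solve_free_ligand <- function(Xt, Mt, N, Ka, rel_tol = 1e-12) {
  if (Xt <= 0) return(0)
  f <- function(L) L + Mt * sum(N * Ka * L / (1 + Ka * L)) - Xt
  stats::uniroot(f, lower = 0, upper = Xt,
                 tol = max(rel_tol * Xt, .Machine$double.xmin),
                 check.conv = TRUE)$root
}

## Cumulative binding heat (kcal) at given totals, with cell volume in uL.
cumulative_heat <- function(Xt, Mt, model, cell_volume_ul) {
  L <- solve_free_ligand(Xt, Mt, model$N, model$Ka)
  theta <- model$Ka * L / (1 + model$Ka * L)
  ## V0 [L] * Mt [mol/L] * sum(N dH theta) [kcal/mol] -> kcal
  (cell_volume_ul * 1e-6) * Mt * sum(model$N * model$dH * theta)
}

#' Simulate a titration curve
#'
#' Forward simulation of per-injection heats for an independent-sites binding
#' model under the perfusion (overflow) dilution convention.  After the k-th
#' injection, with cumulative injected volume v, total concentrations in the
#' cell are \deqn{M_t = M_0 (1 - v/2V_0)/(1 + v/2V_0), \quad
#' X_t = X_0 (v/V_0)/(1 + v/2V_0).}  The free ligand concentration is solved
#' from the mass balance by bracketed root finding, the cumulative heat is
#' \eqn{Q = V_0 M_t \sum_i N_i \Delta H_i \theta_i}, and the per-injection heat
#' includes the trapezoidal displacement correction
#' \eqn{dq_k = Q_k - Q_{k-1} + (dV_k/V_0)(Q_k + Q_{k-1})/2}, normalized per mol
#' of injected ligand.
#'
#' @param model An [itc_model()].
#' @param protocol An [itc_protocol()].
#' @return A data frame of class \code{itc_curve} with columns
#'   \code{injection}, \code{volume_uL}, \code{molar_ratio} (Zn/peptide) and
#'   \code{heat} (kcal per mol of injectant), carrying the protocol and the
#'   cumulative heats as attributes.
#' @examples
#' curve <- itc_simulate(itc_model(1, 2.3e4, -10.3), itc_protocol())
#' head(curve)
#' @export
itc_simulate <- function(model, protocol) {
  stopifnot(inherits(model, "itc_model"), inherits(protocol, "itc_protocol"))
  V0 <- protocol$cell_volume_ul
  dV <- protocol$injection_volumes_ul
  M0 <- protocol$cell_conc_mM * 1e-3
  X0 <- protocol$syringe_conc_mM * 1e-3
  v <- cumsum(dV)
  Mt <- M0 * (1 - v / (2 * V0)) / (1 + v / (2 * V0))
  Xt <- X0 * (v / V0) / (1 + v / (2 * V0))
  if (any(Mt <= 0))
    stop("injected volume too large: cell peptide concentration became non-positive")
  Q <- vapply(seq_along(v), function(k)
    cumulative_heat(Xt[k], Mt[k], model, V0), numeric(1))
  Qprev <- c(0, Q[-length(Q)])
  dq <- Q - Qprev + (dV / V0) * (Q + Qprev) / 2      # kcal
  mol_inj <- X0 * dV * 1e-6                          # mol of ligand per injection
  heat <- dq / mol_inj                               # kcal / mol injectant
  out <- data.frame(injection = seq_along(dV), volume_uL = dV,
                    molar_ratio = Xt / Mt, heat = heat)
  class(out) <- c("itc_curve", "data.frame")
  attr(out, "protocol") <- protocol
  attr(out, "model") <- model
  attr(out, "Q_cumulative") <- Q
  attr(out, "dq_raw") <- dq
  out
}

#' Build a titration curve from observed heats
#'
#' @param molar_ratio Zn/peptide molar ratio per injection (strictly
#'   increasing).
#' @param heat Heat per mol of injectant (kcal/mol) per injection.
#' @param protocol The [itc_protocol()] that produced the data (required for
#'   fitting).
#' @param volume_uL Optional per-injection volumes; defaults to the protocol's.
#' @return An \code{itc_curve} data frame.
#' @export
itc_curve <- function(molar_ratio, heat, protocol, volume_uL = NULL) {
  stopifnot(inherits(protocol, "itc_protocol"))
  if (length(molar_ratio) != length(heat))
    stop("'molar_ratio' and 'heat' must have equal length")
  if (any(diff(molar_ratio) <= 0))
    stop("'molar_ratio' must be strictly increasing")
  if (is.null(volume_uL)) volume_uL <- protocol$injection_volumes_ul
  if (length(volume_uL) != length(heat))
    stop("injection schedule does not match the number of heats")
  out <- data.frame(injection = seq_along(heat), volume_uL = volume_uL,
                    molar_ratio = molar_ratio, heat = heat)
  class(out) <- c("itc_curve", "data.frame")
  attr(out, "protocol") <- protocol
  out
}

#' Subtract a blank (dilution) titration
#'
#' Element-wise subtraction of ligand-into-buffer dilution heats from the
#' reaction heats; the injection schedule must match.
#'
#' @param curve,blank \code{itc_curve} objects with identical injection
#'   schedules.
#' @return The blank-corrected \code{itc_curve}.
#' @export
subtract_blank <- function(curve, blank) {
  stopifnot(inherits(curve, "itc_curve"), inherits(blank, "itc_curve"))
  if (nrow(curve) != nrow(blank) ||
      any(abs(curve$volume_uL - blank$volume_uL) > 1e-9))
    stop("injection schedules of curve and blank do not match")
  curve$heat <- curve$heat - blank$heat
  curve
}

#' @export
plot.itc_curve <- function(x, ...) {
  graphics::plot(x$molar_ratio, x$heat, xlab = "molar ratio (Zn/peptide)",
                 ylab = "kcal / mol of injectant", ...)
  invisible(x)
}

#' Read a titration record from a delimited table
#'
#' Expects columns \code{injection_index}, \code{volume_uL} and either
#' \code{heat_kcal_mol} (kcal per mol injectant) or \code{heat_ucal}
#' (microcalories per injection, converted using the protocol).
#'
#' @param file Path to a tab- or comma-delimited table.
#' @param protocol The [itc_protocol()] describing the run.
#' @param sep Field separator (default tab).
#' @return An \code{itc_curve}.
#' @export
read_itc_table <- function(file, protocol, sep = "\t") {
  tab <- utils::read.table(file, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("injection_index", "volume_uL")
  if (!all(need %in% names(tab)))
    stop("table must contain columns: ", paste(need, collapse = ", "))
  tab <- tab[order(tab$injection_index), ]
  if ("heat_kcal_mol" %in% names(tab)) {
    heat <- tab$heat_kcal_mol
  } else if ("heat_ucal" %in% names(tab)) {
    mol_inj <- protocol$syringe_conc_mM * 1e-3 * tab$volume_uL * 1e-6
    heat <- tab$heat_ucal * 1e-9 / mol_inj   # ucal -> kcal, then per mol
  } else stop("table must contain 'heat_kcal_mol' or 'heat_ucal'")
  V0 <- protocol$cell_volume_ul
  v <- cumsum(tab$volume_uL)
  Mt <- protocol$cell_conc_mM * 1e-3 * (1 - v / (2 * V0)) / (1 + v / (2 * V0))
  Xt <- protocol$syringe_conc_mM * 1e-3 * (v / V0) / (1 + v / (2 * V0))
  itc_curve(molar_ratio = Xt / Mt, heat = heat, protocol = protocol,
            volume_uL = tab$volume_uL)
}

#' Write a titration record to a delimited table
#'
#' @param curve An \code{itc_curve}.
#' @param file Output path.
#' @param sep Field separator (default tab).
#' @return Invisibly, \code{file}.
#' @export
write_itc_table <- function(curve, file, sep = "\t") {
  stopifnot(inherits(curve, "itc_curve"))
  tab <- data.frame(injection_index = curve$injection,
                    volume_uL = curve$volume_uL,
                    heat_kcal_mol = curve$heat)
  utils::write.table(tab, file, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(file)
}
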