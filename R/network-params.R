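# Parameters for the GnRH receptor-network ODE model.

#' Parameters for the receptor-network model
#'
#' Constructs the parameter object for [simulate_network()]. Defaults are the
#' package's calibrated values; any subset can be overridden by name. Rates
#' are per minute, concentrations in uM, and the ligand association constant
#' `kon` in /M/min (the stimulus is in M).
#'
#' The model tracks surface receptor, hormone-occupied receptor (HR) and
#' internalized receptor; active PLC; cytoplasmic Ca2+; cytoplasmic and
#' nuclear ppERK; a four-state NFAT phosphorylation/localization cycle; and
#' nuclear Egr1. Agonist-induced internalization (`int_mult * kint_base`) and
#' recycling (`rec_mult * krec_base`) are the only receptor-level feedback.
#'
#' @param ... Named parameter overrides. Unknown names are an error.
#' @param int_mult Internalization rate multiplier (dimensionless fold of the
#'   base rate); scans in this package use `[0.001, 32]`.
#' @param rec_mult Recycling rate multiplier.
#'
#' @section Parameters:
#' \describe{
#'   \item{kon, koff}{GnRH-receptor binding (/M/min, /min).}
#'   \item{kint_base, krec_base}{Base internalization and recycling rates of
#'     occupied/internalized receptor (/min).}
#'   \item{Rtot}{Total receptor (uM).}
#'   \item{kplc_on, kplc_off, PLCtot}{PLC activation by HR (/uM/min),
#'     deactivation (/min) and total PLC (uM).}
#'   \item{kclear, ca_basal, v_ca, K_ca, h_ca}{Ca2+ clearance (/min), basal
#'     Ca2+ (uM), maximal PLC-driven release (uM/min) and its Hill constant
#'     (PLC fraction) and coefficient.}
#'   \item{erk_tot, kact_e, K_e_plc, K_e_ca, h_e_ca, kdeact_e, kimp_e,
#'     kexp_e}{ERK tier: total ERK (uM), maximal activation rate (/min) with
#'     PLC-fraction Michaelis constant and Ca2+ Hill terms, deactivation and
#'     nuclear import/export rates (/min).}
#'   \item{nfat_tot, kdep, K_cn, h_cn, kphos_c, kimp_n, kphos_n,
#'     kexp_n}{NFAT cycle: total NFAT (uM), maximal calcineurin-mediated
#'     dephosphorylation rate (/min) with Ca2+ Hill constant (uM) and
#'     coefficient, cytoplasmic rephosphorylation, nuclear import, nuclear
#'     rephosphorylation and nuclear export rates (/min).}
#'   \item{ksyn_eg, K_eg, kdeg_eg}{Egr1 synthesis driven by nuclear ppERK
#'     (uM/min, Michaelis constant uM) and first-order loss (/min).}
#' }
#'
#' @return An object of class `network_params` (named list).
#' @examples
#' network_params(int_mult = 8)
#' @export
network_params <- function(..., int_mult = 1, rec_mult = 1) {
  defaults <- list(
    kon = 1e9, koff = 6,
    kint_base = 0.018, krec_base = 0.018,
    int_mult = int_mult, rec_mult = rec_mult,
    Rtot = 0.01,
    kplc_on = 140, kplc_off = 0.7, PLCtot = 0.05,
    kclear = 0.8, ca_basal = 0.05, v_ca = 3, K_ca = 0.65, h_ca = 4,
    erk_tot = 1, kact_e = 0.35, K_e_plc = 0.01, K_e_ca = 1.3, h_e_ca = 2,
    kdeact_e = 1.2, kimp_e = 0.5, kexp_e = 0.25,
    nfat_tot = 1, kdep = 0.06, K_cn = 0.4, h_cn = 3,
    kphos_c = 0.5, kimp_n = 0.08, kphos_n = 0.015, kexp_n = 0.018,
    ksyn_eg = 0.02, K_eg = 0.1, kdeg_eg = 0.008
  )
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(defaults))
    stop_if_not(length(unknown) == 0,
                msg = paste0("unknown network parameter(s): ",
                             paste(unknown, collapse = ", ")))
    defaults[names(overrides)] <- overrides
  }
  vals <- unlist(defaults[setdiff(names(defaults), c("int_mult", "rec_mult"))])
  stop_if_not(all(vals > 0), msg = "all network rates and totals must be positive")
  stop_if_not(defaults$int_mult > 0, defaults$rec_mult > 0,
              msg = "int_mult and rec_mult must be positive")
  structure(defaults, class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  cat("<network_params>\n")
  cat(sprintf("  int_mult %g, rec_mult %g, Rtot %g uM, Kd %g M\n",
              x$int_mult, x$rec_mult, x$Rtot, x$koff / x$kon))
  other <- setdiff(names(x), c("int_mult", "rec_mult"))
  cat("  ", paste(sprintf("%s=%g", other, unlist(x[other])), collapse = ", "), "\n")
  invisible(x)
}
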