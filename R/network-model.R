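# GnRH receptor-network ODE model: binding, internalization/recycling, PLC,
# Ca2+, ERK with nuclear ppERK, a four-state NFAT cycle, and Egr1.

# internal canonical state order
.network_state_names <- c("R_surf", "HR", "R_int", "PLC_active", "Ca_cyt",
                          "ppERK_cyt", "ppERK_nuc", "NFAT_cyt_P", "NFAT_cyt_deP",
                          "NFAT_nuc_deP", "NFAT_nuc_P", "Egr1_nuc")

# internal: derivative of the 12-state network given scalar stimulus S (M)
.network_deriv <- function(y, p, S) {
  kint <- p$int_mult * p$kint_base
  krec <- p$rec_mult * p$krec_base
  Rs <- y[1]; HR <- y[2]; Ri <- y[3]; PLC <- y[4]; Ca <- y[5]
  Ec <- y[6]; En <- y[7]; NcP <- y[8]; NcD <- y[9]; NnD <- y[10]; NnP <- y[11]
  Eg <- y[12]
  bind <- p$kon * S * Rs
  unbind <- p$koff * HR
  dRs <- -bind + unbind + krec * Ri
  dHR <- bind - unbind - kint * HR
  dRi <- kint * HR - krec * Ri
  dPLC <- p$kplc_on * HR * (p$PLCtot - PLC) - p$kplc_off * PLC
  pf <- PLC / p$PLCtot
  dCa <- p$kclear * (p$ca_basal - Ca) +
    p$v_ca * pf^p$h_ca / (p$K_ca^p$h_ca + pf^p$h_ca)
  act <- p$kact_e * (pf / (p$K_e_plc + pf)) *
    (Ca^p$h_e_ca / (p$K_e_ca^p$h_e_ca + Ca^p$h_e_ca))
  dEc <- act * (p$erk_tot - Ec - En) - p$kdeact_e * Ec - p$kimp_e * Ec + p$kexp_e * En
  dEn <- p$kimp_e * Ec - p$kexp_e * En - p$kdeact_e * En
  cn <- Ca^p$h_cn / (p$K_cn^p$h_cn + Ca^p$h_cn)
  dNcP <- p$kphos_c * NcD + p$kexp_n * NnP - p$kdep * cn * NcP
  dNcD <- p$kdep * cn * NcP - (p$kphos_c + p$kimp_n) * NcD
  dNnD <- p$kimp_n * NcD - p$kphos_n * NnD
  dNnP <- p$kphos_n * NnD - p$kexp_n * NnP
  dEg <- p$ksyn_eg * En / (p$K_eg + En) - p$kdeg_eg * Eg
  c(dRs, dHR, dRi, dPLC, dCa, dEc, dEn, dNcP, dNcD, dNnD, dNnP, dEg)
}

#' Right-hand side of the receptor-network ODEs
#'
#' Computes the time derivative of the network state under a pulse protocol.
#' Receptor pools and NFAT pools are conserved by construction (their
#' derivatives sum to zero exactly).
#'
#' @param state Named numeric vector with elements `R_surf`, `HR`, `R_int`,
#'   `PLC_active`, `Ca_cyt`, `ppERK_cyt`, `ppERK_nuc`, `NFAT_cyt_P`,
#'   `NFAT_cyt_deP`, `NFAT_nuc_deP`, `NFAT_nuc_P`, `Egr1_nuc` (uM).
#' @param t Time (min).
#' @param params A [network_params()].
#' @param protocol A [pulse_protocol()].
#' @return Named numeric vector of derivatives (uM/min).
#' @examples
#' p <- network_params()
#' y <- resting_steady_state(p)
#' prot <- pulse_protocol(1e-7, 5, 60, 960)
#' network_rhs(y, 0, p, prot)
#' @export
network_rhs <- function(state, t, params, protocol) {
  stopifnot(inherits(params, "network_params"), inherits(protocol, "pulse_protocol"))
  stop_if_not(length(state) == 12, msg = "`state` must have 12 elements")
  if (!is.null(names(state))) {
    stop_if_not(setequal(names(state), .network_state_names),
                msg = "`state` names must match the network state names")
    state <- state[.network_state_names]
  }
  stop_if_not(all(state >= -1e-12),
              msg = "contract violation: negative state component")
  d <- .network_deriv(unname(state), params, signal_at(protocol, t))
  setNames(d, .network_state_names)
}

#' Resting steady state of the receptor network
#'
#' Integrates the network without stimulus from an analytic initial guess
#' until the derivative norm is below `tol`. At rest all receptor is on the
#' surface, Ca2+ sits at its basal value and NFAT is overwhelmingly
#' cytoplasmic-phosphorylated.
#'
#' @param params A [network_params()].
#' @param tol Maximum allowed infinity-norm of the right-hand side at the
#'   returned state (default 1e-10).
#' @return Named numeric state vector (see [network_rhs()]).
#' @export
resting_steady_state <- function(params, tol = 1e-10) {
  stopifnot(inherits(params, "network_params"))
  y0 <- c(params$Rtot, 0, 0, 0, params$ca_basal, 0, 0, params$nfat_tot,
          0, 0, 0, 0)
  f <- function(t, y, parms) list(.network_deriv(y, params, 0))
  out <- deSolve::ode(y0, c(0, 5000, 10000), f, NULL, method = "lsoda",
                      rtol = 1e-12, atol = 1e-14)
  y <- unname(out[nrow(out), -1])
  res <- max(abs(.network_deriv(y, params, 0)))
  if (res > tol) {
    stop(sprintf("resting steady state did not converge: residual %.3e > %.3e",
                 res, tol), call. = FALSE)
  }
  setNames(y, .network_state_names)
}

# internal: segment-wise integration of a rhs driven by a square wave.
# deriv_fn(y, S) returns the derivative vector; returns matrix with time in
# column 1 and states after, on a uniform grid of step dt.
.integrate_pulsed <- function(deriv_fn, y0, protocol, dt = 0.1, rtol = 1e-8,
                              atol = 1e-12) {
  horizon <- protocol$horizon
  f <- function(t, y, parms) list(deriv_fn(y, parms))
  grid <- seq(0, horizon, by = dt)
  if (abs(grid[length(grid)] - horizon) > 1e-9) grid <- c(grid, horizon)
  if (is_constant_protocol(protocol)) {
    out <- deSolve::ode(y0, grid, f, protocol$amplitude, method = "lsoda",
                        rtol = rtol, atol = atol)
    return(unname(out[, seq_len(length(y0) + 1), drop = FALSE]))
  }
  starts <- seq(0, horizon, by = protocol$period)
  brk <- sort(unique(pmin(c(starts, starts + protocol$width, horizon), horizon)))
  res <- matrix(NA_real_, length(grid), length(y0) + 1)
  res[1, ] <- c(0, y0)
  y <- y0
  filled <- 1
  for (i in seq_len(length(brk) - 1)) {
    t0 <- brk[i]; t1 <- brk[i + 1]
    if (t1 <= t0) next
    S <- if ((t0 %% protocol$period) < protocol$width - 1e-9) protocol$amplitude
         else protocol$baseline
    tt <- grid[grid > t0 + 1e-9 & grid <= t1 + 1e-9]
    times <- sort(unique(c(t0, tt, t1)))
    out <- tryCatch(
      deSolve::ode(y, times, f, S, method = "lsoda", rtol = rtol, atol = atol),
      warning = function(w) stop(sprintf(
        "integrator failure in segment [%g, %g] (S = %g): %s",
        t0, t1, S, conditionMessage(w)), call. = FALSE))
    y <- unname(out[nrow(out), -1])
    keep <- which(times %in% tt)
    if (length(keep)) {
      res[filled + seq_along(keep), ] <- out[keep, seq_len(length(y0) + 1)]
      filled <- filled + length(keep)
    }
  }
  res[seq_len(filled), , drop = FALSE]
}

#' Simulate the receptor network under a pulse protocol
#'
#' Integrates the network from its resting steady state with a stiff-capable
#' adaptive solver (lsoda), splitting the integration at every pulse edge so
#' the square-wave input is exact. Output is on a uniform grid.
#'
#' @param params A [network_params()].
#' @param protocol A [pulse_protocol()].
#' @param dt Output grid step (min), default 0.1.
#' @param rtol,atol Solver tolerances.
#' @param full If `TRUE`, include every state variable as a column (needed
#'   for conservation checks); default returns the reported channels only.
#' @param y0 Optional initial state (defaults to [resting_steady_state()];
#'   passing a precomputed state avoids recomputing it across scans).
#' @return A tibble of class `network_timecourse` with columns `time_min`,
#'   `HR_uM`, `PLC_uM`, `Ca_uM`, `ppERK_nuc_uM`, `NFAT_NF`, `Egr1_uM` (and
#'   all states when `full = TRUE`). The parameters and protocol are attached
#'   as attributes `params` and `protocol`.
#' @examples
#' \donttest{
#' tc <- simulate_network(network_params(), pulse_protocol(1e-7, 5, 60, 240))
#' head(tc)
#' }
#' @export
simulate_network <- function(params = network_params(),
                             protocol = pulse_protocol(1e-7, 5, 60, 960),
                             dt = 0.1, rtol = 1e-8, atol = 1e-12,
                             full = FALSE, y0 = NULL) {
  stopifnot(inherits(params, "network_params"), inherits(protocol, "pulse_protocol"))
  stop_if_not(dt > 0, dt <= 0.1 + 1e-12,
              msg = "`dt` must be positive and at most 0.1 min")
  if (is.null(y0)) y0 <- resting_steady_state(params)
  y0 <- unname(y0[.network_state_names])
  m <- .integrate_pulsed(function(y, S) .network_deriv(y, params, S),
                         y0, protocol, dt = dt, rtol = rtol, atol = atol)
  colnames(m) <- c("time_min", .network_state_names)
  df <- tibble::as_tibble(as.data.frame(m))
  nf <- (df$NFAT_nuc_deP + df$NFAT_nuc_P) / params$nfat_tot
  out <- tibble::tibble(
    time_min = df$time_min,
    HR_uM = df$HR,
    PLC_uM = df$PLC_active,
    Ca_uM = df$Ca_cyt,
    ppERK_nuc_uM = df$ppERK_nuc,
    NFAT_NF = nf,
    Egr1_uM = df$Egr1_nuc
  )
  if (full) {
    extra <- df[setdiff(names(df), "time_min")]
    names(extra) <- paste0(names(extra), "_state")
    out <- dplyr::bind_cols(out, extra)
  }
  attr(out, "params") <- params
  attr(out, "protocol") <- protocol
  class(out) <- c("network_timecourse", class(out))
  out
}

#' @method autoplot network_timecourse
#' @export
autoplot.network_timecourse <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("time_min", "HR_uM", "PLC_uM", "Ca_uM",
                                "ppERK_nuc_uM", "NFAT_NF", "Egr1_uM")],
    -"time_min", names_to = "channel", values_to = "value")
  long$channel <- factor(long$channel, levels = c("HR_uM", "PLC_uM", "Ca_uM",
                                                  "ppERK_nuc_uM", "NFAT_NF",
                                                  "Egr1_uM"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_min, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, scales = "free_y", ncol = 2) +
    ggplot2::labs(x = "time (min)", y = NULL)
}
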