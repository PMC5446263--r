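# Minimal pulse-decoding cascade: stimulus -> E1; E1* -> E2 (slow) and E3
# (fast) with Michaelis-Menten activation and inactivation.

#' Parameters for the minimal cascade
#'
#' For each effector `i` in 1..3: `total_i` (a.u.), activation rate constant
#' `kact_i` (/min), activation Michaelis constant `Kact_i` (a.u.), maximal
#' inactivation rate `Vinact_i` (a.u./min) and inactivation Michaelis
#' constant `Kinact_i` (a.u.). E1 and E3 are fast (effective time constants
#' well under a minute), E2 is slow (at least 10-fold slower); the
#' constructor enforces the separation.
#'
#' @param ... Named overrides of the defaults (e.g. `kact_2 = 1`). Unknown
#'   names are an error.
#' @return An object of class `minimal_params`.
#' @examples
#' minimal_params()
#' @export
minimal_params <- function(...) {
  defaults <- list(
    total_1 = 1, kact_1 = 2.2, Kact_1 = 4,   Vinact_1 = 7,    Kinact_1 = 4,
    total_2 = 1, kact_2 = 2.2, Kact_2 = 1.4, Vinact_2 = 0.11, Kinact_2 = 1.35,
    total_3 = 1, kact_3 = 10,  Kact_3 = 8,   Vinact_3 = 18,   Kinact_3 = 8
  )
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(defaults))
    stop_if_not(length(unknown) == 0,
                msg = paste0("unknown minimal-model parameter(s): ",
                             paste(unknown, collapse = ", ")))
    defaults[names(overrides)] <- overrides
  }
  stop_if_not(all(unlist(defaults) > 0),
              msg = "all minimal-model parameters must be positive")
  p <- structure(defaults, class = "minimal_params")
  tau <- minimal_time_constants(p)
  stop_if_not(tau[["E2"]] >= 10 * max(tau[["E1"]], tau[["E3"]]),
              msg = sprintf(paste0(
                "invariant violated: E2 time constant (%.2f min) must be at ",
                "least 10-fold longer than E1 (%.2f) and E3 (%.2f)"),
                tau[["E2"]], tau[["E1"]], tau[["E3"]]))
  p
}

#' Effective relaxation time constants of the minimal cascade
#'
#' Linearized decay time constant of each effector near the off state
#' (`Kinact_i / Vinact_i` min), the scale on which an activated effector
#' relaxes once its input is removed.
#'
#' @param params A [minimal_params()].
#' @return Named numeric vector `c(E1 = , E2 = , E3 = )` in minutes.
#' @export
minimal_time_constants <- function(params) {
  stopifnot(inherits(params, "minimal_params"))
  vapply(1:3, function(i) {
    params[[paste0("Kinact_", i)]] / params[[paste0("Vinact_", i)]]
  }, numeric(1)) |> setNames(c("E1", "E2", "E3"))
}

#' @export
print.minimal_params <- function(x, ...) {
  cat("<minimal_params>\n")
  for (i in 1:3) {
    cat(sprintf("  E%d: total %g, kact %g, Kact %g, Vinact %g, Kinact %g\n",
                i, x[[paste0("total_", i)]], x[[paste0("kact_", i)]],
                x[[paste0("Kact_", i)]], x[[paste0("Vinact_", i)]],
                x[[paste0("Kinact_", i)]]))
  }
  invisible(x)
}

# internal: derivative of (E1*, E2*, E3*) given dimensionless stimulus S
.minimal_deriv <- function(y, p, S) {
  mm_act <- function(free, K) free / (K + free)
  mm_in <- function(act, K) act / (K + act)
  d1 <- S * p$kact_1 * mm_act(p$total_1 - y[1], p$Kact_1) -
    p$Vinact_1 * mm_in(y[1], p$Kinact_1)
  d2 <- y[1] * p$kact_2 * mm_act(p$total_2 - y[2], p$Kact_2) -
    p$Vinact_2 * mm_in(y[2], p$Kinact_2)
  d3 <- y[1] * p$kact_3 * mm_act(p$total_3 - y[3], p$Kact_3) -
    p$Vinact_3 * mm_in(y[3], p$Kinact_3)
  c(d1, d2, d3)
}

#' Right-hand side of the minimal cascade
#'
#' The stimulus enters as a dimensionless 0/1 multiplier (1 during a pulse),
#' so the protocol amplitude only distinguishes ON from baseline.
#'
#' @param state Numeric vector `c(E1_star, E2_star, E3_star)` (optionally
#'   named).
#' @param t Time (min).
#' @param params A [minimal_params()].
#' @param protocol A [pulse_protocol()].
#' @return Named derivative vector (a.u./min).
#' @export
minimal_rhs <- function(state, t, params, protocol) {
  stopifnot(inherits(params, "minimal_params"), inherits(protocol, "pulse_protocol"))
  stop_if_not(length(state) == 3, msg = "`state` must have 3 elements")
  tot <- c(params$total_1, params$total_2, params$total_3)
  stop_if_not(all(state >= -1e-12), all(state <= tot + 1e-12),
              msg = "state out of bounds [0, total_i]")
  S <- as.numeric(signal_at(protocol, t) > protocol$baseline)
  setNames(.minimal_deriv(unname(state), params, S),
           c("E1_star", "E2_star", "E3_star"))
}

#' Simulate the minimal cascade under a pulse protocol
#'
#' Integrates from the all-zero state with a stiff-capable adaptive solver,
#' splitting at pulse edges; output on a uniform grid.
#'
#' @param params A [minimal_params()].
#' @param protocol A [pulse_protocol()].
#' @param dt Output grid step (min), at most 0.1.
#' @param rtol,atol Solver tolerances.
#' @return A tibble of class `minimal_timecourse` with columns `time_min`,
#'   `E1_star`, `E2_star`, `E3_star`.
#' @examples
#' tc <- simulate_minimal(minimal_params(), pulse_protocol(1, 4, 32, 128))
#' effector_auc(tc)
#' @export
simulate_minimal <- function(params = minimal_params(),
                             protocol = pulse_protocol(1, 4, 32, 1024),
                             dt = 0.1, rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(params, "minimal_params"), inherits(protocol, "pulse_protocol"))
  stop_if_not(dt > 0, dt <= 0.1 + 1e-12,
              msg = "`dt` must be positive and at most 0.1 min")
  # binary drive: ON segments use S = 1 (0 if the protocol never rises
  # above its baseline)
  on <- as.numeric(protocol$amplitude > protocol$baseline)
  drive <- pulse_protocol(on, protocol$width, protocol$period,
                          protocol$horizon, baseline = 0)
  m <- tryCatch(
    .integrate_pulsed(function(y, S) .minimal_deriv(y, params, S),
                      c(0, 0, 0), drive, dt = dt, rtol = rtol, atol = atol),
    error = function(e) stop(sprintf(
      "simulate_minimal failed (width %g, period %g): %s", protocol$width,
      protocol$period, conditionMessage(e)), call. = FALSE))
  colnames(m) <- c("time_min", "E1_star", "E2_star", "E3_star")
  out <- tibble::as_tibble(as.data.frame(m))
  attr(out, "params") <- params
  attr(out, "protocol") <- protocol
  class(out) <- c("minimal_timecourse", class(out))
  out
}

#' Trapezoidal AUC of the active effectors
#'
#' @param timecourse A `minimal_timecourse` from [simulate_minimal()].
#' @param horizon Upper limit (min); defaults to the full trace and must not
#'   exceed it.
#' @return A tibble with one row: `E1_auc`, `E2_auc`, `E3_auc` (a.u. * min).
#' @export
effector_auc <- function(timecourse, horizon = max(timecourse$time_min)) {
  need <- c("time_min", "E1_star", "E2_star", "E3_star")
  stop_if_not(all(need %in% names(timecourse)),
              msg = "timecourse lacks minimal-cascade columns")
  stop_if_not(horizon <= max(timecourse$time_min) + 1e-9,
              msg = sprintf("horizon (%g) exceeds trace end (%g)",
                            horizon, max(timecourse$time_min)))
  keep <- timecourse$time_min <= horizon + 1e-9
  t <- timecourse$time_min[keep]
  tibble::tibble(
    E1_auc = pracma::trapz(t, timecourse$E1_star[keep]),
    E2_auc = pracma::trapz(t, timecourse$E2_star[keep]),
    E3_auc = pracma::trapz(t, timecourse$E3_star[keep])
  )
}

#' Frequency scan of the minimal cascade
#'
#' One simulation per period; either fixed pulse width (non-compensated) or
#' a fixed duty fraction via [compensated_family()] so the input integral is
#' equal across the family.
#'
#' @param params A [minimal_params()].
#' @param periods Pulse periods (min).
#' @param width Pulse width (min) for non-compensated scans.
#' @param duty_fraction Duty fraction for compensated scans.
#' @param compensated If `TRUE`, widths are `duty_fraction * period`.
#' @param horizon Simulation horizon (min); for compensated scans it must be
#'   a common multiple of the periods.
#' @param dt,rtol Grid step and solver tolerance.
#' @return A tibble of class `scan_result` with columns `width_min`,
#'   `period_min`, `frequency_per_hr`, `input_integral`, `E1_auc`, `E2_auc`,
#'   `E3_auc`.
#' @examples
#' \donttest{
#' minimal_frequency_scan(periods = c(32, 64, 128), horizon = 512)
#' }
#' @export
minimal_frequency_scan <- function(params = minimal_params(), periods,
                                   width = 4, duty_fraction = 1 / 12,
                                   compensated = FALSE, horizon = 1024,
                                   dt = 0.1, rtol = 1e-8) {
  stopifnot(inherits(params, "minimal_params"))
  protocols <- if (compensated) {
    compensated_family(duty_fraction, periods, amplitude = 1, horizon = horizon)
  } else {
    stop_if_not(all(periods >= width), msg = "all periods must be >= width")
    lapply(periods, function(T) pulse_protocol(1, width, T, horizon))
  }
  rows <- purrr::map(protocols, function(prot) {
    tc <- simulate_minimal(params, prot, dt = dt, rtol = rtol)
    dplyr::bind_cols(
      tibble::tibble(width_min = prot$width, period_min = prot$period,
                     frequency_per_hr = 60 / prot$period,
                     input_integral = input_integral(prot)),
      effector_auc(tc))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, axis = "period_min", class = c("scan_result", class(out)))
}

#' @method autoplot minimal_timecourse
#' @export
autoplot.minimal_timecourse <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object), -"time_min",
    names_to = "effector", values_to = "active")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_min, y = .data$active)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~effector, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "active effector (a.u.)")
}
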