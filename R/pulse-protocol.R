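# Square-wave pulse protocols: construction, evaluation, exact integrals and
# compensated families.

#' Create a square-wave pulse protocol
#'
#' A pulse protocol is a square-wave stimulus train: pulses of `amplitude`
#' lasting `width` minutes start every `period` minutes, beginning at t = 0,
#' with `baseline` concentration between pulses, over `horizon` minutes.
#' `width == period` encodes constant stimulation.
#'
#' @param amplitude Stimulus concentration during a pulse (M).
#' @param width Pulse duration (min); must satisfy `0 < width <= period`.
#' @param period Pulse interval, start to start (min).
#' @param horizon Total simulated time (min); must be positive.
#' @param baseline Concentration between pulses (M); default 0 and must
#'   satisfy `amplitude >= baseline >= 0`.
#'
#' @return An object of class `pulse_protocol` (a named list).
#' @examples
#' pulse_protocol(1e-7, width = 5, period = 60, horizon = 960)
#' # constant stimulation:
#' pulse_protocol(1e-7, width = 4, period = 4, horizon = 960)
#' @export
pulse_protocol <- function(amplitude, width, period, horizon, baseline = 0) {
  stop_if_not(is.numeric(amplitude), length(amplitude) == 1, is.finite(amplitude),
              msg = "`amplitude` must be a single finite number")
  stop_if_not(is.numeric(width), length(width) == 1, is.finite(width), width > 0,
              msg = "`width` must be a single positive number")
  stop_if_not(is.numeric(period), length(period) == 1, is.finite(period),
              msg = "`period` must be a single finite number")
  stop_if_not(width <= period,
              msg = sprintf("protocol invariant violated: width (%g) must be <= period (%g)",
                            width, period))
  stop_if_not(is.numeric(horizon), length(horizon) == 1, is.finite(horizon), horizon > 0,
              msg = "`horizon` must be a single positive number")
  stop_if_not(is.numeric(baseline), length(baseline) == 1, baseline >= 0,
              msg = "`baseline` must be a single non-negative number")
  stop_if_not(amplitude >= baseline,
              msg = sprintf("protocol invariant violated: amplitude (%g) must be >= baseline (%g)",
                            amplitude, baseline))
  structure(
    list(amplitude = amplitude, width = width, period = period,
         horizon = horizon, baseline = baseline),
    class = "pulse_protocol"
  )
}

#' @export
print.pulse_protocol <- function(x, ...) {
  kind <- if (is_constant_protocol(x)) "constant stimulation" else "pulsatile"
  cat(sprintf(
    "<pulse_protocol> %s\n  amplitude %g M, width %g min, period %g min, horizon %g min, baseline %g M\n",
    kind, x$amplitude, x$width, x$period, x$horizon, x$baseline))
  invisible(x)
}

#' Is a protocol constant stimulation?
#'
#' @param protocol A [pulse_protocol()].
#' @return `TRUE` when `width == period` (the square wave never switches off).
#' @export
is_constant_protocol <- function(protocol) {
  stopifnot(inherits(protocol, "pulse_protocol"))
  protocol$width >= protocol$period
}

#' Evaluate a pulse protocol at given times
#'
#' Pulses start at t = 0; the stimulus equals `amplitude` whenever
#' `(t %% period) < width` and `baseline` otherwise.
#'
#' @param protocol A [pulse_protocol()].
#' @param t Time or vector of times (min), each within `[0, horizon]`.
#' @return Concentration(s) in M, same length as `t`.
#' @examples
#' p <- pulse_protocol(1e-7, 5, 60, 960)
#' signal_at(p, c(2, 30))
#' @export
signal_at <- function(protocol, t) {
  stopifnot(inherits(protocol, "pulse_protocol"))
  stop_if_not(is.numeric(t), all(is.finite(t)),
              msg = "`t` must be numeric and finite")
  stop_if_not(all(t >= 0), all(t <= protocol$horizon),
              msg = sprintf("`t` outside [0, %g]", protocol$horizon))
  if (is_constant_protocol(protocol)) {
    return(rep(protocol$amplitude, length(t)))
  }
  phase <- t %% protocol$period
  ifelse(phase < protocol$width, protocol$amplitude, protocol$baseline)
}

#' Exact input integral of a pulse protocol
#'
#' Closed-form time integral of [signal_at()] over `[0, horizon]`, counting
#' partial trailing pulses.
#'
#' @param protocol A [pulse_protocol()].
#' @param horizon Upper integration limit (min); defaults to the protocol
#'   horizon and must not exceed it.
#' @return Input integral in M*min.
#' @examples
#' input_integral(pulse_protocol(1, 2, 24, 384))  # 32
#' @export
input_integral <- function(protocol, horizon = protocol$horizon) {
  stopifnot(inherits(protocol, "pulse_protocol"))
  stop_if_not(is.numeric(horizon), length(horizon) == 1, horizon >= 0,
              msg = "`horizon` must be a single non-negative number")
  stop_if_not(horizon <= protocol$horizon,
              msg = sprintf("`horizon` (%g) exceeds protocol horizon (%g)",
                            horizon, protocol$horizon))
  if (is_constant_protocol(protocol)) {
    return(protocol$amplitude * horizon)
  }
  n_full <- floor(horizon / protocol$period)
  tail_t <- horizon - n_full * protocol$period
  on_time <- n_full * protocol$width + min(tail_t, protocol$width)
  protocol$amplitude * on_time + protocol$baseline * (horizon - on_time)
}

#' Compensated protocol family with equal input integral
#'
#' Builds one protocol per period with `width = duty_fraction * period`, so
#' any increase in frequency is offset by a reduction in pulse width and the
#' input integral over `horizon` is identical for every member.
#'
#' @param duty_fraction Fraction of each period spent ON, in `(0, 1]`.
#' @param periods Vector of pulse periods (min).
#' @param amplitude Pulse amplitude (M).
#' @param horizon Common horizon (min); must be a common multiple of all
#'   periods so the integrals are exactly equal.
#' @param baseline Between-pulse concentration (M), default 0.
#' @return A list of [pulse_protocol()] objects, one per period.
#' @examples
#' fam <- compensated_family(1 / 12, c(24, 384), amplitude = 1, horizon = 384)
#' vapply(fam, input_integral, numeric(1))  # both 32
#' @export
compensated_family <- function(duty_fraction, periods, amplitude, horizon,
                               baseline = 0) {
  stop_if_not(is.numeric(duty_fraction), length(duty_fraction) == 1,
              duty_fraction > 0, duty_fraction <= 1,
              msg = "`duty_fraction` must be a single number in (0, 1]")
  stop_if_not(is.numeric(periods), length(periods) >= 1, all(periods > 0),
              msg = "`periods` must be positive")
  ratio <- horizon / periods
  stop_if_not(all(abs(ratio - round(ratio)) < 1e-9),
              msg = paste0("`horizon` (", horizon, ") must be a common multiple of all ",
                           "periods; offending periods: ",
                           paste(periods[abs(ratio - round(ratio)) >= 1e-9], collapse = ", "),
                           " (unequal input integrals would result)"))
  lapply(periods, function(T) {
    pulse_protocol(amplitude, width = duty_fraction * T, period = T,
                   horizon = horizon, baseline = baseline)
  })
}

#' Tabulate a pulse protocol on a time grid
#'
#' @param x A [pulse_protocol()].
#' @param dt Grid step (min), default 0.1.
#' @param ... Unused.
#' @return A tibble with columns `time_min` and `stimulus_M`.
#' @method tidy pulse_protocol
#' @export
tidy.pulse_protocol <- function(x, dt = 0.1, ...) {
  tt <- seq(0, x$horizon, by = dt)
  tibble::tibble(time_min = tt, stimulus_M = signal_at(x, tt))
}

#' @method autoplot pulse_protocol
#' @export
autoplot.pulse_protocol <- function(object, dt = 0.1, ...) {
  df <- tidy.pulse_protocol(object, dt = dt)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min, y = .data$stimulus_M)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (min)", y = "stimulus (M)",
                  title = sprintf("Pulse protocol: width %g min, period %g min",
                                  object$width, object$period))
}

# internal: assertion helper that raises a single informative error
stop_if_not <- function(..., msg) {
  conds <- list(...)
  ok <- vapply(conds, function(x) isTRUE(all(x)), logical(1))
  if (!all(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
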