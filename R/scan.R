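# Frequency-, dose- and internalization scans with AUC readouts, optimal
# period identification and shape classification.

# channels reported by every network scan
.scan_channels <- c("PLC_uM", "Ca_uM", "ppERK_nuc_uM", "NFAT_NF", "Egr1_uM")

# internal: AUC of every scan channel of one network timecourse (optionally
# plus a reporter driven by `gate`)
.channel_aucs <- function(tc, gate = NULL) {
  t <- tc$time_min
  out <- vapply(.scan_channels, function(ch) pracma::trapz(t, tc[[ch]]),
                numeric(1))
  names(out) <- sub("_uM$", "", names(out))
  names(out) <- paste0(tolower(names(out)), "_auc")
  names(out) <- sub("nfat_nf", "nfat_nf", names(out))
  if (!is.null(gate)) {
    rep_tc <- simulate_reporter(tc, gate)
    out <- c(out, reporter_auc = attr(rep_tc, "auc"))
  }
  out
}

# internal: run one protocol and return a row of AUCs
.scan_row <- function(params, protocol, gate, y0, dt, rtol) {
  tc <- simulate_network(params, protocol, dt = dt, rtol = rtol, y0 = y0)
  .channel_aucs(tc, gate)
}

#' Frequency scan of the receptor network
#'
#' Simulates the network once per pulse period (constant stimulation encoded
#' as `period == width`), from the resting steady state, and reports the AUC
#' of each output channel over the horizon.
#'
#' @param params A [network_params()].
#' @param periods Pulse periods (min), each `>= width`.
#' @param width Pulse width (min), default 5.
#' @param amplitude GnRH concentration during pulses (M), default 1e-7.
#' @param horizon AUC horizon (min), default 960.
#' @param gate Optional [gate_spec()]; adds a `reporter_auc` column.
#' @param dt,rtol Grid step and solver relative tolerance.
#' @return A tibble of class `scan_result`: one row per period with columns
#'   `period_min`, `frequency_per_hr`, one `<channel>_auc` column each for
#'   PLC, Ca2+, nuclear ppERK, NFAT nuclear fraction and Egr1 (plus
#'   `reporter_auc` with a gate), and metadata columns `int_mult`,
#'   `rec_mult`, `width_min`, `amplitude_M`, `horizon_min`.
#' @examples
#' \donttest{
#' frequency_scan(network_params(), periods = c(15, 30, 60), horizon = 240)
#' }
#' @export
frequency_scan <- function(params = network_params(), periods, width = 5,
                           amplitude = 1e-7, horizon = 960, gate = NULL,
                           dt = 0.1, rtol = 1e-8) {
  stopifnot(inherits(params, "network_params"))
  stop_if_not(length(periods) >= 1, all(periods >= width),
              msg = "all `periods` must be >= `width`")
  y0 <- resting_steady_state(params)
  rows <- purrr::map(periods, function(T) {
    prot <- pulse_protocol(amplitude, width = width, period = T,
                           horizon = horizon)
    tryCatch(.scan_row(params, prot, gate, y0, dt, rtol),
             error = function(e) stop(sprintf(
               "frequency_scan failed at period %g min: %s", T,
               conditionMessage(e)), call. = FALSE))
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  out <- dplyr::bind_cols(
    tibble::tibble(period_min = periods, frequency_per_hr = 60 / periods),
    out,
    tibble::tibble(int_mult = params$int_mult, rec_mult = params$rec_mult,
                   width_min = width, amplitude_M = amplitude,
                   horizon_min = horizon))
  structure(out, axis = "period_min",
            class = c("scan_result", class(out)))
}

#' Dose scan of the receptor network
#'
#' Constant stimulation at each GnRH concentration; otherwise as
#' [frequency_scan()].
#'
#' @inheritParams frequency_scan
#' @param concentrations GnRH concentrations (M), strictly positive.
#' @return A tibble of class `scan_result` with axis column `amplitude_M`.
#' @export
dose_scan <- function(params = network_params(), concentrations,
                      horizon = 960, gate = NULL, dt = 0.1, rtol = 1e-8) {
  stopifnot(inherits(params, "network_params"))
  stop_if_not(length(concentrations) >= 1, all(concentrations > 0),
              msg = "`concentrations` must be positive")
  y0 <- resting_steady_state(params)
  rows <- purrr::map(concentrations, function(conc) {
    prot <- pulse_protocol(conc, width = horizon, period = horizon,
                           horizon = horizon)
    tryCatch(.scan_row(params, prot, gate, y0, dt, rtol),
             error = function(e) stop(sprintf(
               "dose_scan failed at %g M: %s", conc, conditionMessage(e)),
               call. = FALSE))
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  out <- dplyr::bind_cols(
    tibble::tibble(amplitude_M = concentrations),
    out,
    tibble::tibble(int_mult = params$int_mult, rec_mult = params$rec_mult,
                   width_min = horizon, horizon_min = horizon))
  structure(out, axis = "amplitude_M",
            class = c("scan_result", class(out)))
}

#' Internalization-multiplier scan
#'
#' Runs [frequency_scan()] at each internalization multiplier and classifies
#' the Ca2+ (and PLC) frequency-response shape.
#'
#' @inheritParams frequency_scan
#' @param int_mults Internalization multipliers (dimensionless).
#' @param periods Period grid; default `c(5, 15, 30, 60, 120, 240, 480)` with
#'   the first entry equal to `width` (constant stimulation).
#' @return A tibble with one row per multiplier: `int_mult`, shape classes
#'   `ca_shape` and `plc_shape`, the optimal Ca2+ period, and a list-column
#'   `scan` holding each full scan.
#' @export
internalization_scan <- function(params = network_params(), int_mults,
                                 periods = c(5, 15, 30, 60, 120, 240, 480),
                                 width = 5, amplitude = 1e-7, horizon = 960,
                                 dt = 0.1, rtol = 1e-8) {
  stop_if_not(length(int_mults) >= 1, all(int_mults > 0),
              msg = "`int_mults` must be positive")
  scans <- purrr::map(int_mults, function(m) {
    p <- params
    p$int_mult <- m
    frequency_scan(p, periods = periods, width = width, amplitude = amplitude,
                   horizon = horizon, dt = dt, rtol = rtol)
  })
  tibble::tibble(
    int_mult = int_mults,
    ca_shape = vapply(scans, classify_shape, character(1), channel = "ca_auc"),
    plc_shape = vapply(scans, classify_shape, character(1), channel = "plc_auc"),
    ca_optimal_period = vapply(scans, optimal_period, numeric(1),
                               channel = "ca_auc"),
    scan = scans
  )
}

# internal: resolve a channel column in a scan result
.scan_channel <- function(scan, channel) {
  cols <- names(scan)[endsWith(names(scan), "_auc")]
  if (!channel %in% cols) {
    alt <- paste0(sub("_auc$", "", channel), "_auc")
    if (alt %in% cols) channel <- alt
    else stop(sprintf("unknown channel '%s'; available: %s", channel,
                      paste(cols, collapse = ", ")), call. = FALSE)
  }
  channel
}

#' Period maximizing a channel AUC
#'
#' Returns the axis value (period) with the largest AUC for the channel.
#' Values within `tie_tol` (relative, default 0.1%) of the maximum are
#' treated as tied and the tie is broken toward the longer period.
#'
#' @param scan A `scan_result` from [frequency_scan()].
#' @param channel AUC column, e.g. `"ca_auc"` (a bare channel name like
#'   `"ca"` is also accepted).
#' @param tie_tol Relative tie tolerance.
#' @return The optimal period (min).
#' @export
optimal_period <- function(scan, channel = "ca_auc", tie_tol = 0.001) {
  stopifnot(inherits(scan, "scan_result"))
  stop_if_not(nrow(scan) >= 2, msg = "need at least 2 scan points")
  channel <- .scan_channel(scan, channel)
  auc <- scan[[channel]]
  per <- scan$period_min
  tied <- auc >= max(auc) * (1 - tie_tol)
  max(per[tied])
}

#' Classify a frequency-response shape
#'
#' Orders the scan by increasing frequency and classifies the AUC sequence:
#' `bell_shaped` iff an interior point exceeds **both** endpoints by more
#' than `tol` (relative); otherwise `monotonic_increasing` iff every
#' successive AUC is at least `previous * (1 - tol / 10)`; otherwise
#' `other`. Bell shape takes precedence.
#'
#' @param scan A `scan_result`, or a bare numeric vector of AUCs already
#'   ordered by increasing frequency.
#' @param channel AUC column (ignored for a numeric vector).
#' @param tol Relative tolerance, default 0.05.
#' @return One of `"bell_shaped"`, `"monotonic_increasing"`, `"other"`.
#' @examples
#' classify_shape(c(1, 2, 3, 4))  # monotonic_increasing
#' classify_shape(c(1, 5, 2))     # bell_shaped
#' @export
classify_shape <- function(scan, channel = "ca_auc", tol = 0.05) {
  if (is.numeric(scan)) {
    v <- scan
  } else {
    stopifnot(inherits(scan, "scan_result"))
    channel <- .scan_channel(scan, channel)
    ord <- order(scan$frequency_per_hr)
    v <- scan[[channel]][ord]
  }
  stop_if_not(length(v) >= 3, msg = "need at least 3 points to classify")
  n <- length(v)
  inner <- v[2:(n - 1)]
  if (any(inner > (1 + tol) * v[1] & inner > (1 + tol) * v[n])) {
    return("bell_shaped")
  }
  if (all(diff(v) >= -abs(v[-n]) * tol / 10)) {
    return("monotonic_increasing")
  }
  "other"
}

#' @method tidy scan_result
#' @export
tidy.scan_result <- function(x, ...) {
  axis <- attr(x, "axis")
  auc_cols <- names(x)[endsWith(names(x), "_auc")]
  out <- tidyr::pivot_longer(tibble::as_tibble(x)[c(axis, auc_cols)],
                             dplyr::all_of(auc_cols),
                             names_to = "channel", values_to = "auc")
  out$channel <- sub("_auc$", "", out$channel)
  out
}

#' @method glance scan_result
#' @export
glance.scan_result <- function(x, ...) {
  auc_cols <- names(x)[endsWith(names(x), "_auc")]
  shapes <- if (attr(x, "axis") == "period_min" && nrow(x) >= 3) {
    vapply(auc_cols, function(ch) classify_shape(x, ch), character(1))
  } else rep(NA_character_, length(auc_cols))
  tibble::tibble(
    channel = sub("_auc$", "", auc_cols),
    max_auc = vapply(auc_cols, function(ch) max(x[[ch]]), numeric(1)),
    shape = shapes
  )
}

#' @method autoplot scan_result
#' @export
autoplot.scan_result <- function(object, ...) {
  axis <- attr(object, "axis")
  long <- tidy.scan_result(object)
  gg <- ggplot2::ggplot(long, ggplot2::aes(x = .data[[axis]], y = .data$auc)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(y = "AUC")
  if (axis == "amplitude_M") gg <- gg + ggplot2::scale_x_log10()
  gg
}
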