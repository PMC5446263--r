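# Transcriptional logic gates driven by nuclear ppERK (E) and nuclear NFAT (N).

#' Specify a transcriptional gate
#'
#' Five gate modes convert nuclear ppERK (`E`, uM) and the NFAT nuclear
#' fraction (`N`) into a reporter transcription rate:
#' \describe{
#'   \item{ERK_DT}{`vmax * Hill(E; K_E, h_E)` — ERK-driven transcription.}
#'   \item{NFAT_DT}{`vmax * Hill(N; K_N, h_N)`.}
#'   \item{AND}{product of the two Hill terms.}
#'   \item{OR}{probabilistic OR of the two Hill terms.}
#'   \item{COOP}{sequential co-operative promoter: NFAT binds the empty
#'     promoter first (rate `b1 * N`, off `u1`), the ERK-induced factor then
#'     converts the NFAT-bound promoter to the transcribing complex (rate
#'     `b2 * E`); resolution of the transcribing complex (`u2`) evicts both
#'     factors. On the NFAT-free promoter the ERK-induced factor can also
#'     occupy its element non-productively, occluding NFAT recruitment; this
#'     occlusion is co-operative in `E` (`K_block`, `h_block`) and is treated
#'     as a fast equilibrium, scaling the priming rate by the unoccluded
#'     fraction. Transcription rate is `vmax *` (transcribing occupancy).}
#' }
#'
#' @param mode One of `"ERK_DT"`, `"NFAT_DT"`, `"AND"`, `"OR"`, `"COOP"`.
#' @param K_E,h_E Half-saturation (uM) and Hill coefficient for `E`.
#' @param K_N,h_N Half-saturation (nuclear fraction) and Hill coefficient
#'   for `N`.
#' @param b1,u1 COOP priming on-rate (/min per unit `N`) and off-rate (/min).
#' @param b2,u2 COOP conversion on-rate (/min per uM `E`) and resolution
#'   rate (/min).
#' @param K_block,h_block COOP occlusion half-saturation (uM `E`) and Hill
#'   coefficient.
#' @param vmax Maximal transcription rate (uM/min).
#' @param kdeg Reporter degradation rate (/min).
#' @return An object of class `gate_spec`.
#' @examples
#' gate_spec("COOP")
#' @export
gate_spec <- function(mode = c("ERK_DT", "NFAT_DT", "AND", "OR", "COOP"),
                      K_E = 0.02, h_E = 2, K_N = 0.15, h_N = 2,
                      b1 = 0.6, u1 = 0.05, b2 = 30, u2 = 0.2,
                      K_block = 0.01, h_block = 4,
                      vmax = 0.01, kdeg = 0.01) {
  mode <- match.arg(mode)
  vals <- c(K_E = K_E, h_E = h_E, K_N = K_N, h_N = h_N, b1 = b1, u1 = u1,
            b2 = b2, u2 = u2, K_block = K_block, h_block = h_block,
            vmax = vmax, kdeg = kdeg)
  stop_if_not(all(vals > 0), msg = "all gate parameters must be positive")
  stop_if_not(h_E >= 1, h_E <= 4, h_N >= 1, h_N <= 4, h_block >= 1,
              msg = "Hill coefficients h_E and h_N must be in [1, 4]")
  structure(as.list(c(list(mode = mode), as.list(vals))), class = "gate_spec")
}

#' @export
print.gate_spec <- function(x, ...) {
  cat(sprintf("<gate_spec> mode %s\n", x$mode))
  other <- setdiff(names(x), "mode")
  cat("  ", paste(sprintf("%s=%g", other, unlist(x[other])), collapse = ", "), "\n")
  invisible(x)
}

# internal Hill function
.hill <- function(x, K, h) {
  x <- pmax(x, 0)
  x^h / (K^h + x^h)
}

# internal: COOP promoter occupancy derivative.
# occupancy = c(P_nfat, P_active); empty = 1 - sum. The occlusion by the
# ERK-induced factor on the empty promoter is a fast equilibrium: priming
# proceeds from the unoccluded fraction (1 - B(E)).
.coop_deriv <- function(occ, E, N, gate) {
  B <- .hill(E, gate$K_block, gate$h_block)
  P0 <- 1 - occ[1] - occ[2]
  dP1 <- gate$b1 * N * (1 - B) * P0 - (gate$u1 + gate$b2 * E) * occ[1]
  dP2 <- gate$b2 * E * occ[1] - gate$u2 * occ[2]
  c(dP1, dP2)
}

#' Promoter occupancy tibble for the COOP gate
#'
#' Stationary occupancy of the sequential co-operative promoter under fixed
#' `E` and `N` (solves the linear balance equations in closed form).
#'
#' @param E,N Constant nuclear ppERK (uM) and NFAT nuclear fraction.
#' @param gate A COOP [gate_spec()].
#' @return A tibble with columns `empty`, `nfat_bound`, `active` summing to 1
#'   (`empty` includes the occluded promoter fraction).
#' @export
coop_stationary <- function(E, N, gate) {
  stopifnot(inherits(gate, "gate_spec"))
  stop_if_not(gate$mode == "COOP", msg = "`gate` must have mode COOP")
  stop_if_not(E >= 0, N >= 0, msg = "E and N must be non-negative")
  B <- .hill(E, gate$K_block, gate$h_block)
  prime <- gate$b1 * N * (1 - B)
  # stationary: prime*P0 = (u1 + b2 E) P1 - ... solve the 2x2 linear system
  A <- rbind(c(prime + gate$u1 + gate$b2 * E, prime),
             c(-gate$b2 * E, gate$u2))
  b <- c(prime, 0)
  sol <- solve(A, b)
  tibble::tibble(empty = 1 - sum(sol), nfat_bound = sol[1], active = sol[2])
}

#' Instantaneous gate transcription rate
#'
#' @param E Nuclear ppERK (uM).
#' @param N NFAT nuclear fraction.
#' @param gate A [gate_spec()].
#' @param promoter For COOP mode, the current promoter occupancy as a numeric
#'   vector `c(nfat_bound, active)`; ignored otherwise.
#' @return Transcription rate (uM/min).
#' @examples
#' gate_rate(0.02, 0.3, gate_spec("AND"))
#' @export
gate_rate <- function(E, N, gate, promoter = c(0, 0)) {
  stopifnot(inherits(gate, "gate_spec"))
  # tolerate solver-scale negative round-off, reject genuinely negative input
  stop_if_not(all(E >= -1e-9), all(N >= -1e-9),
              msg = "E and N must be non-negative")
  E <- pmax(E, 0)
  N <- pmax(N, 0)
  switch(gate$mode,
    ERK_DT = gate$vmax * .hill(E, gate$K_E, gate$h_E),
    NFAT_DT = gate$vmax * .hill(N, gate$K_N, gate$h_N),
    AND = gate$vmax * .hill(E, gate$K_E, gate$h_E) * .hill(N, gate$K_N, gate$h_N),
    OR = {
      hE <- .hill(E, gate$K_E, gate$h_E)
      hN <- .hill(N, gate$K_N, gate$h_N)
      gate$vmax * (hE + hN - hE * hN)
    },
    COOP = gate$vmax * promoter[2],
    stop("unknown gate mode: ", gate$mode, call. = FALSE)
  )
}

#' Simulate a transcriptional reporter from a network time course
#'
#' Integrates promoter occupancy (COOP mode) and
#' `d(reporter)/dt = gate_rate - kdeg * reporter` from zero reporter along a
#' simulated network time course, interpolating the driving channels
#' (`ppERK_nuc_uM` and `NFAT_NF`) linearly between grid points. Promoter
#' occupancy uses a classical fourth-order Runge-Kutta step per grid
#' interval; the driving grid is at most 0.1 min so this is far below solver
#' tolerance elsewhere.
#'
#' @param timecourse A tibble with columns `time_min`, `ppERK_nuc_uM` and
#'   `NFAT_NF` (e.g. from [simulate_network()]).
#' @param gate A [gate_spec()].
#' @return A tibble of class `reporter_timecourse` with columns `time_min`,
#'   `reporter_uM` and (COOP) `promoter_empty`, `promoter_nfat`,
#'   `promoter_active`; the 960-min (or full-horizon) AUC is attached as
#'   attribute `auc` and via [glance()].
#' @export
simulate_reporter <- function(timecourse, gate) {
  stopifnot(inherits(gate, "gate_spec"))
  need <- c("time_min", "ppERK_nuc_uM", "NFAT_NF")
  missing_cols <- setdiff(need, names(timecourse))
  stop_if_not(length(missing_cols) == 0,
              msg = paste0("timecourse lacks required channel(s): ",
                           paste(missing_cols, collapse = ", ")))
  t <- timecourse$time_min
  E <- timecourse$ppERK_nuc_uM
  N <- timecourse$NFAT_NF
  n <- length(t)
  rep_val <- numeric(n)
  occ <- matrix(0, n, 2)
  y_occ <- c(0, 0)
  r <- 0
  for (i in 2:n) {
    h <- t[i] - t[i - 1]
    if (gate$mode == "COOP") {
      Em <- (E[i - 1] + E[i]) / 2
      Nm <- (N[i - 1] + N[i]) / 2
      k1 <- .coop_deriv(y_occ, E[i - 1], N[i - 1], gate)
      k2 <- .coop_deriv(y_occ + h / 2 * k1, Em, Nm, gate)
      k3 <- .coop_deriv(y_occ + h / 2 * k2, Em, Nm, gate)
      k4 <- .coop_deriv(y_occ + h * k3, E[i], N[i], gate)
      y_occ <- y_occ + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      y_occ <- pmin(pmax(y_occ, 0), 1)
      occ[i, ] <- y_occ
    }
    rate <- gate_rate(E[i], N[i], gate, promoter = y_occ)
    # exact exponential step for the linear reporter ODE with frozen rate
    r <- rate / gate$kdeg + (r - rate / gate$kdeg) * exp(-gate$kdeg * h)
    rep_val[i] <- r
  }
  out <- tibble::tibble(time_min = t, reporter_uM = rep_val)
  if (gate$mode == "COOP") {
    out$promoter_empty <- 1 - occ[, 1] - occ[, 2]
    out$promoter_nfat <- occ[, 1]
    out$promoter_active <- occ[, 2]
  }
  attr(out, "gate") <- gate
  attr(out, "auc") <- pracma::trapz(t, rep_val)
  class(out) <- c("reporter_timecourse", class(out))
  out
}

#' @method glance reporter_timecourse
#' @export
glance.reporter_timecourse <- function(x, ...) {
  g <- attr(x, "gate")
  tibble::tibble(mode = g$mode, auc = attr(x, "auc"),
                 horizon_min = max(x$time_min))
}

#' @method autoplot reporter_timecourse
#' @export
autoplot.reporter_timecourse <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_min, y = .data$reporter_uM)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "reporter (uM)",
                  title = sprintf("%s gate reporter", attr(object, "gate")$mode))
}
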