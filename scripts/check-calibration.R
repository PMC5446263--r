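#!/usr/bin/env Rscript
# Calibration property checks for the shipped default parameters.
#
#   Rscript scripts/check-calibration.R
#
# Re-verifies every behavioral property the defaults were calibrated
# against. Each line prints PASS/FAIL; the script exits non-zero on any
# failure. Runtime is roughly 15-25 minutes on one CPU (it spans the full
# internalization ladder plus gate scans).

suppressPackageStartupMessages({
  library(gnrhpulse)
  library(dplyr)
})

failures <- 0L
check <- function(label, ok, detail = "") {
  status <- if (isTRUE(ok)) "PASS" else { failures <<- failures + 1L; "FAIL" }
  cat(sprintf("[%s] %s%s\n", status, label,
              if (nzchar(detail)) paste0("  (", detail, ")") else ""))
}
auc_of <- function(tc, ch) pracma::trapz(tc$time_min, tc[[ch]])

p0 <- network_params()
prot <- function(width, period, horizon = 960, amp = 1e-7)
  pulse_protocol(amp, width, period, horizon)

## -- Fig 2-style kinetics -----------------------------------------------
tc <- simulate_network(p0, prot(5, 60, 240))
half_on <- function(x, t, t1 = 60) {
  w <- t <= t1
  xx <- x[w]; tt <- t[w]
  pk <- max(xx)
  tt[min(which(xx >= xx[1] + (pk - xx[1]) / 2))]
}
for (ch in c("HR_uM", "PLC_uM", "Ca_uM", "ppERK_nuc_uM")) {
  h <- half_on(tc[[ch]], tc$time_min)
  check(sprintf("upstream on half-time < 10 min: %s", ch), h < 10,
        sprintf("%.1f min", h))
}
tc_long <- simulate_network(p0, prot(5, 60, 960))
for (ch in c("NFAT_NF", "Egr1_uM")) {
  h <- half_on(tc_long[[ch]], tc_long$time_min, t1 = 960)
  check(sprintf("downstream on half-time > 20 min: %s", ch), h > 20,
        sprintf("%.1f min", h))
}

tc30 <- simulate_network(p0, prot(5, 30, 300))
rest_nf <- tc30$NFAT_NF[1]
trough <- min(tc30$NFAT_NF[tc30$time_min >= 60])
check("NFAT_NF inter-pulse trough > 1.05x resting (30-min period)",
      trough > 1.05 * rest_nf, sprintf("ratio %.1f", trough / rest_nf))

for (m in c(1, 0.001)) {
  p <- network_params(int_mult = m)
  tcc <- simulate_network(p, prot(5, 5))
  ratio <- max(tcc$PLC_uM) / tcc$PLC_uM[nrow(tcc)]
  if (m == 1) check("PLC spike/plateau > 1.2 at int_mult 1 (constant)",
                    ratio > 1.2, sprintf("%.2f", ratio))
  else check("PLC spike/plateau < 1.05 at int_mult 0.001 (constant)",
             ratio < 1.05, sprintf("%.3f", ratio))
}

## -- Fig 4: pulsatility mitigates internalization -----------------------
D <- function(period, ch) {
  a <- vapply(c(1, 0.001), function(m) {
    auc_of(simulate_network(network_params(int_mult = m), prot(5, period)), ch)
  }, numeric(1))
  abs(a[1] - a[2]) / a[2]
}
for (ch in c("PLC_uM", "Egr1_uM")) {
  d <- vapply(c(5, 30, 120), D, numeric(1), ch = ch)
  check(sprintf("%s: D(const) > D(30) > D(120)", ch), d[1] > d[2] && d[2] > d[3],
        sprintf("%.3f > %.3f > %.3f", d[1], d[2], d[3]))
  check(sprintf("%s: D(120) < 0.1 * D(const)", ch), d[3] < 0.1 * d[1])
}

## -- internalization/recycling sensitivity ------------------------------
plc_auc <- function(im, rm, period) {
  auc_of(simulate_network(network_params(int_mult = im, rec_mult = rm),
                          prot(5, period)), "PLC_uM")
}
lad <- 2^seq(-5, 5)
m50 <- numeric(2)
for (j in 1:2) {
  period <- c(5, 60)[j]
  ints <- vapply(lad, plc_auc, numeric(1), rm = 1, period = period)
  recs <- vapply(lad, function(m) plc_auc(1, m, period), numeric(1))
  check(sprintf("PLC AUC decreasing in int_mult (period %g)", period),
        all(diff(ints) < 0))
  check(sprintf("PLC AUC increasing in rec_mult (period %g)", period),
        all(diff(recs) > 0))
  plateau <- plc_auc(1e-6, 1, period)
  m50[j] <- approx(ints / plateau, lad, xout = 0.5)$y
}
check("int_mult 50%-drop point right-shifted under pulsatile stimulation",
      m50[2] > m50[1], sprintf("constant %.2f vs pulsed %.2f", m50[1], m50[2]))
r_pulse <- plc_auc(1, 1, 60) / plc_auc(0.03125, 32, 60)
r_const <- plc_auc(1, 1, 5) / plc_auc(0.03125, 32, 5)
check("near-maximal pulsatile PLC output at fitted rates (> 0.8)",
      r_pulse > 0.8, sprintf("%.3f (constant: %.3f)", r_pulse, r_const))

## -- Fig 5 / acceptance shapes ------------------------------------------
for (cond in list(c(1, 15), c(8, 30), c(16, 60))) {
  sc <- frequency_scan(network_params(int_mult = cond[1]),
                       periods = c(15, 30, 60))
  check(sprintf("optimal Ca2+ period %g at int_mult %g", cond[2], cond[1]),
        optimal_period(sc, "ca_auc") == cond[2])
}
isc <- internalization_scan(network_params(), int_mults = lad)
bell_at <- isc$int_mult[isc$ca_shape == "bell_shaped"]
check("smallest bell-shaped Ca2+ multiplier is 4",
      length(bell_at) > 0 && min(bell_at) == 4,
      paste(bell_at, collapse = ","))
check("PLC monotonic increasing at every multiplier",
      all(isc$plc_shape == "monotonic_increasing"))

## -- Fig 6: gates --------------------------------------------------------
for (m in c(0.001, 0.5, 1)) {
  p <- network_params(int_mult = m)
  y0 <- resting_steady_state(p)
  tcs <- lapply(c(5, 15, 30, 60, 120, 240, 480), function(T)
    simulate_network(p, prot(5, T), y0 = y0))
  for (mode in c("ERK_DT", "NFAT_DT", "AND", "OR", "COOP")) {
    aucs <- vapply(tcs, function(x)
      attr(simulate_reporter(x, gate_spec(mode)), "auc"), numeric(1))
    shape <- classify_shape(rev(aucs))
    want <- if (mode == "COOP") "bell_shaped" else "monotonic_increasing"
    check(sprintf("%s frequency response %s at int_mult %g", mode, want, m),
          shape == want, paste(signif(aucs, 3), collapse = " "))
  }
}
doses <- 10^seq(-11, -6)
for (m in c(0.001, 0.5)) {
  p <- network_params(int_mult = m)
  y0 <- resting_steady_state(p)
  tcs <- lapply(doses, function(d)
    simulate_network(p, prot(960, 960, amp = d), y0 = y0))
  coop <- vapply(tcs, function(x)
    attr(simulate_reporter(x, gate_spec("COOP")), "auc"), numeric(1))
  check(sprintf("COOP dose response non-monotonic at int_mult %g", m),
        which.max(coop) < length(coop) && max(coop) > 1.05 * coop[length(coop)],
        paste(signif(coop, 3), collapse = " "))
  for (mode in c("ERK_DT", "NFAT_DT")) {
    v <- vapply(tcs, function(x)
      attr(simulate_reporter(x, gate_spec(mode)), "auc"), numeric(1))
    check(sprintf("%s dose response monotonic at int_mult %g", mode, m),
          classify_shape(v) == "monotonic_increasing")
  }
}

## -- Fig 3: minimal cascade ---------------------------------------------
mp <- minimal_params()
nc <- minimal_frequency_scan(mp, periods = c(4, 8, 16, 32, 64, 128, 256),
                             width = 4, horizon = 1024)
r2_origin <- function(f, y) {
  b <- sum(f * y) / sum(f * f)
  1 - sum((y - b * f)^2) / sum((y - mean(y))^2)
}
f <- nc$frequency_per_hr
check("non-compensated E1 AUC proportional to frequency (R2 > 0.98)",
      r2_origin(f, nc$E1_auc) > 0.98, sprintf("%.4f", r2_origin(f, nc$E1_auc)))
check("non-compensated E3 AUC proportional to frequency (R2 > 0.98)",
      r2_origin(f, nc$E3_auc) > 0.98, sprintf("%.4f", r2_origin(f, nc$E3_auc)))
check("non-compensated E2 AUC increasing and non-linear (R2 < 0.98)",
      all(diff(rev(nc$E2_auc)) > 0) && r2_origin(f, nc$E2_auc) < 0.98,
      sprintf("R2 %.3f", r2_origin(f, nc$E2_auc)))
cc <- minimal_frequency_scan(mp, periods = c(12, 24, 48, 96, 192, 384),
                             duty_fraction = 1 / 12, compensated = TRUE,
                             horizon = 768)
sprd <- function(v) (max(v) - min(v)) / mean(v)
check("compensated E1 AUC flat (< 15% spread)", sprd(cc$E1_auc) < 0.15,
      sprintf("%.3f", sprd(cc$E1_auc)))
check("compensated E3 AUC flat (< 15% spread)", sprd(cc$E3_auc) < 0.15,
      sprintf("%.3f", sprd(cc$E3_auc)))
check("compensated E2 AUC strictly increasing with frequency",
      all(diff(rev(cc$E2_auc)) > 0))
a24 <- effector_auc(simulate_minimal(mp, pulse_protocol(1, 2, 24, 768)))
a384 <- effector_auc(simulate_minimal(mp, pulse_protocol(1, 32, 384, 768)))
check("efficiency: E2 AUC (w2 T24) > (w32 T384)", a24$E2_auc > a384$E2_auc,
      sprintf("%.1f vs %.1f", a24$E2_auc, a384$E2_auc))
check("specificity: E2/E3 ratio higher at (w2 T24)",
      a24$E2_auc / a24$E3_auc > a384$E2_auc / a384$E3_auc)

cat(sprintf("\n%s\n", if (failures == 0) "all calibration checks passed"
            else sprintf("%d calibration check(s) FAILED", failures)))
quit(status = if (failures == 0) 0 else 1, save = "no")
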