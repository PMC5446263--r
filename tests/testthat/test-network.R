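test_that("network_params validates inputs", {
  p <- network_params(int_mult = 8)
  expect_s3_class(p, "network_params")
  expect_equal(p$int_mult, 8)
  expect_error(network_params(not_a_param = 1), "not_a_param")
  expect_error(network_params(kon = -1), "positive")
})

test_that("resting steady state satisfies its postconditions", {
  p <- network_params()
  y <- cached_rest(1)
  # the returned state really is stationary (t = 30 is between pulses, so
  # the stimulus is zero there)
  expect_lt(max(abs(network_rhs(y, 30, p, std_protocol(60)))), 1e-10)
  # receptor and NFAT conservation
  expect_equal(y[["R_surf"]] + y[["HR"]] + y[["R_int"]], p$Rtot,
               tolerance = 1e-8)
  nfat <- sum(y[c("NFAT_cyt_P", "NFAT_cyt_deP", "NFAT_nuc_deP", "NFAT_nuc_P")])
  expect_equal(nfat, p$nfat_tot, tolerance = 1e-8)
  # without ligand essentially all receptor is on the surface, Ca2+ basal,
  # NFAT overwhelmingly cytoplasmic-phosphorylated, no active ERK
  expect_gt(y[["R_surf"]] / p$Rtot, 0.999)
  expect_equal(y[["Ca_cyt"]], p$ca_basal, tolerance = 1e-4)
  expect_gt(y[["NFAT_cyt_P"]] / p$nfat_tot, 0.9)
  expect_lt(y[["ppERK_nuc"]], 1e-6)
})

test_that("network_rhs enforces its contract and conservation laws", {
  p <- network_params()
  y <- cached_rest(1)
  prot <- std_protocol(60)
  d <- network_rhs(y, 2, p, prot)   # during a pulse
  expect_named(d, c("R_surf", "HR", "R_int", "PLC_active", "Ca_cyt",
                    "ppERK_cyt", "ppERK_nuc", "NFAT_cyt_P", "NFAT_cyt_deP",
                    "NFAT_nuc_deP", "NFAT_nuc_P", "Egr1_nuc"))
  # receptor pools and NFAT pools are conserved exactly by the RHS
  expect_equal(unname(d[["R_surf"]] + d[["HR"]] + d[["R_int"]]), 0)
  expect_equal(unname(sum(d[c("NFAT_cyt_P", "NFAT_cyt_deP",
                              "NFAT_nuc_deP", "NFAT_nuc_P")])), 0)
  # ligand present -> binding flux makes HR grow from rest
  expect_gt(d[["HR"]], 0)
  # scrambled names are reordered, not misassigned
  perm <- sample(length(y))
  expect_equal(network_rhs(y[perm], 2, p, prot), d)
  expect_error(network_rhs(y[-1], 2, p, prot), "12")
  expect_error(network_rhs(setNames(y, c("bogus", names(y)[-1])), 2, p, prot),
               "names")
})

test_that("simulated trajectories conserve totals and stay physical", {
  p <- network_params()
  tc <- simulate_network(p, std_protocol(60, horizon = 120), full = TRUE,
                         y0 = cached_rest(1))
  rtot <- tc$R_surf_state + tc$HR_state + tc$R_int_state
  expect_lt(max(abs(rtot - p$Rtot)) / p$Rtot, 1e-8)
  ntot <- tc$NFAT_cyt_P_state + tc$NFAT_cyt_deP_state +
    tc$NFAT_nuc_deP_state + tc$NFAT_nuc_P_state
  expect_lt(max(abs(ntot - p$nfat_tot)) / p$nfat_tot, 1e-8)
  erk <- tc$ppERK_cyt_state + tc$ppERK_nuc_state
  expect_true(all(erk <= p$erk_tot + 1e-9))
  expect_true(all(as.matrix(tc[, -1]) >= -1e-9))
  expect_true(all(tc$PLC_uM <= p$PLCtot + 1e-9))
  expect_true(all(tc$NFAT_NF <= 1 + 1e-9))
})

test_that("receptor occupancy matches the binding isotherm when trafficking is frozen", {
  # with negligible internalization, constant ligand gives the textbook
  # equilibrium HR = Rtot * L / (L + Kd), Kd = koff / kon
  p <- network_params(int_mult = 1e-9)
  conc <- 1e-8
  tc <- simulate_network(p, pulse_protocol(conc, 240, 240, 240),
                         y0 = resting_steady_state(p))
  kd <- p$koff / p$kon
  expect_equal(tail(tc$HR_uM, 1), p$Rtot * conc / (conc + kd),
               tolerance = 1e-4)
})

test_that("upstream responses are fast, downstream responses slow", {
  tc <- cached_network_tc(1, 60)
  first_pulse <- tc[tc$time_min <= 5, ]
  # PLC and Ca2+ reach half of their first-pulse max within 10 min of onset
  for (ch in c("PLC_uM", "Ca_uM")) {
    peak <- max(first_pulse[[ch]])
    t_half <- min(tc$time_min[tc[[ch]] >= (tc[[ch]][1] + peak) / 2])
    expect_lt(t_half, 10)
  }
  # NFAT nuclear fraction and Egr1 take more than 20 min to reach half of
  # their overall max
  for (ch in c("NFAT_NF", "Egr1_uM")) {
    peak <- max(tc[[ch]])
    t_half <- min(tc$time_min[tc[[ch]] >= (tc[[ch]][1] + peak) / 2])
    expect_gt(t_half, 20)
  }
})

test_that("PLC spikes then relaxes under constant stimulation; NFAT integrates pulses", {
  dc <- cached_dose_tc(1, 1e-7)
  peak <- max(dc$PLC_uM)
  plateau <- mean(dc$PLC_uM[dc$time_min > 800])
  expect_gt(peak / plateau, 1.1)  # overshoot from receptor internalization
  # NFAT under 60-min pulses: troughs stay well above rest (slow shuttling
  # smooths the pulsatile drive)
  tc <- cached_network_tc(1, 60)
  late <- tc[tc$time_min > 480, ]
  expect_gt(min(late$NFAT_NF), 10 * tc$NFAT_NF[1])
})

test_that("solver-tolerance refinement leaves channel AUCs unchanged to 0.1%", {
  p <- network_params()
  prot <- std_protocol(60, horizon = 240)
  y0 <- cached_rest(1)
  tc8 <- simulate_network(p, prot, rtol = 1e-8, y0 = y0)
  tc10 <- simulate_network(p, prot, rtol = 1e-10, atol = 1e-14, y0 = y0)
  for (ch in c("PLC_uM", "Ca_uM", "ppERK_nuc_uM", "NFAT_NF", "Egr1_uM")) {
    a8 <- pracma::trapz(tc8$time_min, tc8[[ch]])
    a10 <- pracma::trapz(tc10$time_min, tc10[[ch]])
    expect_lt(abs(a8 - a10) / a10, 0.001)
  }
})

test_that("a 1% parameter perturbation changes AUCs by only a few percent", {
  p1 <- network_params()
  p2 <- network_params(kplc_on = p1$kplc_on * 1.01, kclear = p1$kclear * 1.01)
  prot <- std_protocol(60, horizon = 240)
  tc1 <- simulate_network(p1, prot, y0 = cached_rest(1))
  tc2 <- simulate_network(p2, prot, y0 = resting_steady_state(p2))
  for (ch in c("PLC_uM", "Ca_uM", "Egr1_uM")) {
    a1 <- pracma::trapz(tc1$time_min, tc1[[ch]])
    a2 <- pracma::trapz(tc2$time_min, tc2[[ch]])
    expect_lt(abs(a1 - a2) / a1, 0.10)
  }
})
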