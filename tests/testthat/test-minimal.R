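test_that("minimal_rhs fixed point and decay contracts hold", {
  p <- minimal_params()
  prot <- pulse_protocol(1, 4, 32, 128)
  # off state with S = 0 is a fixed point (t = 30 is between pulses)
  expect_equal(unname(minimal_rhs(c(0, 0, 0), 30, p, prot)), c(0, 0, 0))
  # fully active state with S = 0 decays in every component
  d <- minimal_rhs(c(1, 1, 1), 30, p, prot)
  expect_lt(d[["E1_star"]], 0)
  # E2/E3 are driven by E1* = 1 here; with E1 = 0 they also decay
  d0 <- minimal_rhs(c(0, 1, 1), 30, p, prot)
  expect_true(all(d0[c("E2_star", "E3_star")] < 0))
  expect_error(minimal_rhs(c(2, 0, 0), 30, p, prot), "bounds")
})

test_that("constant stimulation drives E1* to the scalar steady state", {
  p <- minimal_params()
  prot <- pulse_protocol(1, 100, 100, 400)  # constant
  tc <- simulate_minimal(p, prot)
  e1_end <- tail(tc$E1_star, 1)
  # independent oracle: solve activation flux == inactivation flux with uniroot
  bal <- function(e) {
    p$kact_1 * (p$total_1 - e) / (p$Kact_1 + p$total_1 - e) -
      p$Vinact_1 * e / (p$Kinact_1 + e)
  }
  e_star <- uniroot(bal, c(1e-12, p$total_1 - 1e-12), tol = 1e-12)$root
  expect_equal(e1_end, e_star, tolerance = 1e-6)
})

test_that("simulate_minimal honors trivial protocols and state bounds", {
  p <- minimal_params()
  # zero-amplitude: the drive is OFF when signal equals baseline
  tc0 <- simulate_minimal(p, pulse_protocol(0, 4, 32, 64))
  expect_true(all(abs(as.matrix(tc0[, -1])) < 1e-12))
  # trajectories stay in [0, total]
  tc <- simulate_minimal(p, pulse_protocol(1, 4, 8, 512))
  expect_true(all(as.matrix(tc[, -1]) >= -1e-9))
  expect_true(all(tc$E1_star <= p$total_1 + 1e-9))
  expect_true(all(tc$E2_star <= p$total_2 + 1e-9))
  expect_true(all(tc$E3_star <= p$total_3 + 1e-9))
  # grid is uniform with step <= 0.1 and covers the horizon
  expect_lte(max(diff(tc$time_min)), 0.1 + 1e-12)
  expect_equal(range(tc$time_min), c(0, 512))
})

test_that("fast/slow separation: E1/E3 recover quickly, E2 slowly", {
  p <- minimal_params()
  tau <- minimal_time_constants(p)
  expect_gte(tau[["E2"]], 10 * max(tau[["E1"]], tau[["E3"]]))
  expect_error(minimal_params(Vinact_2 = 5), "10-fold")
  # behavioral check: between 32-min pulses E1*/E3* reset to ~0 (the 28-min
  # gap is ~50 of their relaxation times) while E2* (~2 relaxation times)
  # retains a substantial fraction and towers over the fast effectors
  tc <- simulate_minimal(p, pulse_protocol(1, 4, 32, 512))
  pre2 <- tc[tc$time_min > 28 & tc$time_min < 32, ]
  expect_lt(max(pre2$E1_star), 1e-4)
  expect_lt(max(pre2$E3_star), 1e-4)
  expect_gt(min(pre2$E2_star), 0.01 * max(tc$E2_star))
  expect_gt(min(pre2$E2_star), 100 * max(pre2$E1_star))
})

test_that("effector_auc matches closed forms and a refinement oracle", {
  # constant trace c over T -> c*T
  fake <- tibble::tibble(time_min = seq(0, 50, 0.1),
                         E1_star = 0.3, E2_star = 0, E3_star = 1)
  a <- effector_auc(fake)
  expect_equal(a$E1_auc, 0.3 * 50, tolerance = 1e-9)
  expect_equal(a$E2_auc, 0)
  expect_equal(a$E3_auc, 50, tolerance = 1e-9)
  expect_error(effector_auc(fake, horizon = 60), "exceeds")
  # refinement oracle: 10x finer grid changes AUC by < 0.5%
  p <- minimal_params()
  prot <- pulse_protocol(1, 4, 32, 256)
  coarse <- effector_auc(simulate_minimal(p, prot, dt = 0.1))
  fine <- effector_auc(simulate_minimal(p, prot, dt = 0.01))
  for (ch in names(coarse)) {
    expect_lt(abs(coarse[[ch]] - fine[[ch]]) / fine[[ch]], 0.005)
  }
})

test_that("solver-tolerance refinement changes AUCs by < 0.1%", {
  p <- minimal_params()
  prot <- pulse_protocol(1, 4, 64, 512)
  a8 <- effector_auc(simulate_minimal(p, prot, rtol = 1e-8))
  a10 <- effector_auc(simulate_minimal(p, prot, rtol = 1e-10))
  for (ch in names(a8)) {
    expect_lt(abs(a8[[ch]] - a10[[ch]]) / a10[[ch]], 0.001)
  }
})

test_that("non-compensated scan: E1/E3 AUC proportional to frequency, E2 non-linear", {
  nc <- cached_minimal_noncomp()
  f <- nc$frequency_per_hr
  expect_gt(r2_origin(f, nc$E1_auc), 0.98)
  expect_gt(r2_origin(f, nc$E3_auc), 0.98)
  # E2: increasing with frequency but far from proportional
  ord <- order(f)
  expect_true(all(diff(nc$E2_auc[ord]) > 0))
  expect_lt(r2_origin(f, nc$E2_auc), 0.98)
})

test_that("compensated scan: flat E1/E3, strictly increasing E2", {
  cc <- cached_minimal_comp()
  expect_equal(cc$input_integral, rep(cc$input_integral[1], nrow(cc)))
  sprd <- function(v) (max(v) - min(v)) / mean(v)
  expect_lt(sprd(cc$E1_auc), 0.15)
  expect_lt(sprd(cc$E3_auc), 0.15)
  ord <- order(cc$frequency_per_hr)
  expect_true(all(diff(cc$E2_auc[ord]) > 0))
})

test_that("efficiency and specificity favor frequent short pulses", {
  a24 <- effector_auc(simulate_minimal(minimal_params(),
                                       pulse_protocol(1, 2, 24, 768)))
  a384 <- effector_auc(simulate_minimal(minimal_params(),
                                        pulse_protocol(1, 32, 384, 768)))
  expect_gt(a24$E2_auc, a384$E2_auc)
  expect_gt(a24$E2_auc / a24$E3_auc, a384$E2_auc / a384$E3_auc)
})
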