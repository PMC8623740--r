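final_sp <- function() {
  structural_params(V1 = 2.6, V2 = 1.9, CL = 0.16, Q = 1.8,
                    R0C = 3.3, KSSC = 15.4, kintC = 0.17,
                    R0P = 0.46, KSSP = 0.49, kintP = 0.0079, kout = 20)
}

test_that("QSS unbound concentration matches an independent root finder", {
  # no target / no drug limits are exact
  expect_identical(qss_unbound(10, 0, 1), 10)
  expect_identical(qss_unbound(0, 5, 15.4), 0)
  expect_equal(qss_unbound(50, 100, 15.4), qss_bisect(50, 100, 15.4),
               tolerance = 1e-10)
  expect_equal(qss_unbound(50, 100, 15.4), 10.19, tolerance = 1e-3)
  set.seed(7)
  for (i in 1:50) {
    ct <- stats::runif(1, 0, 1000)
    rt <- stats::runif(1, 0, 500)
    kss <- stats::runif(1, 0.01, 50)
    C <- qss_unbound(ct, rt, kss)
    expect_gte(C, 0)
    expect_lte(C, ct)
    expect_equal(C, qss_bisect(ct, rt, kss), tolerance = 1e-10)
    # QSS identity: complex equals RT * C / (KSS + C)
    expect_equal(ct - C, rt * C / (kss + C), tolerance = 1e-8 * max(1, ct))
  }
  expect_error(qss_unbound(-1, 0, 1), "non-negative")
})

test_that("ODE right-hand side: equilibrium, conservation, finiteness", {
  p <- final_sp()
  # baseline is an exact equilibrium
  expect_equal(tmdd_rhs(c(0, p$R0C, 0, p$R0P), p), rep(0, 4))
  # with TMDD off and CL = 0 the printed transfer form conserves the sum of
  # the two drug concentration states
  lin <- structural_params(V1 = 2.6, V2 = 1.9, CL = 1e-12, Q = 1.8)
  d <- tmdd_rhs(c(40, 0, 10, 0), lin)
  expect_equal(d[1] + d[3], 0, tolerance = 1e-10)
  # full double-TMDD state: matches a direct evaluation of the equations
  st <- c(100, 3.3, 20, 0.46)
  d <- tmdd_rhs(st, p)
  C <- qss_unbound(st[1], st[2], p$KSSC)
  CP <- qss_unbound(st[3], st[4], p$KSSP)
  expect_equal(d[1], -(p$CL / p$V1) * C - (p$Q / p$V1) * C +
                 (p$Q / p$V2) * CP - p$kintC * (st[1] - C))
  expect_equal(d[2], p$R0C * p$kout - p$kout * (st[2] - (st[1] - C)) -
                 p$kintC * (st[1] - C))
  expect_true(all(is.finite(d)))
})

test_that("terminal half-life matches the linear disposition eigenvalues", {
  # base double-TMDD estimates give ~17 days
  s <- terminal_half_life(V1 = 2.8, V2 = 1.9, CL = 0.20, Q = 1.5)
  expect_equal(s$t_half_beta, 17, tolerance = 0.03)
  expect_lte(s$t_half_alpha, s$t_half_beta)
  # one-compartment limit as Q -> 0: the alpha phase carries the
  # elimination (the beta phase is the vanishing peripheral exchange)
  s1 <- terminal_half_life(V1 = 2.8, V2 = 1.9, CL = 0.20, Q = 1e-10)
  expect_equal(s1$t_half_alpha, log(2) * 2.8 / 0.20, tolerance = 1e-4)
  # eigenvalue oracle for the final-model linear parameters
  V1 <- 2.6; V2 <- 1.9; CL <- 0.16; Q <- 1.8
  M <- matrix(c(-(CL / V1 + Q / V1), Q / V1, Q / V2, -Q / V2), 2, 2)
  lam <- sort(eigen(M)$values) # most negative first
  s2 <- terminal_half_life(V1, V2, CL, Q)
  expect_equal(s2$alpha, -lam[1], tolerance = 1e-12)
  expect_equal(s2$beta, -lam[2], tolerance = 1e-12)
  expect_equal(s2$t_half_beta, 19.81, tolerance = 1e-3)
})

test_that("linear mode matches the closed form, scales with dose, bolus limit", {
  lp <- structural_params(V1 = 2.6, V2 = 1.9, CL = 0.16, Q = 1.8)
  reg <- dose_events(7 * c(0, 2, 6), 330)
  tt <- sort(c(seq(0.25, 56, by = 0.5), 7 * c(2, 6)))
  ode <- simulate_profile(lp, reg, tt)$conc_mgL
  cf <- linear_2cpt_conc(tt, reg, 2.6, 1.9, 0.16, 1.8)
  expect_equal(ode, cf, tolerance = 1e-6)
  # and against the independent macro-constant formula
  expect_equal(cf, biexp_conc(tt, reg, 2.6, 1.9, 0.16, 1.8),
               tolerance = 1e-10)
  # doubling the dose doubles every concentration
  ode2 <- simulate_profile(lp, dose_events(7 * c(0, 2, 6), 660), tt)$conc_mgL
  expect_equal(ode2, 2 * ode, tolerance = 1e-8)
  # 330 mg over 2 h: peak just below dose/V1 (elimination and distribution
  # remove a few percent during the infusion)
  pk <- simulate_profile(lp, dose_events(0, 330), 2 / 24)$conc_mgL
  expect_lt(pk, 330 / 2.6)
  expect_equal(pk, 330 / 2.6, tolerance = 0.05)
})

test_that("double-TMDD trajectory agrees with independent stiff integration", {
  skip_if_not_installed("deSolve")
  p <- final_sp()
  reg <- dose_events(7 * c(0, 2, 6, 14, 22), 330)
  tt <- seq(1, 210, by = 3.5)
  prof <- simulate_profile(p, reg, tt, rtol = 1e-10, atol = 1e-12)
  orc <- oracle_profile(p, reg, tt)
  for (j in 1:4) {
    col <- c("CT_nM", "RTC_nM", "CPT_nM", "RTP_nM")[j]
    expect_equal(prof[[col]], orc[, j], tolerance = 1e-6)
  }
})

test_that("simulated profiles satisfy the QSS identities and monotonicity", {
  p <- final_sp()
  reg <- dose_events(7 * c(0, 2, 6, 14, 22), 330)
  tt <- seq(0, 210, by = 0.5)
  prof <- simulate_profile(p, reg, tt)
  # complex = RT * C / (KSS + C) in both compartments
  cplxC <- prof$CT_nM - prof$C_nM
  expC <- prof$RTC_nM * prof$C_nM / (p$KSSC + prof$C_nM)
  expect_equal(cplxC, expC, tolerance = 1e-8)
  cplxP <- prof$CPT_nM - prof$CP_nM
  expP <- prof$RTP_nM * prof$CP_nM / (p$KSSP + prof$CP_nM)
  expect_equal(cplxP, expP, tolerance = 1e-8)
  # occupancy ratio closed form KSS/(KSS + C)
  expect_equal(prof$ratio_C, p$KSSC / (p$KSSC + prof$C_nM), tolerance = 1e-8)
  # all outputs non-negative, bounded unbound fractions
  expect_true(all(prof$C_nM >= 0 & prof$C_nM <= prof$CT_nM + 1e-12))
  # baseline equilibrium without dosing: drift below 1e-9 nM over 200 days
  prof0 <- simulate_profile(p, dose_events(0, 0), seq(0, 200, by = 10))
  expect_lt(max(abs(prof0$RTC_nM - p$R0C)), 1e-9)
  expect_lt(max(abs(prof0$CT_nM)), 1e-9)
  # monotonicity: higher dose never lowers C; higher R0C never raises C
  hi <- simulate_profile(p, dose_events(7 * c(0, 2, 6, 14, 22), 400), tt)
  expect_true(all(hi$C_nM >= prof$C_nM - 1e-6))
  p2 <- structural_params(V1 = p$V1, V2 = p$V2, CL = p$CL, Q = p$Q,
                          R0C = 6.6, KSSC = p$KSSC, kintC = p$kintC,
                          R0P = p$R0P, KSSP = p$KSSP, kintP = p$kintP,
                          kout = p$kout)
  lo <- simulate_profile(p2, reg, tt)
  expect_true(all(lo$C_nM <= prof$C_nM + 1e-6))
  # total target accumulates well above baseline under the regimen
  expect_gt(max(prof$RTC_nM) / p$R0C, 1)
})

test_that("solver reports the failure time when its step budget is exhausted", {
  p <- final_sp()
  expect_error(
    dtmdd:::tmdd_solve(dtmdd:::par_vector(p),
                       cbind(0, 2 / 24, 330 / (2 / 24)), c(0, 50),
                       149000, dtmdd:::solver_control(1e-8, 1e-10,
                                                      maxstep = 20)),
    "failed at t")
})

test_that("dose events validate their preconditions", {
  expect_error(dose_events(c(14, 0), 330), "sorted")
  expect_error(dose_events(0, -5), ">= 0")
  expect_error(dose_events(0, 330, 0), "> 0")
  r <- dose_events(c(0, 14), 330, 2 / 24)
  expect_equal(r$rate, rep(330 / (2 / 24), 2))
})
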