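test_that("with all variances zero the marginal -2LL is the closed-form residual sum", {
  pop0 <- population_params(
    theta = c(V1 = 3.0, CL = 0.29, V2 = 2.2, Q = 0.29, kout = 20),
    omega = c(V1 = 0, CL = 0, V2 = 0),
    sigma = c(add = 1.8, prop = 0.20))
  gen <- infliximab_population("base_2cpt")
  ds <- generate_dataset(study_design("as_rich"), gen, 4, seed = 51)
  v <- marginal_neg2ll(ds, pop0, "two_compartment")
  expect_equal(attr(v, "mcse"), 0)
  # oracle: Gaussian residual sum over non-censored observations with
  # closed-form linear predictions
  dat <- ds$data
  tot <- 0
  for (id in unique(dat$ID)) {
    d <- dat[dat$ID == id, ]
    dose <- d[d$EVID == 1, ]
    obs <- d[d$EVID == 0 & d$CENS == 0, ]
    reg <- data.frame(time = dose$TIME, duration = dose$AMT / dose$RATE,
                      rate = dose$RATE)
    f <- biexp_conc(obs$TIME, reg, 3.0, 2.2, 0.29, 0.29)
    sdv <- 1.8 + 0.20 * pmax(f, 0)
    tot <- tot - 2 * sum(stats::dnorm(obs$DV, f, sdv, log = TRUE))
  }
  expect_equal(as.numeric(v), tot, tolerance = 1e-8)
  # additivity: duplicating every subject doubles -2LL exactly
  ds2 <- bind_datasets(ds, generate_dataset(study_design("as_rich"), gen, 4,
                                            seed = 51, id_offset = 100L))
  v2 <- marginal_neg2ll(ds2, pop0, "two_compartment")
  expect_equal(as.numeric(v2), 2 * as.numeric(v), tolerance = 1e-8)
})

test_that("importance sampling agrees with brute-force Monte-Carlo integration", {
  pop <- infliximab_population("base_2cpt")
  ds <- generate_dataset(study_design("ibd_sparse"), pop, 3, seed = 52)
  is_val <- marginal_neg2ll(ds, pop, "two_compartment", method = "is",
                            n_mc = 3000, seed = 53)
  expect_lt(attr(is_val, "mcse"), 1)
  mc_val <- mc_neg2ll_linear(ds, pop, n_draws = 40000, seed = 54)
  tol <- 3 * (attr(is_val, "mcse") + attr(mc_val, "mcse"))
  expect_lt(abs(as.numeric(is_val) - as.numeric(mc_val)), max(tol, 0.1))
  # Laplace is close to the exact integral on this fixture
  lap <- marginal_neg2ll(ds, pop, "two_compartment", method = "laplace")
  expect_lt(abs(as.numeric(lap) - as.numeric(mc_val)), 2)
})

test_that("low-noise degenerate data are recovered by the linear fit", {
  # omega = 0, small residual noise: self-consistency of the estimator
  truth <- population_params(
    theta = c(V1 = 3.0, CL = 0.29, V2 = 2.2, Q = 0.9, kout = 20),
    omega = c(V1 = 0, CL = 0, V2 = 0),
    sigma = c(add = 0.2, prop = 0.02))
  ds <- generate_dataset(study_design("as_rich"), truth, 16, seed = 55,
                         missingness = 0)
  fit <- fit_tmdd(ds, "two_compartment", control = fit_control(maxit = 80))
  th <- fit$estimates$theta
  for (nm in c("V1", "CL", "V2"))
    expect_equal(th[[nm]], truth$theta[[nm]], tolerance = 0.05)
  # intercompartmental clearance is by far the least determined linear
  # parameter (an independent pooled weighted-least-squares fit of this
  # dataset lands at the same displaced value)
  expect_equal(th[["Q"]], truth$theta[["Q"]], tolerance = 0.2)
  # AIC bookkeeping is exact
  expect_equal(fit$aic, fit$neg2ll + 2 * fit$n_par, tolerance = 1e-9)
})

test_that("likelihood ratio test matches the chi-squared reference values", {
  # published covariate tests: LRT 15.29 -> 9.2e-5; 5.71 -> 0.017 (df 1)
  expect_equal(signif(lrt_pvalue(10765.34, 10750.05, 1), 2), 9.2e-5)
  expect_equal(signif(lrt_pvalue(5.71, 0, 1), 2), 0.017)
  expect_equal(lrt_pvalue(10, 10, 1), 1)
  expect_equal(lrt_pvalue(9.9, 10, 1), 1) # negative difference clamps to 0
  # independent chi-squared(1) tail via the normal distribution
  for (d in c(0.3, 1.7, 5.71, 15.29, 30)) {
    expect_equal(lrt_pvalue(d, 0, 1), 2 * stats::pnorm(-sqrt(d)),
                 tolerance = 1e-10)
  }
  expect_error(lrt_pvalue(5, 1, 0), "df")
})

test_that("kout grid selection honours its contract on a single-point grid", {
  pop <- infliximab_population("base_2cpt")
  ds <- generate_dataset(study_design("ibd_sparse"), pop, 6, seed = 56)
  sel <- kout_grid_select(ds, "two_compartment", grid = 20,
                          control = fit_control(maxit = 30))
  expect_equal(sel$best, 20)
  expect_equal(nrow(sel$table), 1)
  expect_true(all(c("kout", "neg2ll", "aic", "converged") %in%
                    names(sel$table)))
  expect_equal(sel$table$aic, sel$table$neg2ll + 2 * sel$fits[[1]]$n_par,
               tolerance = 1e-9)
})

test_that("estimator is approximately unbiased for the disposition parameters", {
  truth <- infliximab_population("base_2cpt")
  est <- matrix(NA_real_, 3, 3, dimnames = list(NULL, c("V1", "CL", "V2")))
  for (r in 1:3) {
    ds <- generate_dataset(study_design("as_rich"), truth, 30,
                           seed = 600 + r)
    fit <- fit_tmdd(ds, "two_compartment", control = fit_control(maxit = 60))
    est[r, ] <- unlist(fit$estimates$theta[c("V1", "CL", "V2")])
  }
  bias <- colMeans(est) / unlist(truth$theta[c("V1", "CL", "V2")]) - 1
  # 3 replicates of 30 subjects: the Monte-Carlo error of the mean estimate
  # is a few percent, so this is a coarse consistency bound
  expect_lt(max(abs(bias)), 0.12)
})

test_that("sparse designs inflate the uncertainty of peripheral TMDD parameters", {
  pop <- infliximab_population("final")
  init <- population_params(theta = pop$theta, bw_ref = pop$bw_ref,
                            omega = pop$omega, sigma = pop$sigma)
  rich <- bind_datasets(
    generate_dataset(study_design("as_rich"), pop, 5, seed = 61),
    generate_dataset(study_design("ibd_rich"), pop, 12, seed = 62,
                     id_offset = 100L))
  sparse <- bind_datasets(
    generate_dataset(study_design("as_rich"), pop, 5, seed = 61),
    generate_dataset(study_design("ibd_sparse"), pop, 12, seed = 63,
                     id_offset = 100L))
  ctrl <- fit_control(maxit = 40)
  f_rich <- fit_tmdd(rich, "peripheral_tmdd", init = init, control = ctrl,
                     rse = TRUE)
  f_sparse <- fit_tmdd(sparse, "peripheral_tmdd", init = init,
                       control = ctrl, rse = TRUE)
  for (nm in c("lkintP", "lR0P")) {
    expect_gt(f_sparse$rse[[nm]], f_rich$rse[[nm]])
  }
})
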