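test_that("covariate model reproduces the reference typical values", {
  pop <- infliximab_population("final")
  # reference category: parameters unchanged
  ref <- typical_params(pop, subject_covariates(66, "F", "CD"))
  expect_equal(ref$V1, 2.6)
  expect_equal(ref$CL, 0.16)
  expect_equal(ref$R0C, 3.3)
  # male clearance 0.16 * exp(0.36) ~ 0.23 L/day
  male <- typical_params(pop, subject_covariates(66, "M", "CD"))
  expect_equal(signif(male$CL, 2), 0.23)
  # ulcerative colitis baseline target 3.3 * exp(0.57) ~ 5.8 nM
  uc <- typical_params(pop, subject_covariates(66, "F", "UC"))
  expect_equal(signif(uc$R0C, 2), 5.8)
  # body weight as a centred power function
  heavy <- typical_params(pop, subject_covariates(90, "F", "CD"))
  expect_equal(heavy$V1, 2.6 * (90 / 66)^0.33, tolerance = 1e-12)
  # multiplicative effects are order-independent
  pop2 <- pop
  pop2$covariates <- pop$covariates[rev(seq_len(nrow(pop$covariates))), ]
  m1 <- typical_params(pop, subject_covariates(80, "M", "UC"))
  m2 <- typical_params(pop2, subject_covariates(80, "M", "UC"))
  expect_equal(unclass(m1), unclass(m2))
  # AS subjects are the linear reference: TMDD off, linear parameters shared
  as_sub <- typical_params(pop, subject_covariates(66, "F", "AS"))
  expect_false(as_sub$tmdd_central)
  expect_false(as_sub$tmdd_peripheral)
  expect_identical(as_sub$R0C, 0)
  expect_equal(as_sub$CL, ref$CL)
})

test_that("exponential IIV acts multiplicatively on the five parameters", {
  pop <- infliximab_population("final")
  tp <- typical_params(pop, subject_covariates(66, "F", "CD"))
  expect_equal(unclass(individual_params(tp, rep(0, 5))), unclass(tp))
  dbl <- individual_params(tp, c(CL = log(2)))
  expect_equal(dbl$CL, 2 * tp$CL)
  expect_equal(dbl$V1, tp$V1)
  # etas on disabled arms are ignored
  as_tp <- typical_params(pop, subject_covariates(66, "F", "AS"))
  as_ind <- individual_params(as_tp, c(R0C = 3, V1 = 0.1))
  expect_identical(as_ind$R0C, 0)
  expect_equal(as_ind$V1, as_tp$V1 * exp(0.1))
})

test_that("simulated individual parameters are log-normal with the stated omega", {
  pop <- infliximab_population("final")
  tp <- typical_params(pop, subject_covariates(66, "F", "CD"))
  n <- 4000
  set.seed(42)
  cl <- vapply(seq_len(n), function(i) {
    individual_params(tp, c(CL = stats::rnorm(1, 0, pop$omega[["CL"]])))$CL
  }, 1)
  lcl <- log(cl)
  # sample SD of log CL within 3 Monte-Carlo SEs of omega = 0.35
  se <- pop$omega[["CL"]] / sqrt(2 * (n - 1))
  expect_lt(abs(stats::sd(lcl) - 0.35), 3 * se)
  expect_equal(mean(lcl), log(tp$CL), tolerance = 3 * 0.35 / sqrt(n))
  expect_gt(stats::shapiro.test(lcl[1:3000])$p.value, 0.01)
})

test_that("combined residual error model and its SD", {
  expect_equal(residual_sd(0, 1.8, 0.2), 1.8)
  expect_equal(residual_sd(9, 1.8, 0.2), 3.6)
  expect_equal(residual_error(7, 1.8, 0.2, 0), 7)
  expect_equal(residual_error(9, 1.8, 0.2, 1), 12.6)
  # combined2 alternative
  expect_equal(residual_sd(9, 1.8, 0.2, form = "combined2"),
               sqrt(1.8^2 + 1.8^2))
  expect_error(residual_sd(-1, 1, 0.1), ">= 0")
})

test_that("degenerate population (omega = 0, eps = 0) reduces to the typical subject", {
  pop <- infliximab_population("final")
  pop0 <- population_params(theta = pop$theta, covariates = pop$covariates,
                            bw_ref = pop$bw_ref,
                            omega = c(V1 = 0, CL = 0, V2 = 0, R0C = 0,
                                      R0P = 0),
                            sigma = c(add = 0, prop = 0))
  ds <- generate_dataset(study_design("ibd_sparse"), pop0, 4, seed = 5,
                         missingness = 0)
  obs <- ds$data[ds$data$EVID == 0 & ds$data$CENS == 0, ]
  for (id in unique(obs$ID)) {
    o <- obs[obs$ID == id, ]
    cov <- subject_covariates(o$BW[1], if (o$SEX[1] == 1) "M" else "F",
                              c("CD", "UC", "AS")[o$DIS[1] + 1])
    tp <- typical_params(pop0, cov)
    amt <- dose_from_weight(cov$BW, 5)
    prof <- simulate_profile(tp, dose_events(7 * c(0, 2, 6, 14, 22), amt),
                             o$TIME)
    expect_equal(o$DV, prof$conc_mgL, tolerance = 1e-8)
  }
})
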