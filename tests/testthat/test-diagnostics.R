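noise_free_pop <- function() {
  pop <- infliximab_population("final")
  population_params(theta = pop$theta, covariates = pop$covariates,
                    bw_ref = pop$bw_ref,
                    omega = c(V1 = 0, CL = 0, V2 = 0, R0C = 0, R0P = 0),
                    sigma = c(add = 0, prop = 0))
}

test_that("weighted residuals are exact in degenerate cases", {
  pop0 <- noise_free_pop()
  ds <- generate_dataset(study_design("ibd_sparse"), pop0, 4, seed = 90,
                         missingness = 0)
  # evaluate against a non-degenerate error model so the SDs are finite
  pop_eval <- pop0
  pop_eval$sigma <- c(add = 1.8, prop = 0.20)
  gof <- gof_table(ds, pop_eval, n_reps = 50, seed = 1)
  expect_equal(gof$IWRES, rep(0, nrow(gof)), tolerance = 1e-6)
  expect_equal(gof$IPRED, gof$DV, tolerance = 1e-6)
  # shifting each observation by one residual SD gives IWRES = 1
  ds2 <- ds
  obs_rows <- ds2$data$EVID == 0 & ds2$data$CENS == 0
  ds2$data$DV[obs_rows] <- ds2$data$DV[obs_rows] +
    residual_sd(ds2$data$DV[obs_rows], 1.8, 0.20)
  gof2 <- gof_table(ds2, pop_eval, n_reps = 50, seed = 1)
  # with omega = 0 the EB mode is fixed, so IPRED is unchanged
  expect_equal(gof2$IWRES, rep(1, nrow(gof2)), tolerance = 1e-6)
})

test_that("IWRES are centred under a correctly specified model", {
  pop <- infliximab_population("final")
  ds <- bind_datasets(
    generate_dataset(study_design("as_rich"), pop, 10, seed = 91),
    generate_dataset(study_design("ibd_rich"), pop, 60, seed = 92,
                     id_offset = 100L))
  gof <- gof_table(ds, pop, n_reps = 200, seed = 2)
  expect_gt(nrow(gof), 1500)
  expect_lt(abs(mean(gof$IWRES)), 0.05)
  expect_true(all(is.finite(gof$WRES)))
})

test_that("VPC bands behave per contract and calibrate on self-simulated data", {
  pop <- infliximab_population("final")
  ds <- generate_dataset(study_design("ibd_sparse"), pop, 40, seed = 93)
  # n_reps = 1: bands collapse onto the single replicate
  expect_warning(v1 <- vpc(ds, pop, n_reps = 1, seed = 3), "unreliable")
  expect_equal(v1$sim_lo, v1$sim_hi)
  expect_equal(v1$sim_lo, v1$sim_med)
  # single-percentile configuration
  v50 <- vpc(ds, pop, n_reps = 120, percentiles = 50, seed = 3)
  expect_true(all(v50$pctl == 50))
  # self-VPC: observed percentiles fall inside the 90% bands in most bins
  v <- vpc(ds, pop, n_reps = 250, seed = 4)
  inside <- mean(v$observed >= v$sim_lo & v$observed <= v$sim_hi)
  expect_gte(inside, 0.8)
  # the median band covers the true median profile (computed from a large
  # independent simulation of the same design) in >= 90% of bins
  big <- generate_dataset(study_design("ibd_sparse"), pop, 800, seed = 95,
                          missingness = 0)
  obs <- big$data[big$data$EVID == 0, ]
  med <- v[v$pctl == 50, ]
  truth_med <- vapply(med$bin_time, function(b)
    stats::median(obs$DV[abs(obs$TIME - b) < 1e-6]), 1)
  cover <- mean(truth_med >= med$sim_lo & truth_med <= med$sim_hi)
  expect_gte(cover, 0.9)
  # small bins are flagged
  expect_true(all(v$low_n == (v$n_obs < 5)))
})

test_that("NPDE is standard normal under the generating model and detects misfit", {
  pop <- infliximab_population("final")
  # self-consistency on a low-censoring configuration (below-limit records
  # are excluded from NPDE, so frequent censoring leaves a selection bias)
  lown <- population_params(theta = pop$theta, covariates = pop$covariates,
                            bw_ref = 66, omega = pop$omega,
                            sigma = c(add = 0.3, prop = 0.15))
  ds <- generate_dataset(study_design("ibd_rich"), lown, 40, seed = 97)
  res <- npde(ds, lown, n_reps = 600, seed = 5)
  expect_gte(res$summary$n, 800)
  expect_lt(abs(res$summary$mean), 0.05)
  expect_gt(res$summary$var, 0.9)
  expect_lt(res$summary$var, 1.1)
  expect_gt(res$summary$ks_pvalue, 0.01)
  # determinism
  res2 <- npde(ds, lown, n_reps = 600, seed = 5)
  expect_identical(res$table$npde, res2$table$npde)
  # halving clearance is flagged as bias (trough-rich sparse design)
  dss <- generate_dataset(study_design("ibd_sparse"), pop, 60, seed = 98)
  mis <- pop
  mis$theta[["CL"]] <- pop$theta[["CL"]] / 2
  res_mis <- npde(dss, mis, n_reps = 400, seed = 6)
  expect_gt(abs(res_mis$summary$mean), 0.2)
})
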