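# simulate latent prediction matrix (n_obs x n_reps) for one subject under
# the population model; caller controls the RNG state
sim_pred_matrix <- function(sub, pop, spec, ctrl, n_reps) {
  active <- active_etas(spec, pop, sub)
  k <- length(active)
  sspec <- spec
  sspec$active <- active
  pr <- make_predictor(sub, pop, sspec, ctrl)
  if (k == 0L)
    return(matrix(drop(pr(NULL)), length(sub$times), n_reps))
  etas <- matrix(stats::rnorm(k * n_reps, 0, pop$omega[active]), k, n_reps)
  pr(etas)
}

#' Goodness-of-fit table
#'
#' Per-observation population and individual predictions and weighted
#' residuals. Individual predictions (`IPRED`) come from the empirical-Bayes
#' conditional modes; `IWRES = (DV - IPRED) / sd(IPRED)` with the residual
#' error SD of the fit. Population predictions (`PRED`) and weighted
#' residuals (`WRES`) use the simulation-based mean and covariance of each
#' subject's observation vector (`n_reps` replicates of the random effects
#' plus the analytic residual variance), `WRES` being the decorrelated
#' residual through the lower-triangular covariance square root.
#'
#' @param dataset A `study_dataset`.
#' @param fit A [fit_tmdd()] result, or a [population_params()] object to
#'   diagnose the dataset against known parameters.
#' @param n_reps Simulation replicates for the population moments.
#' @param seed RNG seed.
#' @return A data frame with `ID`, `TIME`, `DV`, `PRED`, `IPRED`, `WRES`,
#'   `IWRES`.
#' @export
gof_table <- function(dataset, fit, n_reps = 1000, seed = 1) {
  pop <- if (inherits(fit, "fit_result")) fit$estimates else fit
  ctrl <- if (inherits(fit, "fit_result")) fit$control else fit_control()
  spec <- variant_spec(if (inherits(fit, "fit_result")) fit$variant
                       else variant_from_pop(pop))
  subs <- prepare_subjects(dataset)
  out <- vector("list", length(subs))
  with_seed(seed, {
    for (i in seq_along(subs)) {
      sub <- subs[[i]]
      sspec <- spec
      sspec$active <- active_etas(spec, pop, sub)
      lap <- subject_laplace(sub, pop, sspec, ctrl)
      ipred <- lap$f
      iwres <- (sub$dv - ipred) /
        residual_sd(pmax(ipred, 0), pop$sigma[["add"]],
                    pop$sigma[["prop"]], pop$error_form)
      fmat <- sim_pred_matrix(sub, pop, spec, ctrl, n_reps)
      pred <- rowMeans(fmat)
      vres <- rowMeans(residual_sd(pmax(fmat, 0), pop$sigma[["add"]],
                                   pop$sigma[["prop"]],
                                   pop$error_form)^2)
      covY <- stats::cov(t(fmat)) + diag(vres, length(pred))
      L <- t(chol_psd(covY))
      wres <- drop(forwardsolve(L, sub$dv - pred))
      out[[i]] <- data.frame(ID = sub$id, TIME = sub$times, DV = sub$dv,
                             PRED = pred, IPRED = ipred,
                             WRES = wres, IWRES = iwres)
    }
  })
  do.call(rbind, out)
}

chol_psd <- function(S) {
  tryCatch(chol(S), error = function(e) {
    warning("singular simulated covariance; ridge-regularised",
            call. = FALSE)
    chol(S + diag(1e-6 * mean(diag(S)), nrow(S)))
  })
}

#' Visual predictive check table
#'
#' Simulates `n_reps` replicates of the dataset on its own design (new random
#' effects and residual errors) and compares observed percentiles with the
#' simulation-based percentile bands per nominal design time bin. Designs are
#' scheduled, so observations are binned by their nominal time; bins with
#' fewer than 5 observations are flagged. Rendering is left to the caller;
#' the return value is the binned table.
#'
#' @param dataset A `study_dataset`.
#' @param fit A [fit_tmdd()] result or a [population_params()] object.
#' @param n_reps Number of simulated replicates (>= 100 for meaningful
#'   bands; with `n_reps = 1` the bands collapse onto that replicate).
#' @param percentiles Percentiles to track, in (0, 100).
#' @param seed RNG seed.
#' @param band Coverage of the simulated prediction band.
#' @return A data frame with one row per (bin, percentile): `bin_time`,
#'   `n_obs`, `pctl`, `observed`, `sim_lo`, `sim_med`, `sim_hi`, `low_n`.
#' @export
vpc <- function(dataset, fit, n_reps = 1000, percentiles = c(10, 50, 90),
                seed = 1, band = 0.90) {
  stopifnot(n_reps >= 1)
  if (n_reps < 100)
    warning("n_reps < 100 gives unreliable prediction bands", call. = FALSE)
  pop <- if (inherits(fit, "fit_result")) fit$estimates else fit
  ctrl <- if (inherits(fit, "fit_result")) fit$control else fit_control()
  spec <- variant_spec(if (inherits(fit, "fit_result")) fit$variant
                       else variant_from_pop(pop))
  subs <- prepare_subjects(dataset)
  probs <- percentiles / 100
  times_all <- unlist(lapply(subs, `[[`, "times"))
  dv_all <- unlist(lapply(subs, `[[`, "dv"))
  bin <- round(times_all, 6)
  ubin <- sort(unique(bin))
  nb <- length(ubin)
  obs_pct <- t(vapply(ubin, function(b)
    stats::quantile(dv_all[bin == b], probs, names = FALSE),
    numeric(length(probs))))
  n_obs <- vapply(ubin, function(b) sum(bin == b), 1L)

  simq <- array(NA_real_, c(nb, length(probs), n_reps))
  with_seed(seed, {
    sim_dv <- matrix(NA_real_, length(dv_all), n_reps)
    pos <- 0L
    for (sub in subs) {
      ni <- length(sub$times)
      fmat <- sim_pred_matrix(sub, pop, spec, ctrl, n_reps)
      eps <- matrix(stats::rnorm(ni * n_reps), ni, n_reps)
      sdm <- residual_sd(pmax(fmat, 0), pop$sigma[["add"]],
                         pop$sigma[["prop"]], pop$error_form)
      sim_dv[pos + seq_len(ni), ] <- pmax(fmat + sdm * eps, 0)
      pos <- pos + ni
    }
    for (r in seq_len(n_reps)) {
      for (b in seq_len(nb)) {
        simq[b, , r] <- stats::quantile(sim_dv[bin == ubin[b], r], probs,
                                        names = FALSE)
      }
    }
  })
  alpha <- (1 - band) / 2
  out <- do.call(rbind, lapply(seq_along(probs), function(j) {
    data.frame(bin_time = ubin, n_obs = n_obs, pctl = percentiles[j],
               observed = obs_pct[, j],
               sim_lo = apply(simq[, j, , drop = FALSE], 1, stats::quantile,
                              alpha),
               sim_med = apply(simq[, j, , drop = FALSE], 1, stats::median),
               sim_hi = apply(simq[, j, , drop = FALSE], 1, stats::quantile,
                              1 - alpha),
               low_n = n_obs < 5L)
  }))
  rownames(out) <- NULL
  out
}

#' Normalised prediction distribution errors
#'
#' For each subject, `n_reps` replicates of the observation vector are
#' simulated under the model; observed and simulated vectors are decorrelated
#' with the lower-triangular square root of the simulated covariance
#' (observations ordered by time), prediction distribution errors are the
#' rank-based probabilities of the decorrelated observations within the
#' decorrelated replicates (ties jittered, probabilities clipped to
#' `(1/(2 n_reps), 1 - 1/(2 n_reps))`), and NPDE is their standard-normal
#' quantile. Under a correct model the NPDE are standard normal for
#' observations whose below-quantitation-limit probability is negligible;
#' records below the limit are excluded, which leaves a small positive
#' selection bias when censoring is frequent.
#'
#' @param dataset A `study_dataset`.
#' @param fit A [fit_tmdd()] result or a [population_params()] object.
#' @param n_reps Number of replicates (>= 500 recommended for the global
#'   test).
#' @param seed RNG seed.
#' @return A list with `table` (per-observation `ID`, `TIME`, `DV`, `npde`)
#'   and `summary` (`mean`, `var`, `t_pvalue` for mean 0, `ks_pvalue`
#'   against N(0,1), `n`).
#' @export
npde <- function(dataset, fit, n_reps = 1000, seed = 1) {
  pop <- if (inherits(fit, "fit_result")) fit$estimates else fit
  ctrl <- if (inherits(fit, "fit_result")) fit$control else fit_control()
  spec <- variant_spec(if (inherits(fit, "fit_result")) fit$variant
                       else variant_from_pop(pop))
  subs <- prepare_subjects(dataset)
  out <- vector("list", length(subs))
  with_seed(seed, {
    for (i in seq_along(subs)) {
      sub <- subs[[i]]
      ni <- length(sub$times)
      fmat <- sim_pred_matrix(sub, pop, spec, ctrl, n_reps)
      eps <- matrix(stats::rnorm(ni * n_reps), ni, n_reps)
      sdm <- residual_sd(pmax(fmat, 0), pop$sigma[["add"]],
                         pop$sigma[["prop"]], pop$error_form)
      # truncation at zero mirrors the observation process
      yrep <- pmax(fmat + sdm * eps, 0)
      m <- rowMeans(yrep)
      S <- stats::cov(t(yrep))
      L <- t(chol_psd(S))
      ystar <- drop(forwardsolve(L, sub$dv - m))
      yrepstar <- forwardsolve(L, yrep - m)
      jit <- 1e-9 * stats::runif(ni * n_reps)
      pde <- (rowSums(yrepstar + jit < ystar) + 0.5) / (n_reps + 1)
      pde <- pmin(pmax(pde, 1 / (2 * n_reps)), 1 - 1 / (2 * n_reps))
      out[[i]] <- data.frame(ID = sub$id, TIME = sub$times, DV = sub$dv,
                             npde = stats::qnorm(pde))
    }
  })
  tab <- do.call(rbind, out)
  x <- tab$npde
  list(table = tab,
       summary = list(mean = mean(x), var = stats::var(x),
                      t_pvalue = stats::t.test(x)$p.value,
                      ks_pvalue = suppressWarnings(
                        stats::ks.test(x, "pnorm")$p.value),
                      n = length(x)))
}
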