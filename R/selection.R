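#' Likelihood ratio test p-value for nested models
#'
#' The difference in -2LL between nested models is referred to a chi-squared
#' distribution with `df` degrees of freedom. Small negative differences
#' (numerical noise from approximate optimisation) are clamped to 0.
#'
#' @param neg2ll_reduced -2LL of the reduced (smaller) model.
#' @param neg2ll_full -2LL of the full model.
#' @param df Degrees of freedom (number of additional parameters), `>= 1`.
#' @return Upper-tail chi-squared p-value.
#' @examples
#' lrt_pvalue(10765.34, 10750.05, 1) # ~9.2e-5
#' @export
lrt_pvalue <- function(neg2ll_reduced, neg2ll_full, df) {
  stopifnot(df >= 1)
  d <- max(neg2ll_reduced - neg2ll_full, 0)
  stats::pchisq(d, df = df, lower.tail = FALSE)
}

#' Select the fixed target turnover rate by AIC over a grid
#'
#' The target elimination rate constant `kout` is not identifiable from drug
#' concentrations alone and is fixed; candidate values (spanning reported
#' TNF-alpha turnover across species) are compared by refitting the model at
#' each and keeping the lowest AIC. Ties break toward the smaller `kout`.
#'
#' @param dataset A `study_dataset`.
#' @param variant Structural variant to fit at each grid value.
#' @param grid Candidate `kout` values (1/day).
#' @param init,covariates,control Passed to [fit_tmdd()].
#' @return A list with `best` (selected `kout`), `table` (per-value -2LL,
#'   AIC, convergence), and `fits` (the [fit_tmdd()] results).
#' @export
kout_grid_select <- function(dataset, variant = "double_tmdd",
                             grid = c(5, 10, 20, 40, 100, 150, 200),
                             init = NULL, covariates = NULL,
                             control = fit_control()) {
  stopifnot(length(grid) >= 1)
  fits <- vector("list", length(grid))
  ok <- logical(length(grid))
  for (i in seq_along(grid)) {
    fits[[i]] <- tryCatch(
      fit_tmdd(dataset, variant, kout = grid[i], init = init,
               covariates = covariates, control = control),
      error = function(e) e)
    ok[i] <- inherits(fits[[i]], "fit_result") &&
      is.finite(fits[[i]]$neg2ll)
  }
  if (!all(ok))
    warning("non-convergent grid point(s) excluded: kout = ",
            paste(grid[!ok], collapse = ", "), call. = FALSE)
  if (!any(ok)) stop("no kout grid point converged", call. = FALSE)
  tab <- data.frame(
    kout = grid,
    neg2ll = vapply(fits, function(f)
      if (inherits(f, "fit_result")) f$neg2ll else NA_real_, 1),
    aic = vapply(fits, function(f)
      if (inherits(f, "fit_result")) f$aic else NA_real_, 1),
    converged = ok)
  cand <- which(ok)
  # argmin AIC; ties toward smaller kout (grid assumed increasing)
  best <- cand[order(tab$aic[cand], tab$kout[cand])][1]
  list(best = grid[best], table = tab, fits = fits)
}

#' Compare the four structural variants by AIC
#'
#' Fits the structural ladder -- linear two-compartment, central TMDD,
#' peripheral TMDD, double TMDD -- with shared settings and ranks the
#' variants by AIC. The linear variant is fitted first and its disposition
#' estimates seed the TMDD variants.
#'
#' @param dataset A `study_dataset` containing the cohorts to describe.
#' @param kout Fixed target elimination rate (1/day) for the TMDD variants.
#' @param control A [fit_control()] list.
#' @param init Optional [population_params()] starting values for the linear
#'   parameters.
#' @return A list with `table` (variants sorted by AIC) and `fits`.
#' @export
structural_ladder <- function(dataset, kout = 20, control = fit_control(),
                              init = NULL) {
  fits <- list()
  fits$two_compartment <- fit_tmdd(dataset, "two_compartment", kout = kout,
                                   init = init, control = control)
  lin <- fits$two_compartment$estimates
  seed_init <- function() {
    base <- infliximab_population("base")
    th <- base$theta
    th[c("V1", "CL", "V2", "Q")] <- lin$theta[c("V1", "CL", "V2", "Q")]
    om <- base$omega
    om[c("V1", "CL", "V2")] <- pmax(lin$omega[c("V1", "CL", "V2")], 0.05)
    population_params(theta = th, omega = om, sigma = lin$sigma,
                      error_form = base$error_form, mw = base$mw,
                      bw_ref = base$bw_ref)
  }
  for (v in c("central_tmdd", "peripheral_tmdd", "double_tmdd")) {
    fits[[v]] <- tryCatch(
      fit_tmdd(dataset, v, kout = kout, init = seed_init(),
               control = control),
      error = function(e) e)
  }
  ok <- vapply(fits, inherits, TRUE, "fit_result")
  if (!all(ok))
    warning("variant fit(s) failed: ", paste(names(fits)[!ok],
                                             collapse = ", "),
            call. = FALSE)
  tab <- data.frame(
    variant = names(fits)[ok],
    n_par = vapply(fits[ok], `[[`, 1L, "n_par"),
    neg2ll = vapply(fits[ok], `[[`, 1, "neg2ll"),
    aic = vapply(fits[ok], `[[`, 1, "aic"))
  tab <- tab[order(tab$aic, tab$n_par), ]
  rownames(tab) <- NULL
  list(table = tab, fits = fits)
}

default_candidates <- function() {
  expand.grid(cov = c("BW", "SX", "UC"),
              param = c("V1", "CL", "V2", "R0C", "R0P"),
              stringsAsFactors = FALSE)[, c("param", "cov")]
}

#' Two-stage stepwise covariate selection
#'
#' Univariate screening followed by backward elimination, both by likelihood
#' ratio test: each candidate covariate-parameter pair is added alone to the
#' base model and retained for the full model when significant at
#' `alpha_add`; covariates of the full model are then removed one at a time,
#' dropping the least significant until every remaining effect is
#' significant at `alpha_drop`. Candidates on parameters without estimated
#' interindividual variance are not tested. At equal p-values covariates are
#' processed in the fixed order BW, SX, UC for reproducibility.
#'
#' @param dataset A `study_dataset`.
#' @param base_fit A [fit_tmdd()] result without covariates.
#' @param candidates Data frame with columns `param`, `cov`; defaults to the
#'   full grid of BW/SX/UC on the parameters carrying IIV.
#' @param alpha_add Univariate inclusion level.
#' @param alpha_drop Backward retention level.
#' @param control A [fit_control()] list.
#' @return A list with `final_fit`, `selected` (data frame of retained
#'   effects), and `trail` (the full decision log).
#' @export
covariate_stepwise <- function(dataset, base_fit,
                               candidates = default_candidates(),
                               alpha_add = 0.05, alpha_drop = 0.02,
                               control = fit_control()) {
  stopifnot(inherits(base_fit, "fit_result"))
  spec <- variant_spec(base_fit$variant)
  candidates <- as.data.frame(candidates)
  keep <- candidates$param %in% spec$omega &
    pmax(base_fit$estimates$omega[candidates$param], 0) > 0
  candidates <- candidates[keep, , drop = FALSE]
  cov_order <- c(BW = 1L, SX = 2L, UC = 3L)
  candidates <- candidates[order(cov_order[candidates$cov],
                                 candidates$param), , drop = FALSE]
  trail <- list()
  log_step <- function(stage, action, param, cov, neg2ll, lrt, p, decision) {
    trail[[length(trail) + 1L]] <<- data.frame(
      stage = stage, action = action, param = param, cov = cov,
      neg2ll = neg2ll, lrt = lrt, p = p, decision = decision)
  }
  refit <- function(cm) {
    if (!is.null(cm) && !nrow(cm)) cm <- NULL
    fit_tmdd(dataset, base_fit$variant, kout = base_fit$kout,
             init = base_fit$estimates, covariates = cm, control = control)
  }
  if (!nrow(candidates)) {
    return(list(final_fit = base_fit, selected = candidates,
                trail = data.frame()))
  }
  # univariate step
  pvals <- numeric(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    f1 <- tryCatch(refit(candidates[i, , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(f1)) {
      pvals[i] <- NA_real_
      log_step("univariate", "add", candidates$param[i], candidates$cov[i],
               NA, NA, NA, "failed")
      next
    }
    lrt <- max(base_fit$neg2ll - f1$neg2ll, 0)
    pvals[i] <- lrt_pvalue(base_fit$neg2ll, f1$neg2ll, 1)
    log_step("univariate", "add", candidates$param[i], candidates$cov[i],
             f1$neg2ll, lrt, pvals[i],
             if (pvals[i] < alpha_add) "enter" else "reject")
  }
  if (any(is.na(pvals)))
    warning("non-convergent candidate fit(s) excluded", call. = FALSE)
  current <- candidates[!is.na(pvals) & pvals < alpha_add, , drop = FALSE]
  if (!nrow(current)) {
    return(list(final_fit = base_fit, selected = current,
                trail = do.call(rbind, trail)))
  }
  full_fit <- refit(current)
  # backward elimination
  repeat {
    if (!nrow(current)) break
    pdrop <- numeric(nrow(current))
    fdrop <- vector("list", nrow(current))
    t0 <- length(trail)
    for (i in seq_len(nrow(current))) {
      reduced <- current[-i, , drop = FALSE]
      fdrop[[i]] <- tryCatch(refit(reduced), error = function(e) NULL)
      pdrop[i] <- if (is.null(fdrop[[i]])) NA_real_
      else lrt_pvalue(fdrop[[i]]$neg2ll, full_fit$neg2ll, 1)
      log_step("backward", "remove", current$param[i], current$cov[i],
               if (is.null(fdrop[[i]])) NA else fdrop[[i]]$neg2ll,
               if (is.null(fdrop[[i]])) NA
               else max(fdrop[[i]]$neg2ll - full_fit$neg2ll, 0),
               pdrop[i], "")
    }
    worst <- which.max(ifelse(is.na(pdrop), -Inf, pdrop))
    for (i in seq_len(nrow(current)))
      trail[[t0 + i]]$decision <-
        if (i == worst && !is.na(pdrop[i]) && pdrop[i] >= alpha_drop)
          "drop" else "keep"
    if (length(worst) && is.finite(pdrop[worst]) &&
        pdrop[worst] >= alpha_drop) {
      current <- current[-worst, , drop = FALSE]
      full_fit <- if (is.null(fdrop[[worst]])) refit(current)
      else fdrop[[worst]]
    } else break
  }
  final <- if (nrow(current)) full_fit else base_fit
  list(final_fit = final, selected = current,
       trail = do.call(rbind, trail))
}
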