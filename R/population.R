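#' Population (mixed-effects) parameters
#'
#' Typical structural values plus the statistical model: covariate
#' coefficients, interindividual variability (IIV) standard deviations and
#' the residual error model. IIV is exponential (log-normal): an individual
#' parameter is `theta_TV * exp(eta)` with `eta ~ N(0, omega^2)`. Parameters
#' whose variance is not estimable carry `omega = 0` exactly.
#'
#' Covariate coefficients act on the log scale: body weight enters as a power
#' function centred on `bw_ref`, `theta * (BW/bw_ref)^beta`; a categorical
#' covariate multiplies by `exp(beta)` for the non-reference category
#' (references: female, Crohn's disease).
#'
#' @param theta Named numeric vector of typical values with names `V1`, `CL`,
#'   `V2`, `Q`, `R0C`, `KSSC`, `kintC`, `R0P`, `KSSP`, `kintP`, `kout`.
#'   TMDD entries may be 0/absent for reduced model variants.
#' @param covariates `NULL` or a data frame with columns `param` (one of
#'   `V1`, `CL`, `V2`, `R0C`, `R0P`), `cov` (`"BW"`, `"SX"`, `"UC"`) and
#'   `value` (the coefficient `beta`).
#' @param bw_ref Reference (centering) body weight, kg.
#' @param omega Named numeric vector of IIV standard deviations for a subset
#'   of `V1`, `CL`, `V2`, `R0C`, `R0P`; missing entries are 0.
#' @param sigma Residual error parameters `c(add = , prop = )`: additive SD
#'   in mg/L and proportional fraction.
#' @param error_form `"combined1"` (default): SD = `add + prop * f`;
#'   `"combined2"`: SD = `sqrt(add^2 + (prop * f)^2)`.
#' @param mw Molar mass (g/mol) used at the data boundary.
#' @return An object of class `population_params`.
#' @seealso [infliximab_population()] for the reference estimates shipped
#'   with the package.
#' @export
population_params <- function(theta, covariates = NULL, bw_ref = 66,
                              omega = c(V1 = 0, CL = 0, V2 = 0,
                                        R0C = 0, R0P = 0),
                              sigma = c(add = 0, prop = 0),
                              error_form = c("combined1", "combined2"),
                              mw = 149000) {
  error_form <- match.arg(error_form)
  th_names <- c("V1", "CL", "V2", "Q", "R0C", "KSSC", "kintC",
                "R0P", "KSSP", "kintP", "kout")
  full <- stats::setNames(numeric(length(th_names)), th_names)
  full[names(theta)] <- theta
  om_names <- c("V1", "CL", "V2", "R0C", "R0P")
  om <- stats::setNames(numeric(5L), om_names)
  om[names(omega)] <- omega
  if (any(om < 0)) stop("omega must be >= 0", call. = FALSE)
  sg <- c(add = 0, prop = 0)
  sg[names(sigma)] <- sigma
  if (any(sg < 0)) stop("sigma must be >= 0", call. = FALSE)
  if (!is.null(covariates)) {
    stopifnot(is.data.frame(covariates),
              all(c("param", "cov", "value") %in% names(covariates)),
              all(covariates$param %in% om_names),
              all(covariates$cov %in% c("BW", "SX", "UC")))
    covariates <- covariates[, c("param", "cov", "value")]
    rownames(covariates) <- NULL
  }
  structure(list(theta = full, covariates = covariates, bw_ref = bw_ref,
                 omega = om, sigma = sg, error_form = error_form, mw = mw),
            class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat("<population_params>\n  theta:\n")
  th <- x$theta[x$theta != 0 | names(x$theta) %in% c("V1", "CL", "V2", "Q")]
  print(signif(th, 4))
  if (!is.null(x$covariates) && nrow(x$covariates)) {
    cat(sprintf("  covariates (BW centred on %g kg):\n", x$bw_ref))
    print(x$covariates)
  }
  cat("  omega:", paste(sprintf("%s=%g", names(x$omega), x$omega),
                        collapse = ", "), "\n")
  cat(sprintf("  sigma: add=%g mg/L, prop=%g (%s)\n",
              x$sigma["add"], x$sigma["prop"], x$error_form))
  invisible(x)
}

#' Reference population parameter sets for infliximab
#'
#' Published population estimates of the infliximab double-TMDD QSS model in
#' inflammatory bowel disease (with an ankylosing spondylitis cohort as the
#' linear reference), used throughout the package as generator truth,
#' fitting starting values and simulation inputs.
#'
#' @param model `"final"`: the covariate model (BW and sex on V1, sex on CL,
#'   ulcerative colitis on R0C). `"base"`: the double-TMDD model without
#'   covariates. `"base_2cpt"`: the linear two-compartment base model.
#' @return A [population_params()] object.
#' @examples
#' infliximab_population("final")
#' @export
infliximab_population <- function(model = c("final", "base", "base_2cpt")) {
  model <- match.arg(model)
  switch(model,
    final = population_params(
      theta = c(V1 = 2.6, CL = 0.16, V2 = 1.9, Q = 1.8,
                R0C = 3.3, KSSC = 15.4, kintC = 0.17,
                R0P = 0.46, KSSP = 0.49, kintP = 0.0079, kout = 20),
      covariates = data.frame(
        param = c("V1", "V1", "CL", "R0C"),
        cov = c("BW", "SX", "SX", "UC"),
        value = c(0.33, 0.13, 0.36, 0.57)),
      bw_ref = 66,
      omega = c(V1 = 0.27, CL = 0.35, V2 = 0.39, R0C = 1.0, R0P = 1.1),
      sigma = c(add = 1.8, prop = 0.20)),
    base = population_params(
      theta = c(V1 = 2.8, CL = 0.20, V2 = 1.9, Q = 1.5,
                R0C = 2.6, KSSC = 13.7, kintC = 0.13,
                R0P = 0.30, KSSP = 0.45, kintP = 0.0050, kout = 20),
      omega = c(V1 = 0.29, CL = 0.38, V2 = 0.36, R0C = 1.0, R0P = 1.2),
      sigma = c(add = 1.8, prop = 0.20)),
    base_2cpt = population_params(
      theta = c(V1 = 3.0, CL = 0.29, V2 = 2.2, Q = 0.29, kout = 20),
      omega = c(V1 = 0.28, CL = 0.46, V2 = 0.62),
      sigma = c(add = 1.8, prop = 0.20))
  )
}

#' Subject covariates
#'
#' @param BW Body weight (kg), `> 0`.
#' @param sex `"F"` (reference) or `"M"`.
#' @param disease `"CD"` (reference), `"UC"`, or `"AS"`. Ankylosing
#'   spondylitis subjects are the linear reference: both TMDD arms are forced
#'   off for them.
#' @return An object of class `subject_covariates`.
#' @export
subject_covariates <- function(BW, sex = c("F", "M"),
                               disease = c("CD", "UC", "AS")) {
  sex <- match.arg(sex)
  disease <- match.arg(disease)
  if (!is.numeric(BW) || length(BW) != 1L || BW <= 0)
    stop("BW must be a single positive number", call. = FALSE)
  structure(list(BW = BW, sex = sex, disease = disease),
            class = "subject_covariates")
}

#' Typical structural parameters for a covariate profile
#'
#' Applies the covariate model of a [population_params()] object to obtain
#' the typical-value [structural_params()] of a subject: body weight as a
#' centred power function, categorical effects as `exp(beta)` multipliers.
#' Effects are multiplicative, hence order-independent. For ankylosing
#' spondylitis subjects both TMDD arms are switched off (`R0 = 0`), all
#' linear parameters being shared with the TMDD population.
#'
#' @param pop A [population_params()] object.
#' @param cov A [subject_covariates()] object.
#' @return A [structural_params()] object.
#' @examples
#' pop <- infliximab_population("final")
#' typical_params(pop, subject_covariates(66, "M", "CD"))$CL # ~0.23 L/day
#' @export
typical_params <- function(pop, cov) {
  stopifnot(inherits(pop, "population_params"),
            inherits(cov, "subject_covariates"))
  th <- pop$theta
  cm <- pop$covariates
  if (!is.null(cm)) {
    for (i in seq_len(nrow(cm))) {
      p <- cm$param[i]; b <- cm$value[i]
      th[p] <- th[p] * switch(cm$cov[i],
        BW = (cov$BW / pop$bw_ref)^b,
        SX = exp(b * (cov$sex == "M")),
        UC = exp(b * (cov$disease == "UC")))
    }
  }
  as_sp <- function(th, central, peripheral) {
    structural_params(V1 = th[["V1"]], V2 = th[["V2"]], CL = th[["CL"]],
                      Q = th[["Q"]],
                      R0C = th[["R0C"]], KSSC = th[["KSSC"]],
                      kintC = th[["kintC"]],
                      R0P = th[["R0P"]], KSSP = th[["KSSP"]],
                      kintP = th[["kintP"]], kout = th[["kout"]],
                      tmdd_central = central, tmdd_peripheral = peripheral)
  }
  if (cov$disease == "AS")
    as_sp(th, central = FALSE, peripheral = FALSE)
  else
    as_sp(th, central = th[["R0C"]] > 0, peripheral = th[["R0P"]] > 0)
}

#' Individual parameters from random effects
#'
#' Exponential interindividual variability: each of the five parameters
#' carrying IIV (`V1`, `CL`, `V2`, `R0C`, `R0P`) is multiplied by
#' `exp(eta)`; all other parameters are untouched. Random effects on a
#' disabled TMDD arm are ignored.
#'
#' @param typical A [structural_params()] object (the subject's typical
#'   values).
#' @param eta Named numeric vector of random effects; names among `V1`,
#'   `CL`, `V2`, `R0C`, `R0P`. Unnamed vectors of length 5 are taken in that
#'   order.
#' @return A [structural_params()] object.
#' @export
individual_params <- function(typical, eta) {
  stopifnot(inherits(typical, "structural_params"))
  nm5 <- c("V1", "CL", "V2", "R0C", "R0P")
  if (is.null(names(eta))) {
    stopifnot(length(eta) == 5L)
    names(eta) <- nm5
  }
  stopifnot(all(names(eta) %in% nm5))
  p <- typical
  for (nm in names(eta)) {
    if (nm %in% c("R0C") && !p$tmdd_central) next
    if (nm %in% c("R0P") && !p$tmdd_peripheral) next
    p[[nm]] <- p[[nm]] * exp(eta[[nm]])
  }
  structural_params(V1 = p$V1, V2 = p$V2, CL = p$CL, Q = p$Q,
                    R0C = p$R0C, KSSC = p$KSSC, kintC = p$kintC,
                    R0P = p$R0P, KSSP = p$KSSP, kintP = p$kintP,
                    kout = p$kout,
                    tmdd_central = p$tmdd_central,
                    tmdd_peripheral = p$tmdd_peripheral)
}

#' Residual error model
#'
#' Mixed additive-proportional residual error. In the default `"combined1"`
#' form an observation is `y = f + (sigma_add + sigma_prop * f) * eps` with
#' standard-normal `eps`; the per-observation SD used in the likelihood is
#' `residual_sd()`. The `"combined2"` alternative uses
#' `sqrt(sigma_add^2 + (sigma_prop * f)^2)`.
#'
#' @param pred_conc Model-predicted concentration(s), mg/L, `>= 0`.
#' @param sigma_add Additive SD (mg/L).
#' @param sigma_prop Proportional fraction.
#' @param epsilon Standard-normal deviate(s).
#' @param form `"combined1"` or `"combined2"`.
#' @return `residual_error()`: simulated observation(s) (mg/L, possibly
#'   negative; the generator truncates at 0). `residual_sd()`: the
#'   per-observation SD (mg/L).
#' @examples
#' residual_sd(9, 1.8, 0.20) # 3.6 mg/L
#' @export
residual_error <- function(pred_conc, sigma_add, sigma_prop, epsilon,
                           form = c("combined1", "combined2")) {
  pred_conc + residual_sd(pred_conc, sigma_add, sigma_prop, form) * epsilon
}

#' @rdname residual_error
#' @export
residual_sd <- function(pred_conc, sigma_add, sigma_prop,
                        form = c("combined1", "combined2")) {
  form <- match.arg(form)
  if (any(pred_conc < 0)) stop("pred_conc must be >= 0", call. = FALSE)
  if (form == "combined1") sigma_add + sigma_prop * pred_conc
  else sqrt(sigma_add^2 + (sigma_prop * pred_conc)^2)
}
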