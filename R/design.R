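# run expr under a local RNG state; restores .Random.seed afterwards
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Study designs of the two infliximab cohorts
#'
#' Scheduled designs used by the synthetic-trial generator:
#'
#' * `"as_rich"` - ankylosing spondylitis cohort: 5 mg/kg infusions at weeks
#'   0, 2, 6, 12, 18; samples pre-dose and 2 h and 4 h after the end of each
#'   infusion, plus intermediate visits at weeks 1, 3, 4, 5, 8, 10 and 14
#'   (about 22 scheduled samples per subject). Subjects are the linear
#'   reference: both TMDD arms off.
#' * `"ibd_sparse"` - routine inflammatory-bowel-disease cohort: 5 mg/kg at
#'   weeks 0, 2, 6 then every 8 weeks (weeks 14, 22); trough (pre-dose) and
#'   peak (end of infusion + 1 h) per cycle, with 3 or 4 cycles retained per
#'   subject. The exact routine sampling occasions are an emulation and are
#'   flagged as such in the provenance metadata.
#' * `"ibd_rich"` - the IBD regimen (weeks 0, 2, 6, 14, 22) with dense
#'   AS-like sampling; used for simulation studies requiring an
#'   identification-rich IBD design.
#'
#' Body weight is drawn from a cohort-specific truncated normal; sex and
#' disease with the cohort frequencies. Assay quantitation limits are 0.103
#' and 15 mg/L; values below the lower limit are censored, values above the
#' upper limit are retained (dilution-corrected reporting assumed).
#'
#' @param cohort One of `"as_rich"`, `"ibd_sparse"`, `"ibd_rich"`.
#' @param dose_per_kg Dose level, mg/kg.
#' @param infusion_duration Infusion duration, day.
#' @param missingness Independent per-sample dropout probability applied by
#'   the generator so realised sample counts resemble the study counts.
#' @return An object of class `study_design`.
#' @export
study_design <- function(cohort = c("as_rich", "ibd_sparse", "ibd_rich"),
                         dose_per_kg = 5, infusion_duration = 2 / 24,
                         missingness = 0.10) {
  cohort <- match.arg(cohort)
  h <- 1 / 24
  per_dose <- function(t, dur) {
    data.frame(time = c(t, t + dur + 2 * h, t + dur + 4 * h),
               label = c("trough", "peak", "peak"))
  }
  d <- switch(cohort,
    as_rich = list(
      dose_days = 7 * c(0, 2, 6, 12, 18),
      covariates = list(bw_mean = 75, bw_sd = 15, bw_range = c(41, 110),
                        p_male = 19 / 25, p_uc = 0, disease = "AS"),
      sampler = function(dose_days, dur) {
        tpl <- do.call(rbind, lapply(dose_days, per_dose, dur = dur))
        tpl <- rbind(tpl, data.frame(time = 7 * c(1, 3, 4, 5, 8, 10, 14),
                                     label = "intermediate"))
        tpl[order(tpl$time), ]
      }),
    ibd_sparse = list(
      dose_days = 7 * c(0, 2, 6, 14, 22),
      covariates = list(bw_mean = 64, bw_sd = 12, bw_range = c(41, 110),
                        p_male = 80 / 133, p_uc = 25 / 133, disease = "IBD"),
      sampler = function(dose_days, dur, ncycles) {
        keep <- dose_days[seq_len(ncycles)]
        tpl <- data.frame(time = c(keep, keep + dur + 1 * h),
                          label = rep(c("trough", "peak"), each = ncycles))
        tpl[order(tpl$time), ]
      }),
    ibd_rich = list(
      dose_days = 7 * c(0, 2, 6, 14, 22),
      covariates = list(bw_mean = 64, bw_sd = 12, bw_range = c(41, 110),
                        p_male = 80 / 133, p_uc = 25 / 133, disease = "IBD"),
      sampler = function(dose_days, dur) {
        tpl <- do.call(rbind, lapply(dose_days, per_dose, dur = dur))
        tpl <- rbind(tpl, data.frame(
          time = 7 * c(1, 3, 4, 5, 8, 10, 12, 16, 18, 20, 24, 26),
          label = "intermediate"))
        tpl[order(tpl$time), ]
      })
  )
  structure(c(list(cohort = cohort, dose_per_kg = dose_per_kg,
                   infusion_duration = infusion_duration,
                   missingness = missingness,
                   lloq = 0.103, uloq = 15), d),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design>", x$cohort, "\n")
  cat("  doses:", x$dose_per_kg, "mg/kg on days",
      paste(x$dose_days, collapse = ", "), "\n")
  cat("  LLOQ", x$lloq, "mg/L, missingness", x$missingness, "\n")
  invisible(x)
}

# covariate spec of the population simulation scenario: BW ~ N(66, 15)
# truncated to [41, 110], sex 50/50, CD:UC = 5:1
scenario_covariates <- function() {
  list(bw_mean = 66, bw_sd = 15, bw_range = c(41, 110),
       p_male = 0.5, p_uc = 1 / 6, disease = "IBD")
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Sample subject covariates for a cohort
#'
#' Draws body weight from a truncated normal and sex/disease from the cohort
#' frequencies. `cohort = "scenario"` uses the population-simulation
#' scenario: BW ~ Normal(66, 15) truncated to 41-110 kg, 50/50 sex,
#' CD:UC = 5:1.
#'
#' @param cohort A [study_design()], a cohort name, or `"scenario"`.
#' @param n Number of subjects.
#' @param seed Optional integer seed (local RNG state).
#' @return A data frame with columns `BW`, `SEX` (0 = F, 1 = M), `DIS`
#'   (0 = CD, 1 = UC, 2 = AS).
#' @export
sample_covariates <- function(cohort, n, seed = NULL) {
  if (inherits(cohort, "study_design")) spec <- cohort$covariates
  else if (identical(cohort, "scenario")) spec <- scenario_covariates()
  else if (is.character(cohort)) spec <- study_design(cohort)$covariates
  else stop("unknown cohort", call. = FALSE)
  if (n <= 0) stop("n must be > 0", call. = FALSE)
  with_seed(seed, {
    bw <- rtruncnorm1(n, spec$bw_mean, spec$bw_sd,
                      spec$bw_range[1], spec$bw_range[2])
    sex <- stats::rbinom(n, 1L, spec$p_male)
    dis <- if (spec$disease == "AS") rep(2L, n)
           else stats::rbinom(n, 1L, spec$p_uc)
    data.frame(BW = bw, SEX = sex, DIS = dis)
  })
}

#' Weight-based dose with vial rounding
#'
#' `BW * dose_per_kg` rounded half-up to the nearest vial size (100 mg).
#'
#' @param BW Body weight (kg), `> 0`.
#' @param dose_per_kg Dose level (mg/kg).
#' @param vial Vial size (mg).
#' @return Dose in mg. Vectorised over `BW`.
#' @examples
#' dose_from_weight(c(64, 75), 5) # 300, 400
#' @export
dose_from_weight <- function(BW, dose_per_kg = 5, vial = 100) {
  if (any(BW <= 0)) stop("BW must be > 0", call. = FALSE)
  floor(BW * dose_per_kg / vial + 0.5) * vial
}

cov_object <- function(row) {
  subject_covariates(row$BW,
                     sex = if (row$SEX == 1) "M" else "F",
                     disease = c("CD", "UC", "AS")[row$DIS + 1L])
}

#' Generate a synthetic study dataset
#'
#' Simulates an ADA-free cohort under a [study_design()]: covariates are
#' sampled, each subject receives weight-based vial-rounded doses on the
#' design schedule, the individual latent concentration profile is simulated
#' from the population model (exponential IIV; ankylosing spondylitis
#' subjects with both TMDD arms off), residual error is added, negative
#' values are truncated at 0, and values below the 0.103 mg/L quantitation
#' limit are flagged as censored (carrying the limit as bound). Values above
#' 15 mg/L are retained as-is (dilution-corrected reporting). Independent
#' per-sample dropout thins the schedule to realistic sample counts.
#'
#' @param design A [study_design()].
#' @param pop A [population_params()] object (generator truth).
#' @param n Number of subjects.
#' @param seed Integer seed; identical `(design, pop, n, seed)` give
#'   byte-identical datasets.
#' @param missingness Per-sample dropout probability; defaults to the
#'   design's value.
#' @param id_offset Added to the 1-based subject IDs.
#' @return An object of class `study_dataset`: a list with `data` (a
#'   NONMEM-style data frame with columns `ID, TIME, AMT, RATE, DV, EVID,
#'   MDV, CENS, BW, SEX, DIS, COHORT, LABEL`), `subjects`, and `provenance`
#'   (seed, generator version, true parameters, design label).
#' @export
generate_dataset <- function(design, pop, n, seed,
                             missingness = design$missingness,
                             id_offset = 0L) {
  stopifnot(inherits(design, "study_design"),
            inherits(pop, "population_params"), n > 0)
  units <- unit_system(pop$mw)
  with_seed(seed, {
    covs <- sample_covariates(design, n)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      ci <- cov_object(covs[i, ])
      amt <- dose_from_weight(ci$BW, design$dose_per_kg)
      reg <- dose_events(design$dose_days, amt, design$infusion_duration)
      eta <- stats::rnorm(5L, 0, pop$omega)
      names(eta) <- names(pop$omega)
      ip <- individual_params(typical_params(pop, ci), eta)
      tpl <- if (design$cohort == "ibd_sparse")
        design$sampler(design$dose_days, design$infusion_duration,
                       ncycles = 3L + stats::rbinom(1L, 1L, 0.5))
      else design$sampler(design$dose_days, design$infusion_duration)
      keep <- stats::runif(nrow(tpl)) >= missingness
      tpl <- tpl[keep, , drop = FALSE]
      prof <- simulate_profile(ip, reg, tpl$time, units,
                               rtol = 1e-8, atol = 1e-10)
      eps <- stats::rnorm(nrow(tpl))
      dv <- residual_error(prof$conc_mgL, pop$sigma["add"],
                           pop$sigma["prop"], eps, pop$error_form)
      dv <- pmax(dv, 0)
      # pre-first-dose samples contain no drug: the assay reports them
      # below the quantitation limit, not as residual noise around zero
      dv[tpl$time <= reg$time[1] + 1e-12] <- 0
      cens <- as.integer(dv < design$lloq)
      dv[cens == 1L] <- design$lloq
      id <- i + id_offset
      dose_rows <- data.frame(
        ID = id, TIME = reg$time, AMT = reg$amount, RATE = reg$rate,
        DV = NA_real_, EVID = 1L, MDV = 1L, CENS = 0L,
        BW = ci$BW, SEX = covs$SEX[i], DIS = covs$DIS[i],
        COHORT = design$cohort, LABEL = "dose")
      obs_rows <- data.frame(
        ID = id, TIME = tpl$time, AMT = 0, RATE = 0,
        DV = dv, EVID = 0L, MDV = 0L, CENS = cens,
        BW = ci$BW, SEX = covs$SEX[i], DIS = covs$DIS[i],
        COHORT = design$cohort, LABEL = tpl$label)
      sub <- rbind(dose_rows, obs_rows)
      sub <- sub[order(sub$TIME, -sub$EVID), ]
      rows[[i]] <- sub
    }
    dat <- do.call(rbind, rows)
    rownames(dat) <- NULL
    subjects <- cbind(ID = seq_len(n) + id_offset, covs,
                      COHORT = design$cohort)
    structure(list(
      data = dat, subjects = subjects,
      provenance = list(seed = seed, n = n, design = design$cohort,
                        sampling_emulated = design$cohort == "ibd_sparse",
                        generator_version =
                          as.character(utils::packageVersion("dtmdd")),
                        true_pop = pop)),
      class = "study_dataset")
  })
}

#' Combine study datasets
#'
#' Stacks several [generate_dataset()] results (e.g. the AS reference cohort
#' and an IBD cohort) into one joint dataset. Subject IDs must not collide;
#' use `id_offset` when generating.
#'
#' @param ... `study_dataset` objects.
#' @return A `study_dataset`.
#' @export
bind_datasets <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1L,
            all(vapply(parts, inherits, TRUE, "study_dataset")))
  ids <- unlist(lapply(parts, function(p) unique(p$data$ID)))
  if (anyDuplicated(ids))
    stop("subject IDs collide; use id_offset in generate_dataset()",
         call. = FALSE)
  structure(list(
    data = do.call(rbind, lapply(parts, `[[`, "data")),
    subjects = do.call(rbind, lapply(parts, `[[`, "subjects")),
    provenance = lapply(parts, `[[`, "provenance")),
    class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  obs <- x$data[x$data$EVID == 0L, ]
  cat("<study_dataset>", nrow(x$subjects), "subjects,", nrow(obs),
      "observations (", sum(obs$CENS), "below LLOQ )\n")
  cat("  cohorts:", paste(unique(x$data$COHORT), collapse = ", "), "\n")
  invisible(x)
}

#' Read and write NONMEM-style dataset files
#'
#' Plain-CSV serialisation of a [generate_dataset()] dataset. Factor
#' encodings: `SEX` 0 = F / 1 = M; `DIS` 0 = CD / 1 = UC / 2 = AS; dose rows
#' have `EVID = 1`, `MDV = 1` and an empty `DV`; censored observations carry
#' `CENS = 1` and the quantitation limit in `DV`. A written file re-read and
#' re-written is byte-identical.
#'
#' @param ds A `study_dataset` (or a bare data frame in the same layout).
#' @param path File path.
#' @return `read_dataset()` returns a `study_dataset` (without generator
#'   provenance); `write_dataset()` returns `path` invisibly.
#' @export
write_dataset <- function(ds, path) {
  dat <- if (inherits(ds, "study_dataset")) ds$data else ds
  utils::write.csv(dat, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(COHORT = "character",
                                        LABEL = "character"))
  dat$DV <- as.numeric(dat$DV)
  subs <- unique(dat[, c("ID", "BW", "SEX", "DIS", "COHORT")])
  rownames(subs) <- NULL
  structure(list(data = dat, subjects = subs,
                 provenance = list(source = path)),
            class = "study_dataset")
}
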