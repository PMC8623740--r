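#' Structural double-TMDD model parameters for one subject
#'
#' Fixed-effect parameters of the two-compartment model with target-mediated
#' drug disposition (TMDD) in the central and/or peripheral compartment under
#' the quasi-steady-state (QSS) approximation. Target production rates are
#' never stored: `kinC = R0C * kout` and `kinP = R0P * kout` are recomputed
#' from the baseline levels, so baseline is always an equilibrium of the
#' target turnover.
#'
#' A TMDD arm is active iff its baseline target level `R0` is positive; with
#' an arm disabled the corresponding compartment reduces exactly to linear
#' two-compartment kinetics. The peripheral drug state `CPT` is an apparent
#' concentration in the k12/k21 micro-constant convention: the transfer terms
#' `(Q/V1) C - (Q/V2) CP` conserve the sum of the two concentration states,
#' not amounts scaled by the volumes. This is the convention in which the
#' model was estimated and it is deliberately not "corrected".
#'
#' @param V1,V2 Central and peripheral volumes of distribution (L).
#' @param CL,Q Systemic and intercompartmental clearances (L/day).
#' @param R0C,R0P Baseline total target levels (nM); `0` disables the arm.
#' @param KSSC,KSSP Steady-state dissociation constants (nM); required
#'   (positive) when the corresponding arm is active.
#' @param kintC,kintP First-order elimination rate constants of the
#'   drug-target complex (1/day).
#' @param kout First-order target elimination rate constant (1/day), shared
#'   by both compartments.
#' @param tmdd_central,tmdd_peripheral Logical switches for the two TMDD
#'   arms. Defaults follow `R0C`/`R0P`; setting a switch `FALSE` forces the
#'   corresponding `R0` to zero.
#' @return An object of class `structural_params`.
#' @examples
#' structural_params(V1 = 2.6, V2 = 1.9, CL = 0.16, Q = 1.8,
#'                   R0C = 3.3, KSSC = 15.4, kintC = 0.17,
#'                   R0P = 0.46, KSSP = 0.49, kintP = 0.0079, kout = 20)
#' @export
structural_params <- function(V1, V2, CL, Q,
                              R0C = 0, KSSC = 0, kintC = 0,
                              R0P = 0, KSSP = 0, kintP = 0,
                              kout = 20,
                              tmdd_central = R0C > 0,
                              tmdd_peripheral = R0P > 0) {
  chk_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop(nm, " must be a single positive number", call. = FALSE)
  }
  for (nm in c("V1", "V2", "CL", "Q"))
    chk_pos(get(nm), nm)
  if (!tmdd_central) R0C <- 0
  if (!tmdd_peripheral) R0P <- 0
  if (tmdd_central) {
    chk_pos(R0C, "R0C"); chk_pos(KSSC, "KSSC"); chk_pos(kintC, "kintC")
    chk_pos(kout, "kout")
  }
  if (tmdd_peripheral) {
    chk_pos(R0P, "R0P"); chk_pos(KSSP, "KSSP"); chk_pos(kintP, "kintP")
    chk_pos(kout, "kout")
  }
  structure(list(V1 = V1, V2 = V2, CL = CL, Q = Q,
                 R0C = R0C, KSSC = KSSC, kintC = kintC,
                 R0P = R0P, KSSP = KSSP, kintP = kintP,
                 kout = kout,
                 tmdd_central = R0C > 0, tmdd_peripheral = R0P > 0),
            class = "structural_params")
}

#' @export
print.structural_params <- function(x, ...) {
  cat("<structural_params>\n")
  cat(sprintf("  linear:     V1 = %g L, V2 = %g L, CL = %g L/d, Q = %g L/d\n",
              x$V1, x$V2, x$CL, x$Q))
  if (x$tmdd_central)
    cat(sprintf("  central:    R0C = %g nM, KSSC = %g nM, kintC = %g /d\n",
                x$R0C, x$KSSC, x$kintC))
  if (x$tmdd_peripheral)
    cat(sprintf("  peripheral: R0P = %g nM, KSSP = %g nM, kintP = %g /d\n",
                x$R0P, x$KSSP, x$kintP))
  if (x$tmdd_central || x$tmdd_peripheral)
    cat(sprintf("  target:     kout = %g /d\n", x$kout))
  if (!x$tmdd_central && !x$tmdd_peripheral)
    cat("  TMDD: off (linear two-compartment kinetics)\n")
  invisible(x)
}

# parameter vector in the order the C solver expects
par_vector <- function(p) {
  c(p$CL, p$V1, p$Q, p$V2, p$R0C, p$KSSC, p$kintC,
    p$R0P, p$KSSP, p$kintP, p$kout)
}

#' Infusion dose events
#'
#' Zero-order infusion events. The input function equals `amount/duration`
#' (mg/day) on `[time, time + duration)` and 0 elsewhere; overlapping
#' infusions add.
#'
#' @param time Start times (day), non-decreasing.
#' @param amount Doses (mg), `>= 0`.
#' @param duration Infusion durations (day), `> 0`. Default 2 h.
#' @return A `dose_events` data frame with columns `time`, `amount`,
#'   `duration`, `rate` (mg/day).
#' @examples
#' dose_events(time = c(0, 14, 42), amount = 330)
#' @export
dose_events <- function(time, amount, duration = 2 / 24) {
  n <- max(length(time), length(amount), length(duration))
  time <- rep_len(time, n); amount <- rep_len(amount, n)
  duration <- rep_len(duration, n)
  if (any(!is.finite(time)) || is.unsorted(time))
    stop("dose times must be finite and sorted", call. = FALSE)
  if (any(amount < 0)) stop("dose amounts must be >= 0", call. = FALSE)
  if (any(duration <= 0)) stop("infusion durations must be > 0", call. = FALSE)
  structure(data.frame(time = time, amount = amount, duration = duration,
                       rate = amount / duration),
            class = c("dose_events", "data.frame"))
}

dose_matrix <- function(regimen) {
  stopifnot(is.data.frame(regimen))
  cbind(regimen$time, regimen$duration, regimen$rate)
}

#' Unbound drug concentration under the QSS approximation
#'
#' Non-negative root of `C^2 + (RT + KSS - CT) C - KSS CT = 0`, i.e. the
#' unbound drug concentration when free drug, free target and complex are in
#' quasi-steady state. Evaluated in a cancellation-safe form; roundoff
#' negatives are clamped to 0 and the result never exceeds the total
#' concentration.
#'
#' @param total_drug Total drug concentration `CT` (nM), `>= 0`.
#' @param total_target Total target level `RT` (nM), `>= 0`.
#' @param kss Steady-state dissociation constant (nM), `> 0`. As a special
#'   case `kss = 0` with `total_target = 0` returns `total_drug` (no target).
#' @return Unbound drug concentration (nM), in `[0, total_drug]`. Vectorised.
#' @examples
#' qss_unbound(50, 100, 15.4) # ~10.19
#' @export
qss_unbound <- function(total_drug, total_target, kss) {
  n <- max(length(total_drug), length(total_target), length(kss))
  ct <- rep_len(total_drug, n); rt <- rep_len(total_target, n)
  k <- rep_len(kss, n)
  if (any(ct < 0) || any(rt < 0) || any(k < 0))
    stop("qss_unbound: inputs must be non-negative", call. = FALSE)
  if (any(k == 0 & rt > 0))
    stop("qss_unbound: kss must be > 0 when target is present", call. = FALSE)
  b <- ct - rt - k
  s <- sqrt(b * b + 4 * k * ct)
  out <- ifelse(b >= 0, 0.5 * (b + s), 2 * k * ct / (s - b))
  out[rt == 0] <- ct[rt == 0]
  pmin(pmax(out, 0), ct)
}

#' Right-hand side of the double-TMDD ODE system
#'
#' Derivatives of the four model states. Unbound concentrations are first
#' recovered from the totals with [qss_unbound()], then the mass balance of
#' each compartment is evaluated. With a TMDD arm disabled (`R0 = 0`) the
#' compartment reduces to the linear two-compartment terms.
#'
#' This R implementation mirrors the compiled solver and is mainly useful for
#' inspection and for integrating the system with an external ODE solver.
#'
#' @param state Numeric vector `c(CT, RTC, CPT, RTP)` (nM).
#' @param params A [structural_params()] object.
#' @param infusion_rate Zero-order drug input into the central compartment,
#'   nM/day (i.e. already divided by `V1` and converted to molar units).
#' @return Numeric vector of derivatives `d(CT, RTC, CPT, RTP)/dt` (nM/day).
#' @export
tmdd_rhs <- function(state, params, infusion_rate = 0) {
  stopifnot(inherits(params, "structural_params"), length(state) == 4L)
  CT <- state[1]; RTC <- state[2]; CPT <- state[3]; RTP <- state[4]
  C <- if (params$R0C > 0) qss_unbound(CT, RTC, params$KSSC) else CT
  CP <- if (params$R0P > 0) qss_unbound(CPT, RTP, params$KSSP) else CPT
  cplxC <- CT - C
  cplxP <- CPT - CP
  kinC <- params$R0C * params$kout
  kinP <- params$R0P * params$kout
  c(infusion_rate - (params$CL / params$V1) * C - (params$Q / params$V1) * C +
      (params$Q / params$V2) * CP - params$kintC * cplxC,
    kinC - params$kout * (RTC - cplxC) - params$kintC * cplxC,
    (params$Q / params$V1) * C - (params$Q / params$V2) * CP -
      params$kintP * cplxP,
    kinP - params$kout * (RTP - cplxP) - params$kintP * cplxP)
}

solver_control <- function(rtol = 1e-8, atol = 1e-10, maxstep = 5e6) {
  c(rtol, atol, maxstep)
}

# low-level batched solve: pars is an 11 x M matrix, returns either an
# nt x M matrix of unbound central concentration (nM) or an nt x 4 x M array
# of states
tmdd_solve <- function(pars, doses, times, mw, ctrl = solver_control(),
                       full = FALSE) {
  if (is.null(dim(pars))) pars <- matrix(pars, ncol = 1L)
  storage.mode(pars) <- "double"
  storage.mode(doses) <- "double"
  .Call(C_tmdd_solve, pars, doses, as.double(times), as.double(mw),
        as.double(ctrl), as.integer(full))
}

#' Simulate a concentration and target-kinetics profile
#'
#' Integrates the double-TMDD QSS system for one subject under a regimen of
#' zero-order infusions, starting from the drug-free equilibrium
#' `CT = CPT = 0`, `RTC = R0C`, `RTP = R0P`. Integration uses the package's
#' compiled adaptive Runge-Kutta solver with hard restarts at every infusion
#' start/stop, then recomputes all unbound quantities from the states at the
#' requested output times.
#'
#' @param params A [structural_params()] object.
#' @param regimen A [dose_events()] data frame.
#' @param times Output times (day), sorted, `>= 0`.
#' @param units A [unit_system()] used to express serum concentration in mg/L
#'   and convert the infusion input to nM/day.
#' @param rtol,atol Relative / absolute (nM) integration tolerances.
#' @return A data frame with columns `time_day`, `conc_mgL` (unbound central
#'   serum concentration), `C_nM`, `CT_nM`, `CP_nM`, `CPT_nM`, `RTC_nM`,
#'   `RTP_nM`, `RC_nM`, `RP_nM` (unbound target), and the occupancy ratios
#'   `ratio_C`, `ratio_P` (unbound/total target; `NA` where the arm is off).
#' @examples
#' p <- structural_params(V1 = 2.6, V2 = 1.9, CL = 0.16, Q = 1.8,
#'                        R0C = 3.3, KSSC = 15.4, kintC = 0.17,
#'                        R0P = 0.46, KSSP = 0.49, kintP = 0.0079)
#' reg <- dose_events(time = c(0, 14, 42) , amount = 330)
#' head(simulate_profile(p, reg, times = 0:56))
#' @export
simulate_profile <- function(params, regimen, times, units = unit_system(),
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "structural_params"))
  if (is.unsorted(times) || any(times < 0))
    stop("output times must be sorted and non-negative", call. = FALSE)
  st <- tmdd_solve(par_vector(params), dose_matrix(regimen), times,
                   units$mw, solver_control(rtol, atol), full = TRUE)
  CT <- st[, 1, 1]; RTC <- st[, 2, 1]; CPT <- st[, 3, 1]; RTP <- st[, 4, 1]
  C <- if (params$R0C > 0) qss_unbound(CT, RTC, params$KSSC) else CT
  CP <- if (params$R0P > 0) qss_unbound(CPT, RTP, params$KSSP) else CPT
  RC <- RTC - (CT - C)
  RP <- RTP - (CPT - CP)
  data.frame(
    time_day = times,
    conc_mgL = convert_concentration(C, units, from = "nM"),
    C_nM = C, CT_nM = CT, CP_nM = CP, CPT_nM = CPT,
    RTC_nM = RTC, RTP_nM = RTP, RC_nM = RC, RP_nM = RP,
    ratio_C = if (params$R0C > 0) RC / RTC else NA_real_,
    ratio_P = if (params$R0P > 0) RP / RTP else NA_real_
  )
}

#' Secondary (linear-phase) disposition parameters
#'
#' Micro-rate constants and half-lives of the linear two-compartment system,
#' computed from the non-target-mediated parameters only. `T1/2-beta` is the
#' endogenous (terminal) elimination half-life.
#'
#' @param V1,V2 Central and peripheral volumes (L).
#' @param CL,Q Systemic and intercompartmental clearances (L/day).
#' @return An object of class `secondary_params`: `k10`, `k12`, `k21`
#'   (1/day), `alpha`, `beta` (1/day) and `t_half_alpha`, `t_half_beta`
#'   (day), with `t_half_alpha <= t_half_beta`.
#' @examples
#' terminal_half_life(V1 = 2.8, V2 = 1.9, CL = 0.20, Q = 1.5)$t_half_beta
#' @export
terminal_half_life <- function(V1, V2, CL, Q) {
  stopifnot(V1 > 0, V2 > 0, CL > 0, Q > 0)
  k10 <- CL / V1; k12 <- Q / V1; k21 <- Q / V2
  s <- k10 + k12 + k21
  d <- sqrt(s^2 - 4 * k10 * k21)
  alpha <- (s + d) / 2
  beta <- (s - d) / 2
  structure(list(k10 = k10, k12 = k12, k21 = k21,
                 alpha = alpha, beta = beta,
                 t_half_alpha = log(2) / alpha,
                 t_half_beta = log(2) / beta),
            class = "secondary_params")
}

#' @export
print.secondary_params <- function(x, ...) {
  cat(sprintf("<secondary_params> T1/2-alpha = %.3g d, T1/2-beta = %.3g d\n",
              x$t_half_alpha, x$t_half_beta))
  cat(sprintf("  k10 = %.4g, k12 = %.4g, k21 = %.4g (1/day)\n",
              x$k10, x$k12, x$k21))
  invisible(x)
}

#' Exact linear two-compartment concentrations under infusion dosing
#'
#' Closed-form (piecewise matrix-exponential) solution of the linear
#' two-compartment model in the k12/k21 concentration convention, by
#' superposition of step responses over the infusion events. Used internally
#' as a fast exact predictor for subjects with both TMDD arms off; exposed
#' because it is the reference the ODE path is checked against.
#'
#' @param times Output times (day), `>= 0`.
#' @param regimen A [dose_events()] data frame.
#' @param V1,V2,CL,Q Linear disposition parameters.
#' @return Numeric vector of central concentrations (mg/L) at `times`.
#' @export
linear_2cpt_conc <- function(times, regimen, V1, V2, CL, Q) {
  sec <- terminal_half_life(V1, V2, CL, Q)
  lam <- c(-sec$alpha, -sec$beta)
  # M = [[-(k10+k12), k21], [k12, -k21]] = S diag(lam) S^-1
  M <- matrix(c(-(sec$k10 + sec$k12), sec$k12, sec$k21, -sec$k21), 2, 2)
  eg <- eigen(M)
  S <- eg$vectors
  lam <- eg$values
  Sinv <- solve(S)
  out <- numeric(length(times))
  phi <- function(l, tau) {
    if (abs(l) < 1e-12) tau else (exp(l * tau) - 1) / l
  }
  for (k in seq_len(nrow(regimen))) {
    u <- Sinv %*% c(regimen$rate[k] / V1, 0)
    t_on <- pmax(times - regimen$time[k], 0)
    t_off <- pmax(times - regimen$time[k] - regimen$duration[k], 0)
    g <- S[1, 1] * u[1] * (phi(lam[1], t_on) - phi(lam[1], t_off)) +
      S[1, 2] * u[2] * (phi(lam[2], t_on) - phi(lam[2], t_off))
    out <- out + g
  }
  out
}
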