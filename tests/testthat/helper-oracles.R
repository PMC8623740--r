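# Independent oracles used across the suite. Each reimplements the quantity
# it checks by a different route than the package code.

# unbound concentration under QSS by bisection on the monotone mass balance
# C + RT * C / (KSS + C) = CT (independent of the quadratic-root formula)
qss_bisect <- function(ct, rt, kss, tol = 1e-14) {
  if (ct == 0) return(0)
  h <- function(C) C + rt * C / (kss + C) - ct
  lo <- 0; hi <- ct
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (h(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol * max(1, ct)) break
  }
  (lo + hi) / 2
}

# independent stiff integration of the double-TMDD system with deSolve::lsoda
# and an R-coded right-hand side, restarting at infusion boundaries
oracle_profile <- function(params, regimen, times, mw = 149000,
                           rtol = 1e-10, atol = 1e-12) {
  rhs <- function(t, y, p) {
    C <- dtmdd::qss_unbound(y[1], y[2], max(p$KSSC, 1e-300))
    if (p$R0C == 0) C <- y[1]
    CP <- dtmdd::qss_unbound(y[3], y[4], max(p$KSSP, 1e-300))
    if (p$R0P == 0) CP <- y[3]
    list(c(
      p$inrate - (p$CL / p$V1) * C - (p$Q / p$V1) * C +
        (p$Q / p$V2) * CP - p$kintC * (y[1] - C),
      p$R0C * p$kout - p$kout * (y[2] - (y[1] - C)) - p$kintC * (y[1] - C),
      (p$Q / p$V1) * C - (p$Q / p$V2) * CP - p$kintP * (y[3] - CP),
      p$R0P * p$kout - p$kout * (y[4] - (y[3] - CP)) - p$kintP * (y[3] - CP)
    ))
  }
  bounds <- sort(unique(c(0, regimen$time, regimen$time + regimen$duration,
                          times)))
  y <- c(0, params$R0C, 0, params$R0P)
  out <- matrix(NA_real_, length(times), 4)
  if (any(times <= 1e-12)) out[times <= 1e-12, ] <- rep(y, each = sum(times <= 1e-12))
  p <- params
  for (k in seq_len(length(bounds) - 1)) {
    t0 <- bounds[k]; t1 <- bounds[k + 1]
    if (t1 <= t0) next
    tm <- (t0 + t1) / 2
    act <- tm >= regimen$time & tm < regimen$time + regimen$duration
    p$inrate <- sum(regimen$rate[act]) * 1e6 / (mw * params$V1)
    seg <- deSolve::lsoda(y, c(t0, t1), rhs, p, rtol = rtol, atol = atol)
    y <- pmax(as.numeric(seg[nrow(seg), -1]), 0)
    sel <- abs(times - t1) <= 1e-12
    if (any(sel)) out[sel, ] <- rep(y, each = sum(sel))
  }
  colnames(out) <- c("CT", "RTC", "CPT", "RTP")
  out
}

# independent closed-form central concentration of the linear two-compartment
# model (textbook macro-constant superposition form)
biexp_conc <- function(times, regimen, V1, V2, CL, Q) {
  k10 <- CL / V1; k12 <- Q / V1; k21 <- Q / V2
  s <- k10 + k12 + k21
  d <- sqrt(s^2 - 4 * k10 * k21)
  a <- (s + d) / 2; b <- (s - d) / 2
  A <- (k21 - a) / (b - a)
  B <- (k21 - b) / (a - b)
  step_on <- function(tau, R) {
    tau <- pmax(tau, 0)
    (R / V1) * (A * (1 - exp(-a * tau)) / a + B * (1 - exp(-b * tau)) / b)
  }
  out <- numeric(length(times))
  for (k in seq_len(nrow(regimen))) {
    out <- out + step_on(times - regimen$time[k], regimen$rate[k]) -
      step_on(times - regimen$time[k] - regimen$duration[k], regimen$rate[k])
  }
  out
}

# brute-force plain Monte-Carlo -2LL for linear-kinetics subjects with
# exponential IIV on V1, CL, V2 (vectorised over draws)
mc_neg2ll_linear <- function(dataset, pop, n_draws = 30000, seed = 99) {
  dat <- if (inherits(dataset, "study_dataset")) dataset$data else dataset
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  tot <- 0; var_tot <- 0
  for (id in unique(dat$ID)) {
    d <- dat[dat$ID == id, ]
    dose <- d[d$EVID == 1, ]
    obs <- d[d$EVID == 0 & d$CENS == 0, ]
    reg <- data.frame(time = dose$TIME, duration = dose$AMT / dose$RATE,
                      rate = dose$RATE)
    th <- pop$theta
    om <- pop$omega
    eV1 <- exp(stats::rnorm(n_draws, 0, om[["V1"]]))
    eCL <- exp(stats::rnorm(n_draws, 0, om[["CL"]]))
    eV2 <- exp(stats::rnorm(n_draws, 0, om[["V2"]]))
    ll_draw <- vapply(seq_len(n_draws), function(s) {
      f <- biexp_conc(obs$TIME, reg, th[["V1"]] * eV1[s],
                      th[["V2"]] * eV2[s], th[["CL"]] * eCL[s], th[["Q"]])
      sdv <- pop$sigma[["add"]] + pop$sigma[["prop"]] * pmax(f, 0)
      sum(stats::dnorm(obs$DV, f, sdv, log = TRUE))
    }, 1)
    mx <- max(ll_draw)
    w <- exp(ll_draw - mx)
    tot <- tot + (-2) * (mx + log(mean(w)))
    var_tot <- var_tot + (2 * stats::sd(w) / (sqrt(n_draws) * mean(w)))^2
  }
  structure(tot, mcse = sqrt(var_tot))
}

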