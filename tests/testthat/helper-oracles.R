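# Independent numerical oracles used by the tests. These deliberately do not
# share code with the package internals they check.

# Closed-form amount in the final compartment of a linear cascade
# S -k1-> I -k2-> E -k3-> C -ke-> out (all rates distinct), unit bolus in S
# at t = 0 scaled by `dose`.
bateman_central <- function(t, dose, k1, k2, k3, ke) {
  lam <- c(k1, k2, k3, ke)
  stopifnot(length(unique(lam)) == 4L)
  acc <- 0
  for (i in 1:4) {
    denom <- prod(lam[-i] - lam[i])
    acc <- acc + exp(-lam[i] * t) / denom
  }
  dose * k1 * k2 * k3 * acc
}

# Method-of-steps reference for the delayed model: integrates segment by
# segment with a plain (non-delay) ODE solver, feeding the conversion term
# from a spline interpolant of the already-computed history. Returns a data
# frame with time and all six compartment amounts.
mos_simulate <- function(params, dose_nmol, t_end, dt = 0.002) {
  Tdel <- params$T
  stopifnot(Tdel > 0)
  eps_conv <- 1e-4 * dose_nmol
  rhs <- function(t, y, p, hist_fun) {
    vsg <- if (p$valve == "constant") p$a else
      p$a * (1 + sin(2 * pi * t / p$b)) / 2
    f <- if (y[4] <= 0) 0 else min(1, y[4] / eps_conv)
    conv <- p$k_m * hist_fun(t - Tdel) * f
    dS <- -vsg * y[1]
    dI <- vsg * y[1] - (p$k_int_ent + p$k_int_ex) * y[2] +
      p$k_ent_int * y[3]
    dE <- p$k_int_ent * y[2] - (p$k_ent_int + p$k_ent_cc) * y[3]
    dC <- p$k_ent_cc * y[3] - conv -
      (p$CL_p / p$Vp_1) * y[4] - (p$Q / p$Vp_1) * y[4] +
      (p$Q / p$Vp_2) * y[5]
    dP <- (p$Q / p$Vp_1) * y[4] - (p$Q / p$Vp_2) * y[5]
    dM <- conv - (p$CL_m / p$Vm) * y[6]
    list(c(dS, dI, dE, dC, dP, dM))
  }
  y <- c(dose_nmol, 0, 0, 0, 0, 0)
  hist_t <- 0
  hist_A <- 0  # central losartan history
  out <- NULL
  s <- 0
  while (s < t_end - 1e-12) {
    e <- min(s + Tdel, t_end)
    seg_times <- unique(c(seq(s, e, by = dt), e))
    hfun <- if (length(hist_t) > 3L) {
      f <- stats::splinefun(hist_t, hist_A, method = "natural")
      function(tt) if (tt <= 0) 0 else f(tt)
    } else {
      function(tt) 0
    }
    sol <- deSolve::ode(y = y, times = seg_times, func = rhs,
                        parms = params, hist_fun = hfun,
                        rtol = 1e-10, atol = 1e-12)
    sol <- unclass(sol)
    y <- sol[nrow(sol), -1]
    keep <- if (is.null(out)) sol else sol[-1, , drop = FALSE]
    out <- rbind(out, keep)
    hist_t <- out[, 1]
    hist_A <- out[, 5]  # column 5 = central losartan (time is col 1)
    s <- e
  }
  colnames(out) <- c("time", "stomach", "intestine", "enterocyte",
                     "central_losartan", "peripheral_losartan",
                     "central_E3174")
  as.data.frame(out)
}

# relative sup-norm disagreement, scaled by the larger curve's sup norm
rel_disagreement <- function(a, b) {
  max(abs(a - b)) / max(max(abs(a)), max(abs(b)), .Machine$double.eps)
}

# a conc_series from closed-form concentration functions on a grid
series_from_funs <- function(times, fp, fm = function(t) rep(0, length(t))) {
  conc_series(times, fp(times), fm(times))
}
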