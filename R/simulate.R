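#' Gastric pyloric valve emptying rate
#'
#' The stomach empties through periodic open-close cycles of the pyloric
#' valve, modelled as a nonnegative sinusoid `a*(1 + sin(2*pi*t/b))/2`:
#' amplitude `a` bounds the rate, `b` is the cycle period, and the mean rate
#' over one period is `a/2`. The `"constant"` form returns the fixed rate
#' `a` (useful for closed-form reductions of the model).
#'
#' @param t Time (h, >= 0); vectorized.
#' @param a Amplitude (1/h, > 0).
#' @param b Period (h, > 0).
#' @param form `"sinusoidal"` (default) or `"constant"`.
#' @return Emptying rate(s) in 1/h, in `[0, a]`.
#' @export
#' @examples
#' gastric_valve_rate(c(0, 0.25, 0.5), a = 1.5, b = 1)
gastric_valve_rate <- function(t, a, b, form = c("sinusoidal", "constant")) {
  form <- match.arg(form)
  if (!is.numeric(a) || a <= 0) stop("'a' must be > 0", call. = FALSE)
  if (!is.numeric(b) || b <= 0) stop("'b' must be > 0", call. = FALSE)
  if (any(t < 0)) stop("'t' must be nonnegative", call. = FALSE)
  if (form == "constant") return(rep_len(a, length(t)))
  a * (1 + sin(2 * pi * t / b)) / 2
}

# State indexing for the augmented system
STATE_NAMES <- c("stomach", "intestine", "enterocyte", "central_losartan",
                 "peripheral_losartan", "central_E3174", "AUC_p", "AUC_m")

# pack a losartan_params object into the flat vector the compiled right-hand
# side expects (order fixed; see src/losartan_model.c)
pack_parms <- function(params, t0, eps_conv) {
  c(params$a, params$b, params$k_int_ent, params$k_ent_int,
    params$k_ent_cc, params$k_m, params$T, params$CL_m, params$Vm,
    params$CL_p, params$Vp_1, params$Q, params$Vp_2, params$k_int_ex,
    as.numeric(params$valve == "constant"), t0, eps_conv)
}

#' Simulate the five-compartment losartan/E-3174 model
#'
#' Integrates the delayed mass-balance system: an oral dose enters the
#' stomach at the administration time (initial assignment), empties into the
#' intestine through the periodic pyloric valve, is absorbed into
#' enterocytes where ABCB1 effluxes part of it back into the lumen, reaches
#' the central compartment, distributes to a peripheral compartment, and is
#' converted to E-3174 by CYP2C9 after a fixed time delay `T`: the
#' conversion rate at time `t` is `k_m * A_cc(t - T)` (zero for `t < T`,
#' with zero pre-dose history), applied symmetrically as a loss from central
#' losartan and a gain to central E-3174 so that total drug mass is
#' conserved. Plasma concentrations are algebraic assignments
#' amount/volume (nM). Exposure integrals `dAUC/dt = C` are carried as
#' auxiliary states for both analytes.
#'
#' @param params A [losartan_params()] object.
#' @param dose A [dose_regimen()] object or a dose in mg.
#' @param t_end Simulation horizon (h, > 0); default 24.
#' @param output_step Dense output step (h); default 0.01, fine enough for
#'   extremum detection.
#' @param rtol,atol Solver tolerances (defaults 1e-8, 1e-10).
#' @param genotype_label Optional label carried through to the result.
#' @param times Optional explicit output times (h, strictly increasing,
#'   overriding `t_end`/`output_step`); used e.g. to evaluate the model only
#'   at observation times during fitting.
#' @return An object of class `conc_series`: a data frame with columns
#'   `time_h`, `C_p_nM` (losartan), `C_m_nM` (E-3174), with the compartment
#'   amount matrix, cumulative AUCs, parameters and dose attached as
#'   attributes.
#' @export
#' @examples
#' sim <- simulate_losartan(losartan_params(), 50, t_end = 12,
#'                          output_step = 0.05)
#' head(sim)
simulate_losartan <- function(params, dose, t_end = 24, output_step = 0.01,
                              rtol = 1e-8, atol = 1e-10,
                              genotype_label = NULL, times = NULL) {
  stopifnot(inherits(params, "losartan_params"))
  if (is.numeric(dose)) dose <- dose_regimen(dose)
  stopifnot(inherits(dose, "dose_regimen"))
  if (is.null(times)) {
    if (!is.numeric(t_end) || t_end <= 0) stop("t_end must be > 0",
                                               call. = FALSE)
    times_out <- seq(0, t_end, by = output_step)
    if (times_out[length(times_out)] < t_end)
      times_out <- c(times_out, t_end)
  } else {
    if (any(diff(times) <= 0) || any(times < 0))
      stop("'times' must be nonnegative and strictly increasing",
           call. = FALSE)
    times_out <- times
    t_end <- max(times)
  }
  t0 <- dose$administration_time
  if (t0 >= t_end)
    stop("administration_time must precede t_end", call. = FALSE)

  amount <- dose_to_amount(dose)
  y0 <- c(amount, 0, 0, 0, 0, 0, 0, 0)
  names(y0) <- STATE_NAMES
  solve_times <- unique(c(t0, times_out[times_out >= t0]))

  if (amount == 0) {
    out <- cbind(time = times_out,
                 matrix(0, length(times_out), 8,
                        dimnames = list(NULL, STATE_NAMES)))
  } else {
    # substrate scale of the delayed-conversion shutoff: the delayed flux
    # k_m * A_cc(t - T) is damped linearly once the central amount falls
    # below 1e-4 of the dose, so that a steeply declining substrate cannot
    # be overdrawn; above that level the flux is the pure delayed form
    pv <- pack_parms(params, t0, eps_conv = 1e-4 * amount)
    sol <- if (params$T > 0 && params$k_m > 0) {
      deSolve::dede(y = y0, times = solve_times,
                    func = "derivs_losartan", dllname = "losartanpkpd",
                    initfunc = "init_losartan", parms = pv,
                    rtol = rtol, atol = atol)
    } else {
      # no delayed term active: plain ODE system
      deSolve::ode(y = y0, times = solve_times,
                   func = "derivs_losartan", dllname = "losartanpkpd",
                   initfunc = "init_losartan", parms = pv,
                   rtol = rtol, atol = atol, method = "lsoda")
    }
    if (attr(sol, "istate")[1L] < 0)
      stop("integration failed (solver istate ",
           attr(sol, "istate")[1L], "); check parameters/tolerances",
           call. = FALSE)
    sol <- unclass(sol)
    # drop duplicated t0 row if it was inserted
    sol <- sol[match(times_out[times_out >= t0], sol[, 1L]), , drop = FALSE]
    pre <- times_out[times_out < t0]
    if (length(pre)) {
      sol <- rbind(cbind(pre, matrix(0, length(pre), 8)), sol)
    }
    out <- sol
    colnames(out) <- c("time", STATE_NAMES)
    states <- out[, 2:7, drop = FALSE]
    worst <- min(states)
    if (worst < -100 * atol * max(1, amount))
      stop("negative compartment amount beyond tolerance (min = ",
           format(worst), "); integration unreliable", call. = FALSE)
    out[, 2:9][out[, 2:9] < 0] <- 0
  }

  res <- data.frame(time_h = out[, "time"],
                    C_p_nM = out[, "central_losartan"] / params$Vp_1,
                    C_m_nM = out[, "central_E3174"] / params$Vm)
  structure(res,
            class = c("conc_series", "data.frame"),
            amounts = out[, STATE_NAMES[1:6], drop = FALSE],
            auc = data.frame(time_h = out[, "time"],
                             AUC_p = out[, "AUC_p"],
                             AUC_m = out[, "AUC_m"]),
            params = params,
            dose_mg = dose$dose_mg,
            genotype_label = genotype_label)
}

#' Construct a concentration-time series
#'
#' Container for (possibly observed) losartan/E-3174 plasma concentration
#' curves on a strictly increasing time grid.
#'
#' @param times Time grid (h), strictly increasing, nonnegative.
#' @param C_p Losartan plasma concentration (nM), same length.
#' @param C_m E-3174 plasma concentration (nM), same length.
#' @param genotype_label Optional label.
#' @param dose_mg Optional dose (mg).
#' @return A `conc_series` object.
#' @export
conc_series <- function(times, C_p, C_m, genotype_label = NULL,
                        dose_mg = NA_real_) {
  if (length(times) == 0L) stop("empty series", call. = FALSE)
  if (length(times) != length(C_p) || length(times) != length(C_m))
    stop("times, C_p and C_m must have equal length", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(times < 0)) stop("times must be nonnegative", call. = FALSE)
  if (any(C_p < 0) || any(C_m < 0))
    stop("concentrations must be nonnegative", call. = FALSE)
  structure(data.frame(time_h = times, C_p_nM = C_p, C_m_nM = C_m),
            class = c("conc_series", "data.frame"),
            genotype_label = genotype_label, dose_mg = dose_mg)
}

#' @export
print.conc_series <- function(x, ...) {
  g <- attr(x, "genotype_label")
  d <- attr(x, "dose_mg")
  cat(sprintf("Concentration-time series: %d points, %g-%g h%s%s\n",
              nrow(x), min(x$time_h), max(x$time_h),
              if (!is.null(g)) paste0(", genotype ", g) else "",
              if (!is.null(d) && !is.na(d)) paste0(", dose ", d, " mg")
              else ""))
  print.data.frame(utils::head(as.data.frame(x)))
  if (nrow(x) > 6L) cat("  ...\n")
  invisible(x)
}

#' @export
plot.conc_series <- function(x, log = "", ...) {
  graphics::matplot(x$time_h, cbind(x$C_p_nM, x$C_m_nM), type = "l",
                    lty = 1, col = c("steelblue", "darkorange"),
                    xlab = "time (h)", ylab = "concentration (nM)",
                    log = log, ...)
  graphics::legend("topright", c("losartan", "E-3174"), lty = 1,
                   col = c("steelblue", "darkorange"), bty = "n")
  invisible(x)
}

#' Read and write concentration curves as CSV
#'
#' The file format is a plain CSV with header `time_h,C_p_nM,C_m_nM`.
#'
#' @param series A `conc_series` object.
#' @param path File path.
#' @return `read_series()` returns a `conc_series`; `write_series()` returns
#'   `path` invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "conc_series"))
  utils::write.csv(as.data.frame(series)[c("time_h", "C_p_nM", "C_m_nM")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time_h", "C_p_nM", "C_m_nM")
  if (!all(need %in% names(d)))
    stop("curve CSV must have header time_h,C_p_nM,C_m_nM", call. = FALSE)
  conc_series(d$time_h, d$C_p_nM, d$C_m_nM)
}
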