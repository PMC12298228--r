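analyte_column <- function(analyte = c("losartan", "E3174")) {
  analyte <- match.arg(analyte)
  if (analyte == "losartan") "C_p_nM" else "C_m_nM"
}

#' Maximum concentration and its time
#'
#' The maximum concentration on the (dense) grid and the earliest time
#' attaining it.
#'
#' @param series A `conc_series`.
#' @param analyte `"losartan"` or `"E3174"`.
#' @return Named numeric vector `c(C_max, t_max)`.
#' @export
cmax_tmax <- function(series, analyte = c("losartan", "E3174")) {
  stopifnot(inherits(series, "conc_series"))
  if (nrow(series) == 0L) stop("empty series", call. = FALSE)
  conc <- series[[analyte_column(analyte)]]
  i <- which.max(conc)  # earliest index attaining the max
  c(C_max = conc[i], t_max = series$time_h[i])
}

# cumulative trapezoid of conc over time, evaluated at the grid points
cum_trapz <- function(t, y) {
  c(0, cumsum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
}

# cumulative AUC function (h -> nmol.h/L): uses the integrated auxiliary
# state when the series was simulated, else the trapezoid on the grid;
# interpolates between grid points with a monotone spline.
cum_auc_fun <- function(series, analyte) {
  aucattr <- attr(series, "auc")
  col <- if (analyte == "losartan") "AUC_p" else "AUC_m"
  if (!is.null(aucattr)) {
    stats::splinefun(aucattr$time_h, aucattr[[col]], method = "hyman")
  } else {
    conc <- series[[analyte_column(analyte)]]
    stats::splinefun(series$time_h, cum_trapz(series$time_h, conc),
                     method = "hyman")
  }
}

#' Area under the concentration-time curve to "infinity"
#'
#' The exposure integral `dAUC/dt = C` evaluated at the horizon. For a
#' simulated series the integral is carried as an auxiliary state of the
#' solver; for an observed series a trapezoid on the stored grid is used.
#' The default horizon is the end of the series; an explicit `horizon`
#' beyond the last point is an error. When `check_convergence = TRUE`, the
#' relative contribution of the last 20% of the window must be below `tol`,
#' otherwise a warning flags a truncated integral.
#'
#' @param series A `conc_series`.
#' @param analyte `"losartan"` or `"E3174"`.
#' @param horizon Upper limit (h); default last observed time.
#' @param check_convergence Warn if the tail still contributes; default
#'   FALSE.
#' @param tol Relative tail-contribution tolerance (default 1e-3).
#' @return AUC in nmol·h/L.
#' @export
auc_0_inf <- function(series, analyte = c("losartan", "E3174"),
                      horizon = NULL, check_convergence = FALSE,
                      tol = 1e-3) {
  stopifnot(inherits(series, "conc_series"))
  analyte <- match.arg(analyte)
  t_last <- max(series$time_h)
  if (is.null(horizon)) horizon <- t_last
  if (horizon > t_last + 1e-9)
    stop("horizon (", horizon, " h) exceeds the last observation (",
         t_last, " h)", call. = FALSE)
  f <- cum_auc_fun(series, analyte)
  val <- f(horizon)
  if (check_convergence && val > 0) {
    tail_frac <- (val - f(0.8 * horizon)) / val
    if (tail_frac > tol)
      warning("AUC not converged at horizon ", horizon,
              " h (last 20% contributes ",
              format(100 * tail_frac, digits = 3), "%)", call. = FALSE)
  }
  val
}

#' Partial area under the curve between two times
#'
#' Computed per the piecewise construction as the difference of two clipped
#' integrals, `AUC(0, y) - AUC(0, x)`.
#'
#' @param series A `conc_series`.
#' @param x,y Window bounds (h), `0 <= x <= y <=` horizon.
#' @param analyte `"losartan"` or `"E3174"`.
#' @return AUC over `[x, y]` in nmol·h/L.
#' @export
auc_x_y <- function(series, x, y, analyte = c("losartan", "E3174")) {
  stopifnot(inherits(series, "conc_series"))
  analyte <- match.arg(analyte)
  if (x < 0 || y < 0) stop("window bounds must be nonnegative",
                           call. = FALSE)
  if (x > y) stop("lower bound x exceeds upper bound y", call. = FALSE)
  t_last <- max(series$time_h)
  if (y > t_last + 1e-9)
    stop("upper bound y exceeds the series horizon", call. = FALSE)
  f <- cum_auc_fun(series, analyte)
  f(y) - f(x)
}

#' Terminal half-life by semilogarithmic regression
#'
#' Ordinary least squares through `(t, log C)` at the fixed anchor times
#' (default 6, 8 and 10 h); the half-life is `log(2)` divided by the
#' negated slope, equivalently the two-point form
#' `t_half = (t2 - t1) * log(2) / log(C1/C2)` evaluated on the fitted
#' regression line. Concentrations are interpolated to the anchor times
#' with a cubic spline when the grid does not contain them.
#'
#' @param series A `conc_series`.
#' @param analyte `"losartan"` or `"E3174"`.
#' @param anchors Anchor times (h); default `c(6, 8, 10)`.
#' @return Terminal half-life (h).
#' @export
half_life_semilog <- function(series, analyte = c("losartan", "E3174"),
                              anchors = c(6, 8, 10)) {
  stopifnot(inherits(series, "conc_series"))
  analyte <- match.arg(analyte)
  if (length(anchors) < 2L) stop("need at least two anchor times",
                                 call. = FALSE)
  if (max(anchors) > max(series$time_h) || min(anchors) < min(series$time_h))
    stop("anchor times outside the observed window", call. = FALSE)
  conc <- series[[analyte_column(analyte)]]
  ci <- if (all(anchors %in% series$time_h)) {
    conc[match(anchors, series$time_h)]
  } else {
    stats::spline(series$time_h, conc, xout = anchors)$y
  }
  if (any(ci <= 0))
    stop("nonpositive concentration at an anchor time; cannot take logs",
         call. = FALSE)
  slope <- stats::coef(stats::lm(log(ci) ~ anchors))[[2L]]
  if (slope >= -1e-12)
    stop("no terminal decline: fitted semilog slope is nonnegative",
         call. = FALSE)
  log(2) / (-slope)
}

#' Apparent oral clearance
#'
#' `CL/F = dose_mg * 1e6 / (AUC * 461.01)`, with a piecewise zero branch
#' when plasma losartan is identically zero (pre-absorption): the
#' clearance is reported as 0 rather than dividing by a zero AUC.
#'
#' @param dose A [dose_regimen()] or dose in mg.
#' @param auc_losartan Losartan `AUC_0_inf` (nmol·h/L, >= 0).
#' @return CL/F in L/h.
#' @export
#' @examples
#' cl_over_f(50, 1349.1)  # ~80.4 L/h
cl_over_f <- function(dose, auc_losartan) {
  if (is.numeric(dose)) dose <- dose_regimen(dose)
  stopifnot(inherits(dose, "dose_regimen"))
  if (!is.numeric(auc_losartan) || length(auc_losartan) != 1L ||
      auc_losartan < 0)
    stop("auc_losartan must be a single nonnegative number", call. = FALSE)
  if (auc_losartan == 0) return(0)
  dose$dose_mg * 1e6 / (auc_losartan * dose$molecular_weight)
}

#' Euclidean distance between two sampled curves
#'
#' `D = sqrt(sum_i (c_i^A - c_i^B)^2)` over the time points common to both
#' series, per analyte or stacked over both analytes.
#'
#' @param curve_a,curve_b `conc_series` objects.
#' @param analyte `"losartan"`, `"E3174"`, or `"both"` (default: residuals
#'   of both analytes stacked).
#' @return Distance D (nM).
#' @export
curve_distance <- function(curve_a, curve_b,
                           analyte = c("both", "losartan", "E3174")) {
  stopifnot(inherits(curve_a, "conc_series"),
            inherits(curve_b, "conc_series"))
  analyte <- match.arg(analyte)
  common <- intersect(curve_a$time_h, curve_b$time_h)
  if (length(common) == 0L)
    stop("curves share no common time points", call. = FALSE)
  ia <- match(common, curve_a$time_h)
  ib <- match(common, curve_b$time_h)
  cols <- switch(analyte, both = c("C_p_nM", "C_m_nM"),
                 losartan = "C_p_nM", E3174 = "C_m_nM")
  d2 <- 0
  for (col in cols)
    d2 <- d2 + sum((curve_a[[col]][ia] - curve_b[[col]][ib])^2)
  sqrt(d2)
}

#' Pharmacokinetic summary of a concentration-time curve
#'
#' Computes, per analyte, `C_max`, `t_max`, the terminal half-life from the
#' fixed semilog anchors, and `AUC_0_inf` at the horizon; for losartan also
#' the apparent oral clearance CL/F.
#'
#' @param series A `conc_series`.
#' @param dose A [dose_regimen()] or dose in mg; defaults to the dose
#'   recorded on the series.
#' @param horizon AUC horizon (h); default the series horizon.
#' @param half_life Logical; compute terminal half-lives (needs positive
#'   concentrations at the 6/8/10 h anchors). Default TRUE.
#' @param windows Optional list of `c(x, y)` pairs for partial AUCs.
#' @return An object of class `pk_summary` (a one-row data frame with
#'   analyte-suffixed columns such as `Cmax_losartan_nM`,
#'   `AUC0inf_E3174_nmolh_L`).
#' @export
#' @examples
#' sim <- simulate_losartan(losartan_params(), 50, t_end = 24,
#'                          output_step = 0.02)
#' pk_summary(sim)
pk_summary <- function(series, dose = attr(series, "dose_mg"),
                       horizon = NULL, half_life = TRUE, windows = NULL) {
  stopifnot(inherits(series, "conc_series"))
  if (is.null(dose) || (is.numeric(dose) && is.na(dose)))
    stop("dose unknown: pass 'dose'", call. = FALSE)
  if (is.numeric(dose)) dose <- dose_regimen(dose)
  out <- list()
  for (an in c("losartan", "E3174")) {
    cm <- cmax_tmax(series, an)
    out[[paste0("Cmax_", an, "_nM")]] <- unname(cm["C_max"])
    out[[paste0("tmax_", an, "_h")]] <- unname(cm["t_max"])
    if (half_life)
      out[[paste0("thalf_", an, "_h")]] <- half_life_semilog(series, an)
    out[[paste0("AUC0inf_", an, "_nmolh_L")]] <-
      auc_0_inf(series, an, horizon = horizon)
    if (!is.null(windows)) {
      for (w in windows)
        out[[sprintf("AUC%g_%g_%s_nmolh_L", w[1], w[2], an)]] <-
          auc_x_y(series, w[1], w[2], an)
    }
  }
  out[["CLF_L_h"]] <- cl_over_f(dose, out[["AUC0inf_losartan_nmolh_L"]])
  res <- as.data.frame(out)
  class(res) <- c("pk_summary", "data.frame")
  attr(res, "genotype_label") <- attr(series, "genotype_label")
  res
}

#' @export
print.pk_summary <- function(x, ...) {
  g <- attr(x, "genotype_label")
  cat("PK summary", if (!is.null(g)) paste0("(", g, ")") else "", "\n")
  for (an in c("losartan", "E3174")) {
    cat(sprintf("  %-8s Cmax %8.1f nM at %5.2f h", an,
                x[[paste0("Cmax_", an, "_nM")]],
                x[[paste0("tmax_", an, "_h")]]))
    th <- x[[paste0("thalf_", an, "_h")]]
    if (!is.null(th)) cat(sprintf(", t1/2 %5.2f h", th))
    cat(sprintf(", AUC0-inf %9.1f nmol.h/L\n",
                x[[paste0("AUC0inf_", an, "_nmolh_L")]]))
  }
  cat(sprintf("  CL/F %8.2f L/h\n", x$CLF_L_h))
  invisible(x)
}
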