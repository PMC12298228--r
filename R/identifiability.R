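#' Profile a fitted parameter for identifiability
#'
#' Excludes one fitted parameter from the optimization, fixes it at a grid
#' of values that first increase and then decrease relative to the
#' optimum, re-optimizes all remaining fitted parameters at each value, and
#' records the objective. A parameter is classified `"identifiable"` when
#' the re-optimized objective rises significantly on both sides of the
#' optimum, `"partially identifiable"` when it rises on one side only, and
#' `"unidentifiable"` when it rises on neither.
#'
#' The significance threshold is a relative increase over the fitted loss
#' (`threshold`, default 5%), with an absolute floor (`abs_floor`) so that
#' near-zero noise-free losses do not make every flat direction look
#' significant. By default the floor is scaled to the numerical noise of
#' the objective (the solver's relative tolerance times the data scale),
#' because re-simulated losses fluctuate at that level even along
#' perfectly flat directions.
#'
#' @param fit A [losartan_fit()] object.
#' @param parameter Name of a fitted parameter (e.g. `"k_m|GG/CC"` or a
#'   shared name).
#' @param values Scan values (natural scale). Default: a geometric grid of
#'   `n` points spanning `span` times the fitted value. Must bracket the
#'   optimum.
#' @param n,span Grid size and multiplicative range (defaults 9 and
#'   `c(0.25, 4)`).
#' @param threshold Relative loss-increase threshold (default 0.05).
#' @param abs_floor Absolute loss-increase floor; default `NULL` scales it
#'   to the objective's numerical noise.
#' @param reoptimize Re-optimize the remaining parameters at each scan
#'   value (default TRUE; FALSE gives a fixed-slice profile).
#' @return An object of class `identifiability_profile`: a list with the
#'   profile data frame (`value`, `loss`), the classification, and the
#'   fitted reference point.
#' @export
identifiability_profile <- function(fit, parameter, values = NULL,
                                    n = 9, span = c(0.25, 4),
                                    threshold = 0.05, abs_floor = NULL,
                                    reoptimize = TRUE) {
  stopifnot(inherits(fit, "losartan_fit"))
  fitted_names <- names(fit$coefficients)
  if (!parameter %in% fitted_names)
    stop("'", parameter, "' is not among the fitted parameters",
         call. = FALSE)
  opt_val <- fit$coefficients[[parameter]]
  if (is.null(values))
    values <- opt_val * exp(seq(log(span[1L]), log(span[2L]),
                                length.out = n))
  if (min(values) >= opt_val || max(values) <= opt_val)
    stop("scan grid does not bracket the fitted optimum", call. = FALSE)

  others <- setdiff(fitted_names, parameter)
  genotypes <- names(fit$params_by_genotype)
  shared <- fit$shared
  local <- fit$local
  base <- sub("\\|.*$", "", parameter)

  obj_at <- function(fix_value, other_log) {
    theta <- stats::setNames(as.list(exp(other_log)), others)
    theta[[parameter]] <- fix_value
    # a fixed local parameter must stay local: rebuild per-genotype params
    pars <- fit$start
    for (g in genotypes) {
      p <- pars[[g]]
      for (nm in shared)
        p[[nm]] <- if (nm == parameter) fix_value else theta[[nm]]
      for (nm in local) {
        key <- paste0(nm, "|", g)
        p[[nm]] <- if (key == parameter) fix_value else theta[[key]]
      }
      validate_params(p)
      class(p) <- "losartan_params"
      pars[[g]] <- p
    }
    tryCatch(
      pk_objective(pars, fit$data, fit$dose, fit$weighting,
                   rtol = fit$control$rtol, atol = fit$control$atol),
      error = function(e) 1e12)  # infeasible scan point: huge finite loss
  }

  start_log <- log(unlist(fit$coefficients[others]))
  losses <- vapply(values, function(v) {
    if (!length(others) || !reoptimize) return(obj_at(v, start_log))
    res <- tryCatch(
      stats::optim(start_log, function(th) obj_at(v, th),
                   method = "L-BFGS-B",
                   lower = log(fit$lower[others]),
                   upper = log(fit$upper[others]),
                   control = list(maxit = 100)),
      error = function(e) list(value = obj_at(v, start_log)))
    res$value
  }, 0)

  if (is.null(abs_floor)) {
    # squared solver noise (rtol x concentration scale) summed over points,
    # with a generous safety factor
    noise2 <- (fit$control$rtol^2) * mean(fit$data$conc_nM^2)
    abs_floor <- max(1e-8, 100 * nrow(fit$data) * noise2)
  }
  sig <- max(threshold * fit$loss, abs_floor)
  left <- any(losses[values < opt_val] - fit$loss > sig)
  right <- any(losses[values > opt_val] - fit$loss > sig)
  classification <- if (left && right) "identifiable" else
    if (left || right) "partially identifiable" else "unidentifiable"
  bounded_side <- if (left && !right) "below" else
    if (right && !left) "above" else NA_character_

  structure(list(parameter = parameter,
                 profile = data.frame(value = values, loss = losses),
                 optimum = opt_val, loss_at_optimum = fit$loss,
                 threshold = sig, classification = classification,
                 bounded_side = bounded_side),
            class = "identifiability_profile")
}

#' @export
print.identifiability_profile <- function(x, ...) {
  cat(sprintf("Identifiability profile for %s: %s\n", x$parameter,
              x$classification))
  cat(sprintf("  optimum %.6g (loss %.6g), significance threshold +%.3g\n",
              x$optimum, x$loss_at_optimum, x$threshold))
  print(x$profile, row.names = FALSE)
  invisible(x)
}

#' @export
plot.identifiability_profile <- function(x, ...) {
  graphics::plot(x$profile$value, x$profile$loss, type = "b", log = "x",
                 xlab = x$parameter, ylab = "re-optimized loss", ...)
  graphics::abline(v = x$optimum, lty = 2, col = "grey40")
  graphics::abline(h = x$loss_at_optimum + x$threshold, lty = 3,
                   col = "firebrick")
  invisible(x)
}
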