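#' Observed concentration-time data format
#'
#' Fitting functions consume long-format data frames with columns
#' `genotype` (label), `time_h`, `analyte` (`"losartan"` or `"E3174"`) and
#' `conc_nM`; an optional `subject` column distinguishes replicate curves.
#' [read_observations()] and [generate_observations()] produce this format.
#'
#' @name observed_data
NULL

check_observed <- function(data) {
  need <- c("genotype", "time_h", "analyte", "conc_nM")
  if (!is.data.frame(data) || !all(need %in% names(data)))
    stop("observed data must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(data$analyte %in% c("losartan", "E3174")))
    stop("analyte must be 'losartan' or 'E3174'", call. = FALSE)
  if (any(data$time_h < 0) || any(!is.finite(data$conc_nM)))
    stop("invalid time or concentration in observed data", call. = FALSE)
  invisible(data)
}

# split the fitted vector (log scale) into per-genotype parameter objects
build_genotype_params <- function(theta_nat, start, shared, local,
                                  genotypes) {
  out <- list()
  for (g in genotypes) {
    p <- start[[g]]
    for (nm in shared) p[[nm]] <- theta_nat[[nm]]
    for (nm in local) p[[nm]] <- theta_nat[[paste0(nm, "|", g)]]
    validate_params(p)
    class(p) <- "losartan_params"
    out[[g]] <- p
  }
  out
}

#' Sum-of-squares objective for concentration data
#'
#' Sum over genotype groups and both analytes of squared residuals
#' (simulated minus observed) at the observation times; all points equally
#' weighted by default, with relative (`(sim-obs)/obs`) and log
#' (`log sim - log obs`) weightings available.
#'
#' @param params_by_genotype Named list of [losartan_params()], one per
#'   genotype present in `data`.
#' @param data Observed data (see [observed_data]).
#' @param dose A [dose_regimen()] or dose in mg.
#' @param weighting `"absolute"` (default), `"relative"` or `"log"`.
#' @param rtol,atol Solver tolerances for the objective simulations.
#' @return Scalar loss (nM^2 under absolute weighting).
#' @export
pk_objective <- function(params_by_genotype, data, dose,
                         weighting = c("absolute", "relative", "log"),
                         rtol = 1e-6, atol = 1e-8) {
  check_observed(data)
  weighting <- match.arg(weighting)
  loss <- 0
  for (g in unique(data$genotype)) {
    dg <- data[data$genotype == g, , drop = FALSE]
    p <- params_by_genotype[[g]]
    if (is.null(p)) stop("no parameters supplied for genotype '", g, "'",
                         call. = FALSE)
    tt <- sort(unique(dg$time_h))
    sim <- simulate_losartan(p, dose, times = tt, rtol = rtol, atol = atol)
    for (an in c("losartan", "E3174")) {
      da <- dg[dg$analyte == an, , drop = FALSE]
      if (!nrow(da)) next
      pred <- sim[[analyte_column(an)]][match(da$time_h, sim$time_h)]
      r <- switch(weighting,
                  absolute = pred - da$conc_nM,
                  relative = (pred - da$conc_nM) /
                    pmax(da$conc_nM, .Machine$double.eps),
                  log = log(pmax(pred, 1e-12)) -
                    log(pmax(da$conc_nM, 1e-12)))
      loss <- loss + sum(r^2)
    }
  }
  loss
}

#' Fit the losartan model to concentration-time data
#'
#' Calibrates selected model parameters to observed losartan/E-3174
#' concentration curves by a seeded global particle-swarm search on the log
#' scale of the parameters, followed by an L-BFGS-B polish. `shared`
#' parameters take one value across all genotype groups; `local` parameters
#' (typically `k_m` across CYP2C9 groups or `k_ent_int` across ABCB1
#' groups) take one value per genotype.
#'
#' @param data Observed data (see [observed_data]).
#' @param dose A [dose_regimen()] or dose in mg.
#' @param start Starting/fixed parameters: a single [losartan_params()]
#'   (recycled per genotype) or a named list, one per genotype.
#' @param shared Character vector of globally fitted parameter names.
#' @param local Character vector of per-genotype fitted parameter names.
#' @param lower,upper Named bounds for fitted parameters (on the natural
#'   scale, > 0). Defaults: start value divided/multiplied by 20.
#' @param weighting Residual weighting, see [pk_objective()].
#' @param seed Integer seed for the swarm.
#' @param control List: `n_particles`, `max_iter` (default 40), `polish`
#'   (TRUE), `rtol`/`atol` for objective simulations.
#' @return An object of class `losartan_fit` with methods `print`,
#'   `summary`, `coef`, `predict`, `fitted`, `residuals` and `plot`.
#' @export
#' @examples
#' \donttest{
#' design <- observation_design(n_subjects = 1, cv = 0, seed = 1)
#' obs <- generate_observations(list("GG/CC" = losartan_params()), 50,
#'                              design)
#' fit <- losartan_fit(obs$mean_long, 50, shared = "k_m",
#'                     control = list(max_iter = 10), seed = 1)
#' coef(fit)
#' }
losartan_fit <- function(data, dose, start = losartan_params(),
                         shared = character(), local = character(),
                         lower = NULL, upper = NULL,
                         weighting = c("absolute", "relative", "log"),
                         seed = 1, control = list()) {
  check_observed(data)
  weighting <- match.arg(weighting)
  if (is.numeric(dose)) dose <- dose_regimen(dose)
  genotypes <- unique(data$genotype)
  if (inherits(start, "losartan_params"))
    start <- stats::setNames(rep(list(start), length(genotypes)), genotypes)
  if (!all(genotypes %in% names(start)))
    stop("start parameters missing for some genotypes", call. = FALSE)
  fitted_names <- c(shared,
                    as.vector(outer(local, genotypes, paste, sep = "|")))
  if (!length(fitted_names)) stop("no parameters to fit", call. = FALSE)
  bad <- setdiff(c(shared, local), c(PARAM_NAMES, "k_int_ex"))
  if (length(bad)) stop("unknown fitted parameter(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)

  start_val <- function(nm) {
    base <- sub("\\|.*$", "", nm)
    g <- if (grepl("|", nm, fixed = TRUE)) sub("^.*\\|", "", nm) else
      genotypes[1L]
    start[[g]][[base]]
  }
  sv <- vapply(fitted_names, start_val, 0)
  default_lower <- pmax(sv / 20, 1e-10)
  default_upper <- pmax(sv * 20, 1e-6)
  lo <- default_lower
  up <- default_upper
  if (!is.null(lower)) lo[names(lower)] <- pmax(lower, 1e-300)
  if (!is.null(upper)) up[names(upper)] <- upper
  if (any(!is.finite(lo)) || any(!is.finite(up)) || any(lo >= up))
    stop("bounds must be finite with lower < upper", call. = FALSE)

  ctrl <- utils::modifyList(
    list(n_particles = NULL, max_iter = 40, polish = TRUE,
         rtol = 1e-6, atol = 1e-8), control)

  obj_log <- function(th) {
    theta <- stats::setNames(as.list(exp(th)), fitted_names)
    pars <- build_genotype_params(theta, start, shared, local, genotypes)
    pk_objective(pars, data, dose, weighting,
                 rtol = ctrl$rtol, atol = ctrl$atol)
  }
  res <- pso_optimize(obj_log, log(lo), log(up),
                      n_particles = ctrl$n_particles,
                      max_iter = ctrl$max_iter, seed = seed,
                      polish = ctrl$polish)
  theta_hat <- stats::setNames(exp(res$par), fitted_names)
  pars_hat <- build_genotype_params(as.list(theta_hat), start, shared,
                                    local, genotypes)
  start_loss <- obj_log(log(sv))
  improved <- res$value <= start_loss + max(1e-8, 1e-6 * start_loss)
  if (!improved) {
    warning("optimizer found no improvement over the starting point; ",
            "returning the best point found", call. = FALSE)
  }
  structure(list(coefficients = theta_hat,
                 params_by_genotype = pars_hat,
                 loss = res$value, start_loss = start_loss,
                 improved = improved,
                 data = data, dose = dose, start = start,
                 shared = shared, local = local,
                 lower = stats::setNames(lo, fitted_names),
                 upper = stats::setNames(up, fitted_names),
                 weighting = weighting, seed = seed, control = ctrl,
                 evals = res$evals, trace = res$trace),
            class = "losartan_fit")
}

#' @export
coef.losartan_fit <- function(object, ...) object$coefficients

#' @export
print.losartan_fit <- function(x, ...) {
  cat("Losartan model fit (", length(x$coefficients),
      " parameter(s), seed ", x$seed, ")\n", sep = "")
  cat("  genotype groups:", paste(names(x$params_by_genotype),
                                  collapse = ", "), "\n")
  cat(sprintf("  final loss: %.6g (%s weighting, %d evaluations)\n",
              x$loss, x$weighting, x$evals))
  print(round(unlist(x$coefficients), 6))
  invisible(x)
}

#' @export
summary.losartan_fit <- function(object, ...) {
  co <- data.frame(parameter = names(object$coefficients),
                   estimate = unname(unlist(object$coefficients)),
                   lower = unname(object$lower),
                   upper = unname(object$upper),
                   stringsAsFactors = FALSE)
  out <- list(coefficients = co, loss = object$loss,
              start_loss = object$start_loss,
              n_obs = nrow(object$data),
              genotypes = names(object$params_by_genotype),
              weighting = object$weighting, seed = object$seed)
  class(out) <- "summary.losartan_fit"
  out
}

#' @export
print.summary.losartan_fit <- function(x, ...) {
  cat("Losartan model fit summary\n")
  cat(sprintf("  %d observations, genotypes: %s\n", x$n_obs,
              paste(x$genotypes, collapse = ", ")))
  cat(sprintf("  loss %.6g (start %.6g), %s weighting, seed %d\n",
              x$loss, x$start_loss, x$weighting, x$seed))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' @export
predict.losartan_fit <- function(object, genotype = NULL, times = NULL,
                                 t_end = NULL, output_step = 0.01, ...) {
  gs <- if (is.null(genotype)) names(object$params_by_genotype) else
    genotype
  if (is.null(t_end)) t_end <- max(object$data$time_h)
  out <- lapply(gs, function(g)
    simulate_losartan(object$params_by_genotype[[g]], object$dose,
                      t_end = t_end, output_step = output_step,
                      times = times, genotype_label = g))
  names(out) <- gs
  if (length(out) == 1L) out[[1L]] else out
}

#' @export
fitted.losartan_fit <- function(object, ...) {
  d <- object$data
  pred <- numeric(nrow(d))
  for (g in unique(d$genotype)) {
    idx <- d$genotype == g
    tt <- sort(unique(d$time_h[idx]))
    sim <- simulate_losartan(object$params_by_genotype[[g]], object$dose,
                             times = tt)
    for (an in c("losartan", "E3174")) {
      ii <- idx & d$analyte == an
      pred[ii] <- sim[[analyte_column(an)]][match(d$time_h[ii], sim$time_h)]
    }
  }
  pred
}

#' @export
residuals.losartan_fit <- function(object, ...) {
  fitted(object) - object$data$conc_nM
}

#' @export
plot.losartan_fit <- function(x, ...) {
  gs <- names(x$params_by_genotype)
  old <- graphics::par(mfrow = c(1, length(gs)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (g in gs) {
    sim <- predict(x, g)
    d <- x$data[x$data$genotype == g, ]
    graphics::matplot(sim$time_h, cbind(sim$C_p_nM, sim$C_m_nM),
                      type = "l", lty = 1,
                      col = c("steelblue", "darkorange"),
                      xlab = "time (h)", ylab = "concentration (nM)",
                      main = g, ...)
    cols <- c(losartan = "steelblue", E3174 = "darkorange")
    graphics::points(d$time_h, d$conc_nM, pch = 1, col = cols[d$analyte])
  }
  invisible(x)
}

#' Two-stage genotype-stratified calibration
#'
#' Mirrors the stepwise protocol used to stratify the model by genotype:
#' stage 1 fits the CYP2C9 conversion rate `k_m` per CYP2C9 genotype
#' (together with any shared globals) on the CYP2C9-stratified data; stage
#' 2 fixes the stage-1 `k_m`, then fits the ABCB1 efflux rate `k_ent_int`
#' per ABCB1 genotype plus refined globals on the ABCB1-stratified data,
#' starting from the stage-1 solution.
#'
#' @param data_cyp2c9 Observed data for CYP2C9 genotype groups.
#' @param data_abcb1 Observed data for ABCB1 genotype groups.
#' @param dose Dose (mg) or [dose_regimen()].
#' @param start Base [losartan_params()].
#' @param shared Globally fitted parameter names (both stages).
#' @param seed Integer seed.
#' @param control Optimizer control, see [losartan_fit()].
#' @return List with elements `stage1`, `stage2` (both `losartan_fit`) and
#'   `k_m` (the fixed stage-1 per-genotype values).
#' @export
losartan_fit_staged <- function(data_cyp2c9, data_abcb1, dose,
                                start = losartan_params(),
                                shared = character(), seed = 1,
                                control = list()) {
  s1 <- losartan_fit(data_cyp2c9, dose, start = start, shared = shared,
                     local = "k_m", seed = seed, control = control)
  km <- coef(s1)[grep("^k_m\\|", names(coef(s1)))]
  start2 <- start
  for (nm in shared) start2[[nm]] <- coef(s1)[[nm]]
  # ABCB1 groups share the wild-type CYP2C9 background
  wt <- grep("CYP2C9\\*1", names(km), value = TRUE)
  if (length(wt)) start2$k_m <- unname(km[wt[1L]])
  validate_params(start2)
  class(start2) <- "losartan_params"
  s2 <- losartan_fit(data_abcb1, dose, start = start2, shared = shared,
                     local = "k_ent_int", seed = seed + 1L,
                     control = control)
  list(stage1 = s1, stage2 = s2, k_m = km)
}
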