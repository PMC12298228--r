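#' Sparse sampling design for synthetic observations
#'
#' Emulates a typical single-dose PK study design: sparse sampling over
#' 0-24 h (including the 6, 8 and 10 h points needed by the terminal
#' half-life anchors), two analytes, and multiplicative assay/subject
#' noise with a fixed coefficient of variation.
#'
#' @param sample_times Sampling times (h, strictly increasing); default
#'   `c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 10, 12, 24)`.
#' @param cv Proportional noise CV (default 0.10; 0 = noise-free).
#' @param n_subjects Subjects per genotype (default 12).
#' @param seed Integer seed.
#' @return An object of class `observation_design`.
#' @export
observation_design <- function(sample_times = c(0.25, 0.5, 1, 1.5, 2, 3,
                                                4, 6, 8, 10, 12, 24),
                               cv = 0.10, n_subjects = 12, seed = 1) {
  if (any(diff(sample_times) <= 0) || any(sample_times < 0))
    stop("sample_times must be nonnegative and strictly increasing",
         call. = FALSE)
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  structure(list(sample_times = sample_times, cv = cv,
                 n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed)),
            class = "observation_design")
}

#' Generate synthetic observed concentration datasets
#'
#' Simulates the true concentration curves per genotype, samples them at
#' the design times, and applies mean-one multiplicative lognormal noise
#' per subject and time point (`sigma^2 = log(1 + CV^2)`, mean-corrected so
#' the expected observation equals the true concentration and the
#' per-point coefficient of variation equals the nominal CV). Aggregates
#' to mean/SD curves.
#'
#' @param params_by_genotype Named list of [losartan_params()] (names are
#'   genotype labels), or a character vector of genotype labels (expanded
#'   via [genotype_params()]).
#' @param dose Dose (mg) or [dose_regimen()].
#' @param design An [observation_design()].
#' @return A list of class `pk_observations`: `subjects` (long data frame
#'   `genotype`, `subject`, `time_h`, `analyte`, `conc_nM`), `summary`
#'   (`genotype`, `time_h`, `analyte`, `mean_nM`, `sd_nM`, `n`),
#'   `mean_long` (mean curves in the fit-ready [observed_data] format) and
#'   `truth` (the noise-free `conc_series` per genotype).
#' @export
#' @examples
#' obs <- generate_observations("GG/CC", 50,
#'                              observation_design(n_subjects = 2))
#' head(obs$summary)
generate_observations <- function(params_by_genotype, dose, design) {
  stopifnot(inherits(design, "observation_design"))
  if (is.character(params_by_genotype))
    params_by_genotype <- lapply(
      stats::setNames(params_by_genotype, params_by_genotype),
      genotype_params)
  gs <- names(params_by_genotype)
  if (is.null(gs) || any(!nzchar(gs)))
    stop("params_by_genotype must be named by genotype label",
         call. = FALSE)
  tt <- design$sample_times
  sdlog <- sqrt(log(1 + design$cv^2))

  truth <- lapply(gs, function(g)
    simulate_losartan(params_by_genotype[[g]], dose, times = tt,
                      genotype_label = g))
  names(truth) <- gs

  subjects <- with_seed(design$seed, {
    do.call(rbind, lapply(gs, function(g) {
      tr <- truth[[g]]
      do.call(rbind, lapply(seq_len(design$n_subjects), function(s) {
        do.call(rbind, lapply(c("losartan", "E3174"), function(an) {
          mu <- tr[[analyte_column(an)]]
          noise <- if (design$cv == 0) rep(1, length(mu)) else
            exp(stats::rnorm(length(mu), -sdlog^2 / 2, sdlog))
          data.frame(genotype = g, subject = s, time_h = tt,
                     analyte = an, conc_nM = mu * noise,
                     stringsAsFactors = FALSE)
        }))
      }))
    }))
  })

  agg <- stats::aggregate(conc_nM ~ genotype + time_h + analyte,
                          data = subjects,
                          FUN = function(x) c(mean = mean(x),
                                              sd = stats::sd(x),
                                              n = length(x)))
  summary_df <- data.frame(genotype = agg$genotype, time_h = agg$time_h,
                           analyte = agg$analyte,
                           mean_nM = agg$conc_nM[, "mean"],
                           sd_nM = agg$conc_nM[, "sd"],
                           n = agg$conc_nM[, "n"],
                           stringsAsFactors = FALSE)
  summary_df <- summary_df[order(summary_df$genotype, summary_df$analyte,
                                 summary_df$time_h), ]
  rownames(summary_df) <- NULL
  mean_long <- data.frame(genotype = summary_df$genotype,
                          time_h = summary_df$time_h,
                          analyte = summary_df$analyte,
                          conc_nM = summary_df$mean_nM,
                          stringsAsFactors = FALSE)

  structure(list(subjects = subjects, summary = summary_df,
                 mean_long = mean_long, truth = truth,
                 design = design, dose_mg = if (is.numeric(dose)) dose else
                   dose$dose_mg),
            class = "pk_observations")
}

#' @export
print.pk_observations <- function(x, ...) {
  cat(sprintf(
    "Synthetic observations: %d genotype(s) x %d subject(s) x %d times, CV %g%%\n",
    length(x$truth), x$design$n_subjects, length(x$design$sample_times),
    100 * x$design$cv))
  print(utils::head(x$summary))
  invisible(x)
}

#' Read and write observed datasets as CSV
#'
#' Two schemas are supported: `"summary"`
#' (`genotype,time_h,analyte,mean_nM,sd_nM,n`) and `"subject"`
#' (`genotype,subject,time_h,analyte,conc_nM`). `read_observations()`
#' detects the schema from the header and returns a fit-ready long data
#' frame (see [observed_data]); summary files yield the mean curves.
#'
#' @param obs A `pk_observations` object.
#' @param path File path.
#' @param format `"summary"` (default) or `"subject"`.
#' @return `read_observations()` returns a data frame;
#'   `write_observations()` returns `path` invisibly.
#' @export
write_observations <- function(obs, path,
                               format = c("summary", "subject")) {
  stopifnot(inherits(obs, "pk_observations"))
  format <- match.arg(format)
  d <- if (format == "summary") obs$summary else obs$subjects
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  d <- utils::read.csv(path)
  if (all(c("genotype", "time_h", "analyte", "mean_nM") %in% names(d))) {
    out <- data.frame(genotype = d$genotype, time_h = d$time_h,
                      analyte = d$analyte, conc_nM = d$mean_nM,
                      stringsAsFactors = FALSE)
  } else if (all(c("genotype", "time_h", "analyte", "conc_nM") %in%
                 names(d))) {
    out <- d
  } else {
    stop("unrecognized observed-data CSV schema", call. = FALSE)
  }
  check_observed(out)
  out
}

#' Parameter-recovery harness
#'
#' Closed-loop check of the calibration machinery: generate synthetic
#' observations from known parameters, fit the chosen parameters to the
#' mean curves, and report per-parameter relative errors (optionally with
#' identifiability classifications from profile scans).
#'
#' @param true_params_by_genotype Named list of true [losartan_params()]
#'   per genotype (or character vector of genotype labels).
#' @param dose Dose (mg).
#' @param design An [observation_design()].
#' @param shared,local Fitted parameter names, as in [losartan_fit()].
#' @param start Starting parameters for the fit; default perturbs nothing
#'   (the true values are NOT given to the optimizer as a start: the start
#'   is the default parameter set).
#' @param seed Integer seed (generation and fitting).
#' @param control Optimizer control, see [losartan_fit()].
#' @param classify Run [identifiability_profile()] on each fitted
#'   parameter (default FALSE).
#' @return A list of class `recovery_report`: `report` (data frame
#'   `parameter`, `true`, `fitted`, `rel_error`, and `classification` when
#'   requested), `fit`, and the inputs.
#' @export
recovery_harness <- function(true_params_by_genotype, dose, design,
                             shared = character(),
                             local = character(),
                             start = losartan_params(), seed = 1,
                             control = list(), classify = FALSE) {
  if (is.character(true_params_by_genotype))
    true_params_by_genotype <- lapply(
      stats::setNames(true_params_by_genotype, true_params_by_genotype),
      genotype_params)
  obs <- generate_observations(true_params_by_genotype, dose, design)
  fit <- losartan_fit(obs$mean_long, dose, start = start, shared = shared,
                      local = local, seed = seed, control = control)
  co <- coef(fit)
  truev <- vapply(names(co), function(nm) {
    base <- sub("\\|.*$", "", nm)
    g <- if (grepl("|", nm, fixed = TRUE)) sub("^.*\\|", "", nm) else
      names(true_params_by_genotype)[1L]
    true_params_by_genotype[[g]][[base]]
  }, 0)
  report <- data.frame(parameter = names(co), true = unname(truev),
                       fitted = unname(co),
                       rel_error = unname(abs(co - truev) /
                                            pmax(abs(truev),
                                                 .Machine$double.eps)),
                       stringsAsFactors = FALSE)
  if (classify) {
    report$classification <- vapply(report$parameter, function(pm) {
      pr <- tryCatch(identifiability_profile(fit, pm),
                     error = function(e) NULL)
      if (is.null(pr)) NA_character_ else pr$classification
    }, "")
  }
  structure(list(report = report, fit = fit, design = design,
                 dose_mg = if (is.numeric(dose)) dose else dose$dose_mg,
                 seed = seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter-recovery report (seed", x$seed, ")\n")
  print(x$report, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write and read a recovery report (JSON round trip)
#'
#' @param report A `recovery_report`.
#' @param path Output path.
#' @return `read_recovery_report()` returns the report data frame.
#' @export
write_recovery_report <- function(report, path) {
  stopifnot(inherits(report, "recovery_report"))
  jsonlite::write_json(list(seed = report$seed, dose_mg = report$dose_mg,
                            report = report$report),
                       path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_recovery_report
#' @export
read_recovery_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$report
}
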