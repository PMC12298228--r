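#' Specification of a virtual population
#'
#' Between-subject variability is modelled by drawing every model parameter
#' independently from a normal distribution whose mean is the optimized
#' (median) value and whose standard deviation is a fixed fraction of it
#' (default 10%), truncated to positive values by resampling.
#'
#' @param n_per_genotype Draws per genotype (default 100).
#' @param sd_fraction SD as a fraction of the median (default 0.10; in
#'   `[0, 1)`).
#' @param genotypes Genotype labels (default the three ABCB1 diplotypes).
#' @param seed Integer seed.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_per_genotype = 100, sd_fraction = 0.10,
                            genotypes = c("GG/CC", "GT/CT", "TT/TT"),
                            seed = 1) {
  if (n_per_genotype < 2) stop("n_per_genotype must be >= 2",
                               call. = FALSE)
  if (sd_fraction < 0 || sd_fraction >= 1)
    stop("sd_fraction must be in [0, 1)", call. = FALSE)
  structure(list(n_per_genotype = as.integer(n_per_genotype),
                 sd_fraction = sd_fraction, genotypes = genotypes,
                 seed = as.integer(seed)),
            class = "population_spec")
}

# one truncated-normal draw matrix: n x length(medians), > 0 by resampling
draw_truncnorm <- function(n, medians, sd_fraction) {
  out <- matrix(NA_real_, n, length(medians),
                dimnames = list(NULL, names(medians)))
  for (j in seq_along(medians)) {
    m <- medians[j]
    s <- sd_fraction * m
    if (s == 0) { out[, j] <- m; next }
    x <- stats::rnorm(n, m, s)
    while (any(x <= 0)) {
      bad <- x <= 0
      x[bad] <- stats::rnorm(sum(bad), m, s)
    }
    out[, j] <- x
  }
  out
}

#' Sample a virtual population and its PK metrics
#'
#' Draws `n_per_genotype` parameter sets per genotype around the
#' genotype-specific medians, simulates each draw at the given dose, and
#' summarizes `C_max`, `t_max` and `AUC_0_inf` for both analytes.
#'
#' In the default (`matched = FALSE`) mode every genotype receives its own
#' independent draws of every parameter, matching a design in which
#' parameter values are drawn separately per genotype group. With
#' `matched = TRUE`, parameters whose medians are identical across
#' genotypes (the global parameters) share one set of draws, which removes
#' between-group sampling noise from genotype contrasts.
#'
#' @param spec A [population_spec()].
#' @param base Base [losartan_params()] from which genotype medians are
#'   derived via [genotype_params()]; alternatively a named list of
#'   `losartan_params`, one per genotype.
#' @param dose Dose (mg); default 50.
#' @param compute_pk Simulate and summarize each draw (default TRUE; FALSE
#'   returns the draws only).
#' @param matched Share global-parameter draws across genotypes (default
#'   FALSE).
#' @param t_end,output_step Simulation window for per-draw PK (defaults 24
#'   h, 0.02 h).
#' @return An object of class `losartan_population`: list with `draws`
#'   (long data frame `draw_id`, `genotype`, `parameter`, `value`), `pk`
#'   (per-draw PK metrics, when computed), and `spec`.
#' @export
#' @examples
#' \donttest{
#' pop <- sample_population(population_spec(n_per_genotype = 5),
#'                          compute_pk = FALSE)
#' head(pop$draws)
#' }
sample_population <- function(spec, base = losartan_params(), dose = 50,
                              compute_pk = TRUE, matched = FALSE,
                              t_end = 24, output_step = 0.02) {
  stopifnot(inherits(spec, "population_spec"))
  gs <- spec$genotypes
  medians <- if (inherits(base, "losartan_params")) {
    lapply(stats::setNames(gs, gs), function(g) genotype_params(g, base))
  } else {
    if (!all(gs %in% names(base)))
      stop("base parameter list missing some genotypes", call. = FALSE)
    base[gs]
  }
  n <- spec$n_per_genotype
  med_mat <- vapply(gs, function(g)
    unlist(medians[[g]][PARAM_NAMES]), numeric(length(PARAM_NAMES)))
  rownames(med_mat) <- PARAM_NAMES
  is_global <- apply(med_mat, 1L, function(r) length(unique(r)) == 1L)

  draws_by_g <- with_seed(spec$seed, {
    if (matched) {
      glob_med <- stats::setNames(med_mat[is_global, 1L],
                                  rownames(med_mat)[is_global])
      shared <- draw_truncnorm(n, glob_med, spec$sd_fraction)
      lapply(gs, function(g) {
        loc_med <- stats::setNames(med_mat[!is_global, g],
                                   rownames(med_mat)[!is_global])
        loc <- draw_truncnorm(n, loc_med, spec$sd_fraction)
        cbind(shared, loc)[, PARAM_NAMES, drop = FALSE]
      })
    } else {
      lapply(gs, function(g)
        draw_truncnorm(n, med_mat[, g], spec$sd_fraction))
    }
  })
  names(draws_by_g) <- gs

  long <- do.call(rbind, lapply(gs, function(g) {
    m <- draws_by_g[[g]]
    data.frame(draw_id = rep(seq_len(n), ncol(m)),
               genotype = g,
               parameter = rep(colnames(m), each = n),
               value = as.vector(m), stringsAsFactors = FALSE)
  }))

  pk <- NULL
  if (compute_pk) {
    rows <- vector("list", n * length(gs))
    k <- 0L
    for (g in gs) {
      m <- draws_by_g[[g]]
      for (i in seq_len(n)) {
        p <- medians[[g]]
        p[PARAM_NAMES] <- as.list(m[i, PARAM_NAMES])
        validate_params(p)
        class(p) <- "losartan_params"
        sim <- simulate_losartan(p, dose, t_end = t_end,
                                 output_step = output_step,
                                 rtol = 1e-6, atol = 1e-8)
        cp <- cmax_tmax(sim, "losartan")
        cm <- cmax_tmax(sim, "E3174")
        k <- k + 1L
        rows[[k]] <- data.frame(
          draw_id = i, genotype = g,
          Cmax_losartan_nM = unname(cp["C_max"]),
          tmax_losartan_h = unname(cp["t_max"]),
          AUC0inf_losartan_nmolh_L = auc_0_inf(sim, "losartan"),
          Cmax_E3174_nM = unname(cm["C_max"]),
          tmax_E3174_h = unname(cm["t_max"]),
          AUC0inf_E3174_nmolh_L = auc_0_inf(sim, "E3174"),
          stringsAsFactors = FALSE)
      }
    }
    pk <- do.call(rbind, rows)
  }

  structure(list(draws = long, pk = pk, spec = spec, dose_mg = dose,
                 matched = matched),
            class = "losartan_population")
}

#' @export
print.losartan_population <- function(x, ...) {
  cat(sprintf(
    "Virtual population: %d draws x %d genotype(s) (SD = %g%% of median, seed %d)\n",
    x$spec$n_per_genotype, length(x$spec$genotypes),
    100 * x$spec$sd_fraction, x$spec$seed))
  if (!is.null(x$pk)) {
    cat(sprintf("  per-draw PK at %g mg:\n", x$dose_mg))
    agg <- stats::aggregate(
      x$pk[, c("Cmax_losartan_nM", "tmax_losartan_h",
               "AUC0inf_losartan_nmolh_L")],
      list(genotype = x$pk$genotype), stats::median)
    print(agg, row.names = FALSE)
  }
  invisible(x)
}

#' Write population outputs as CSV
#'
#' @param pop A `losartan_population`.
#' @param draws_path Path for the long-format draws CSV
#'   (`draw_id,genotype,parameter,value`).
#' @param pk_path Optional path for the per-draw PK summary CSV.
#' @return `draws_path`, invisibly.
#' @export
write_population <- function(pop, draws_path, pk_path = NULL) {
  stopifnot(inherits(pop, "losartan_population"))
  utils::write.csv(pop$draws, draws_path, row.names = FALSE, quote = FALSE)
  if (!is.null(pk_path) && !is.null(pop$pk))
    utils::write.csv(pop$pk, pk_path, row.names = FALSE, quote = FALSE)
  invisible(draws_path)
}

#' Gated comparison of a PK metric across genotype groups
#'
#' Implements the gated procedure used for genotype contrasts: Shapiro-Wilk
#' normality within each group and a Brown-Forsythe (median-centred Levene)
#' equal-variance check, both at p < 0.05, select the pairwise test - a
#' pooled-variance t-test when every group is compatible with normality and
#' homoscedasticity, otherwise the Mann-Whitney rank-sum test. The omnibus
#' comparison is a Kruskal-Wallis one-way ANOVA on ranks. Pairwise
#' significance uses the Bonferroni cutoff `alpha / number of groups`
#' (0.05/3 = 0.0167 for three genotypes).
#'
#' @param values Numeric metric values.
#' @param groups Group labels (same length; >= 2 groups of >= 3 values).
#' @param alpha Base significance level (default 0.05).
#' @return An object of class `group_comparison`.
#' @export
#' @examples
#' set.seed(1)
#' compare_groups(c(rnorm(10), rnorm(10, 2)), rep(c("A", "B"), each = 10))
compare_groups <- function(values, groups, alpha = 0.05) {
  if (length(values) != length(groups))
    stop("values and groups must have the same length", call. = FALSE)
  groups <- as.character(groups)
  gs <- unique(groups)
  if (length(gs) < 2L) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 3L))
    stop("every group needs at least 3 values (got ",
         paste(names(sizes)[sizes < 3], collapse = ", "), ")",
         call. = FALSE)

  norm_p <- vapply(gs, function(g) {
    x <- values[groups == g]
    if (length(unique(x)) == 1L) return(0)  # degenerate: not normal
    stats::shapiro.test(x)$p.value
  }, 0)
  var_p <- if (all(vapply(gs, function(g)
    length(unique(values[groups == g])) > 1L, TRUE))) {
    car::leveneTest(values ~ factor(groups),
                    center = stats::median)[1L, "Pr(>F)"]
  } else 0
  gates_pass <- all(norm_p > 0.05) && var_p > 0.05
  pairwise_test <- if (gates_pass) "t" else "mann-whitney"

  omnibus <- stats::kruskal.test(values ~ factor(groups))
  cutoff <- alpha / length(gs)

  pairs <- utils::combn(gs, 2L)
  pw <- lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1L, k]; g2 <- pairs[2L, k]
    x <- values[groups == g1]; y <- values[groups == g2]
    ht <- if (pairwise_test == "t") {
      stats::t.test(x, y, var.equal = TRUE)
    } else {
      suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
    }
    data.frame(group1 = g1, group2 = g2, test = pairwise_test,
               statistic = unname(ht$statistic), p = ht$p.value,
               significant = ht$p.value < cutoff,
               stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, pw)

  structure(list(normality_p = norm_p, variance_p = var_p,
                 gates_pass = gates_pass,
                 omnibus = list(test = "kruskal-wallis",
                                statistic = unname(omnibus$statistic),
                                p = omnibus$p.value),
                 pairwise = pw, pairwise_test = pairwise_test,
                 cutoff = cutoff, alpha = alpha,
                 n_groups = length(gs), sizes = as.list(sizes),
                 p_value_method = "asymptotic with continuity correction"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison (", x$n_groups, " groups)\n", sep = "")
  cat(sprintf("  normality (Shapiro-Wilk) min p = %.4g; equal variance p = %.4g\n",
              min(x$normality_p), x$variance_p))
  cat(sprintf("  omnibus Kruskal-Wallis: chi^2 = %.4g, p = %.4g\n",
              x$omnibus$statistic, x$omnibus$p))
  cat(sprintf("  pairwise %s tests, Bonferroni cutoff %.4g:\n",
              x$pairwise_test, x$cutoff))
  pwp <- x$pairwise
  pwp$decision <- ifelse(pwp$significant, "*", "NS")
  print(pwp[c("group1", "group2", "p", "decision")], row.names = FALSE)
  invisible(x)
}

#' Write a comparison report as JSON
#'
#' @param report A `group_comparison`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(report, path) {
  stopifnot(inherits(report, "group_comparison"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
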