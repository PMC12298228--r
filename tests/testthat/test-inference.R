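make_noise_free_obs <- function(genotype = "CYP2C9*1/CYP2C9*1",
                                seed = 2) {
  p <- genotype_params(genotype)
  obs <- generate_observations(stats::setNames(list(p), genotype), 50,
                               observation_design(cv = 0, n_subjects = 1,
                                                  seed = seed))
  list(params = p, data = obs$mean_long)
}

test_that("the objective vanishes at the truth and is permutation-invariant", {
  x <- make_noise_free_obs()
  pl <- list("CYP2C9*1/CYP2C9*1" = x$params)
  loss <- pk_objective(pl, x$data, 50, rtol = 1e-8, atol = 1e-10)
  expect_lt(loss, 1e-10)
  shuffled <- x$data[rev(seq_len(nrow(x$data))), ]
  wrong <- list("CYP2C9*1/CYP2C9*1" = set_params(x$params, k_m = 1.5))
  expect_equal(pk_objective(wrong, x$data, 50),
               pk_objective(wrong, shuffled, 50))
})

test_that("the objective equals hand-summed residuals on a toy dataset", {
  p <- losartan_params()
  tt <- c(1, 2, 4)
  sim <- simulate_losartan(p, 50, times = tt, rtol = 1e-6, atol = 1e-8)
  delta <- c(1, -2, 3)
  toy <- data.frame(genotype = "G", time_h = tt, analyte = "losartan",
                    conc_nM = sim$C_p_nM[match(tt, sim$time_h)] + delta)
  loss <- pk_objective(list(G = p), toy, 50)
  expect_equal(loss, sum(delta^2), tolerance = 1e-6)
})

test_that("noise-free recovery: shared k_m and per-genotype efflux rates", {
  pg <- list("GG/CC" = genotype_params("GG/CC"),
             "GT/CT" = genotype_params("GT/CT"))
  obs <- generate_observations(pg, 50,
                               observation_design(cv = 0, n_subjects = 1,
                                                  seed = 4))
  fit <- losartan_fit(obs$mean_long, 50, start = losartan_params(),
                      shared = "k_m", local = "k_ent_int", seed = 5,
                      control = list(n_particles = 16, max_iter = 30,
                                     rtol = 1e-8, atol = 1e-10))
  co <- coef(fit)
  expect_lt(abs(co[["k_m"]] - 2.817) / 2.817, 0.05)
  expect_lt(abs(co[["k_ent_int|GG/CC"]] - 151.485) / 151.485, 0.15)
  expect_lt(abs(co[["k_ent_int|GT/CT"]] - 101.8) / 101.8, 0.15)
})

test_that("fits are deterministic under a seed and respect bounds", {
  x <- make_noise_free_obs(seed = 6)
  run <- function() {
    losartan_fit(x$data, 50, start = set_params(x$params, k_m = 1),
                 shared = "k_m", seed = 11,
                 control = list(n_particles = 6, max_iter = 4,
                                polish = FALSE))
  }
  f1 <- run(); f2 <- run()
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$trace, f2$trace)
  # bounds respected by every candidate the swarm evaluates
  seen <- new.env(); seen$x <- NULL
  quad <- function(v) { seen$x <- rbind(seen$x, v); sum((v - 1)^2) }
  res <- pso_optimize(quad, lower = c(-2, 0.5), upper = c(3, 4),
                      n_particles = 8, max_iter = 15, seed = 3)
  expect_true(all(seen$x[, 1] >= -2 - 1e-12 & seen$x[, 1] <= 3 + 1e-12))
  expect_true(all(seen$x[, 2] >= 0.5 - 1e-12 & seen$x[, 2] <= 4 + 1e-12))
  expect_equal(res$par, c(1, 1), tolerance = 1e-4)
})

test_that("parameters without influence on the data profile as unidentifiable", {
  # metabolite disposition cannot be learned from losartan-only data
  x <- make_noise_free_obs(seed = 8)
  los_only <- x$data[x$data$analyte == "losartan", ]
  fit <- losartan_fit(los_only, 50,
                      start = set_params(x$params, CL_m = 5, Vm = 30),
                      shared = c("CL_m", "Vm"), seed = 9,
                      control = list(n_particles = 6, max_iter = 5))
  pr <- identifiability_profile(fit, "CL_m", n = 5)
  expect_identical(pr$classification, "unidentifiable")
})

test_that("a well-informed conversion rate profiles as identifiable", {
  x <- make_noise_free_obs(seed = 10)
  fit <- losartan_fit(x$data, 50, start = set_params(x$params, k_m = 1),
                      shared = "k_m", seed = 12,
                      control = list(n_particles = 8, max_iter = 12,
                                     rtol = 1e-8, atol = 1e-10))
  pr <- identifiability_profile(fit, "k_m", n = 7)
  expect_identical(pr$classification, "identifiable")
  # profile consistency: the scan loss can never undercut the fitted loss
  expect_true(all(pr$profile$loss >= fit$loss - 1e-9))
  expect_error(identifiability_profile(fit, "k_m",
                                       values = coef(fit)[["k_m"]] * c(2, 4)),
               "bracket")
})

test_that("a near-zero efflux rate is only bounded from above", {
  p <- genotype_params("TT/TT")  # k_ent_int ~ 1e-12
  obs <- generate_observations(list("TT/TT" = p), 50,
                               observation_design(cv = 0, n_subjects = 1,
                                                  seed = 13))
  fit <- losartan_fit(obs$mean_long, 50,
                      start = set_params(p, k_ent_int = 1e-6),
                      local = "k_ent_int", seed = 14,
                      lower = c("k_ent_int|TT/TT" = 1e-9),
                      upper = c("k_ent_int|TT/TT" = 1e3),
                      control = list(n_particles = 8, max_iter = 10))
  est <- coef(fit)[["k_ent_int|TT/TT"]]
  pr <- identifiability_profile(fit, "k_ent_int|TT/TT",
                                values = c(est / 100, est, 50, 200))
  expect_identical(pr$classification, "partially identifiable")
  expect_identical(pr$bounded_side, "above")
})

test_that("elasticity coefficients match analytic oracles", {
  expect_equal(relative_sensitivity(function(a) 7, 3)$SS, 0)
  expect_equal(relative_sensitivity(function(a) a, 2)$SS, 1,
               tolerance = 1e-4)
  expect_equal(relative_sensitivity(function(a) a^2, 3)$SS, 2,
               tolerance = 1e-4)
  expect_error(relative_sensitivity(function(a) 0, 1), "zero")
  # relative mode for parameters far below the absolute step
  r <- relative_sensitivity(function(a) a, 1e-9, relative = TRUE)
  expect_identical(r$mode, "relative")
  expect_equal(r$SS, 1, tolerance = 1e-4)
})

test_that("simulated sensitivities have the expected sign structure", {
  p <- genotype_params("GG/CC")
  ss <- function(par, out) pk_sensitivity(p, par, out, t_end = 48,
                                          output_step = 0.05)$SS
  expect_lt(ss("k_m", "AUC0inf_losartan"), 0)
  expect_gt(ss("k_m", "AUC0inf_E3174"), 0)
  expect_lt(ss("CL_p", "AUC0inf_losartan"), 0)
  expect_lt(ss("CL_p", "AUC0inf_E3174"), 0)
  expect_lt(ss("k_ent_int", "Cmax_losartan"), 0)
  tab <- pk_sensitivity_table(p, parameters = c("k_m", "CL_p"),
                              outputs = "AUC0inf_losartan",
                              t_end = 48, output_step = 0.05)
  expect_identical(nrow(tab), 2L)
  expect_true(all(is.finite(tab$SS)))
})
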