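test_that("Cmax/tmax handle boundary extrema, analytic peaks, and linearity", {
  tt <- seq(0, 12, by = 0.002)
  # monotone decline: the peak sits at the first grid time
  dec <- series_from_funs(tt, function(t) 100 * exp(-0.3 * t))
  expect_equal(unname(cmax_tmax(dec, "losartan")["t_max"]), 0)
  # one-compartment oral curve, ka = 1, ke = 0.5: peak at ln(ka/ke)/(ka-ke)
  ka <- 1; ke <- 0.5
  bat <- series_from_funs(tt, function(t)
    ka / (ka - ke) * (exp(-ke * t) - exp(-ka * t)))
  expect_equal(unname(cmax_tmax(bat, "losartan")["t_max"]),
               log(ka / ke) / (ka - ke), tolerance = 0.002 / 1.386)
  # doubling the curve doubles Cmax and leaves tmax unchanged
  bat2 <- conc_series(tt, 2 * bat$C_p_nM, bat$C_m_nM)
  expect_equal(unname(cmax_tmax(bat2, "losartan")["C_max"]),
               2 * unname(cmax_tmax(bat, "losartan")["C_max"]))
  expect_equal(unname(cmax_tmax(bat2, "losartan")["t_max"]),
               unname(cmax_tmax(bat, "losartan")["t_max"]))
})

test_that("AUC to the horizon matches analytic and quadrature oracles", {
  tt <- seq(0, 40, by = 0.001)
  zero <- series_from_funs(tt, function(t) rep(0, length(t)))
  expect_equal(auc_0_inf(zero, "losartan"), 0)
  # C0 exp(-k t): AUC = C0/k
  expdec <- series_from_funs(tt, function(t) 100 * exp(-0.5 * t))
  expect_equal(auc_0_inf(expdec, "losartan"), 200, tolerance = 1e-4)
  # augmented-state integral vs trapezoid on a fine grid
  sim <- simulate_losartan(losartan_params(), 50, t_end = 24,
                           output_step = 0.001)
  aug <- auc_0_inf(sim, "losartan")
  trap <- sum(diff(sim$time_h) *
                (head(sim$C_p_nM, -1) + tail(sim$C_p_nM, -1)) / 2)
  expect_equal(aug, trap, tolerance = 1e-4)
  expect_error(auc_0_inf(expdec, "losartan", horizon = 100),
               "exceeds the last observation")
})

test_that("windowed AUC follows the clipped-difference construction", {
  tt <- seq(0, 24, by = 0.01)
  flat <- series_from_funs(tt, function(t) rep(1, length(t)))
  expect_equal(auc_x_y(flat, 2, 2), 0)
  expect_equal(auc_x_y(flat, 2, 4), 2, tolerance = 1e-9)
  sim <- simulate_losartan(losartan_params(), 50, t_end = 24,
                           output_step = 0.01)
  expect_equal(auc_x_y(sim, 0, 3) + auc_x_y(sim, 3, 11),
               auc_x_y(sim, 0, 11), tolerance = 1e-8)
  expect_error(auc_x_y(sim, 5, 2), "exceeds upper bound")
})

test_that("terminal half-life comes from the 6/8/10 h semilog regression", {
  tt <- seq(0, 12, by = 0.01)
  pure <- series_from_funs(tt, function(t) 50 * exp(-log(2) * t))
  expect_equal(half_life_semilog(pure, "losartan"), 1, tolerance = 1e-6)
  flat <- series_from_funs(tt, function(t) rep(3, length(t)))
  expect_error(half_life_semilog(flat, "losartan"), "no terminal decline")
  dead <- series_from_funs(tt, function(t) pmax(0, 1 - t / 5))
  expect_error(half_life_semilog(dead, "losartan"), "nonpositive")
  # biexponential: agree with a direct OLS on the three log-points
  bi <- series_from_funs(tt, function(t)
    80 * exp(-0.9 * t) + 20 * exp(-0.25 * t))
  anchors <- c(6, 8, 10)
  ci <- 80 * exp(-0.9 * anchors) + 20 * exp(-0.25 * anchors)
  slope <- stats::coef(stats::lm(log(ci) ~ anchors))[[2]]
  expect_equal(half_life_semilog(bi, "losartan"), log(2) / (-slope),
               tolerance = 1e-8)
})

test_that("apparent oral clearance reproduces printed dose/AUC pairs", {
  expect_equal(cl_over_f(50, 1349.1), 80.4, tolerance = 0.05 / 80.4)
  expect_equal(cl_over_f(50, 1352.644), 80.182, tolerance = 1e-3 / 80.182)
  expect_equal(cl_over_f(50, 2444.236), 44.37, tolerance = 0.01 / 44.37)
  # pre-absorption piecewise branch and input validation
  expect_identical(cl_over_f(50, 0), 0)
  expect_error(cl_over_f(50, -1), "nonnegative")
  # algebraic inverse: CL/F * AUC * MW / 1e6 returns the dose
  auc <- 1830.7
  expect_equal(cl_over_f(50, auc) * auc * 461.01 / 1e6, 50,
               tolerance = 1e-12)
})

test_that("curve distance is a Euclidean metric on common time points", {
  tt <- c(0.5, 1, 2, 4)
  a <- conc_series(tt, c(10, 20, 15, 5), c(1, 2, 3, 4))
  expect_equal(curve_distance(a, a), 0)
  b <- conc_series(tt, c(10, 20, 15, 5) + 1, c(1, 2, 3, 4))
  expect_equal(curve_distance(a, b, "losartan"), 2)  # sqrt(4 * 1)
  # brute-force summation oracle on a random pair with partial overlap
  set.seed(42)
  t1 <- sort(sample(seq(0.5, 12, by = 0.5), 10))
  t2 <- sort(sample(seq(0.5, 12, by = 0.5), 10))
  c1 <- conc_series(t1, runif(10, 0, 100), runif(10, 0, 100))
  c2 <- conc_series(t2, runif(10, 0, 100), runif(10, 0, 100))
  common <- intersect(t1, t2)
  i1 <- match(common, t1); i2 <- match(common, t2)
  oracle <- sqrt(sum((c1$C_p_nM[i1] - c2$C_p_nM[i2])^2) +
                   sum((c1$C_m_nM[i1] - c2$C_m_nM[i2])^2))
  expect_equal(curve_distance(c1, c2), oracle, tolerance = 1e-12)
  # symmetry and the triangle inequality on a shared grid
  c3 <- conc_series(tt, c(3, 8, 30, 2), c(9, 1, 5, 2))
  expect_equal(curve_distance(a, c3), curve_distance(c3, a))
  expect_lte(curve_distance(a, c3),
             curve_distance(a, b) + curve_distance(b, c3))
  far <- conc_series(c(100, 101), c(1, 1), c(1, 1))
  expect_error(curve_distance(a, far), "no common time points")
})

test_that("the PK summary is internally consistent and serializes", {
  sim <- simulate_losartan(losartan_params(), 50, t_end = 24,
                           output_step = 0.02, genotype_label = "GG/CC")
  pk <- pk_summary(sim)
  expect_gte(pk$AUC0inf_losartan_nmolh_L, auc_x_y(sim, 0, 12))
  expect_equal(pk$CLF_L_h,
               cl_over_f(50, pk$AUC0inf_losartan_nmolh_L))
  expect_true(all(c("Cmax_losartan_nM", "AUC0inf_E3174_nmolh_L",
                    "thalf_E3174_h") %in% names(pk)))
  expect_gt(pk$tmax_E3174_h, pk$tmax_losartan_h)
})
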