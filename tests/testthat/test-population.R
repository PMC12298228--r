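test_that("population draws honour the spec: size, determinism, degeneracy", {
  spec <- population_spec(n_per_genotype = 100, sd_fraction = 0.1,
                          seed = 21)
  pop <- sample_population(spec, compute_pk = FALSE)
  # 100 draws for each of 3 genotypes: 300 parameter sets
  sets <- unique(pop$draws[c("draw_id", "genotype")])
  expect_identical(nrow(sets), 300L)
  expect_true(all(pop$draws$value > 0))
  pop2 <- sample_population(spec, compute_pk = FALSE)
  expect_identical(pop$draws, pop2$draws)
  # degenerate spread: every draw equals the median
  pop0 <- sample_population(population_spec(n_per_genotype = 5,
                                            sd_fraction = 0,
                                            genotypes = "GG/CC",
                                            seed = 1),
                            compute_pk = FALSE)
  med <- genotype_params("GG/CC")
  for (pm in unique(pop0$draws$parameter))
    expect_equal(unique(pop0$draws$value[pop0$draws$parameter == pm]),
                 med[[pm]])
  expect_error(population_spec(n_per_genotype = 1), "n_per_genotype")
  expect_error(population_spec(sd_fraction = 1.2), "sd_fraction")
})

test_that("draw means concentrate on the median at large n", {
  spec <- population_spec(n_per_genotype = 10000, sd_fraction = 0.1,
                          genotypes = "GG/CC", seed = 22)
  pop <- sample_population(spec, compute_pk = FALSE)
  med <- genotype_params("GG/CC")
  for (pm in c("CL_p", "Vp_1", "k_m")) {
    v <- pop$draws$value[pop$draws$parameter == pm]
    expect_equal(mean(v), med[[pm]], tolerance = 0.005)
    expect_equal(stats::sd(v) / mean(v), 0.1, tolerance = 0.05)
  }
})

test_that("matched mode shares global draws but not genotype-specific ones", {
  spec <- population_spec(n_per_genotype = 10, seed = 23)
  pop <- sample_population(spec, compute_pk = FALSE, matched = TRUE)
  d <- pop$draws
  clp <- split(d$value[d$parameter == "CL_p"],
               d$genotype[d$parameter == "CL_p"])
  expect_identical(clp[["GG/CC"]], clp[["TT/TT"]])
  kei <- split(d$value[d$parameter == "k_ent_int"],
               d$genotype[d$parameter == "k_ent_int"])
  expect_false(identical(kei[["GG/CC"]], kei[["TT/TT"]]))
})

test_that("the gated comparison reports the Bonferroni cutoff and decisions", {
  set.seed(31)
  # identical groups: nothing significant
  x <- rep(c(5, 6, 7, 8, 9), 3)
  g <- rep(c("A", "B", "C"), each = 5)
  rep0 <- compare_groups(x, g)
  expect_equal(rep0$cutoff, 0.05 / 3, tolerance = 1e-12)
  expect_false(any(rep0$pairwise$significant))
  # two groups shifted by 5 pooled SDs at n = 100: decisively significant,
  # and the decision agrees with a permutation-test oracle
  a <- rnorm(100, 0, 1); b <- rnorm(100, 5, 1)
  rep1 <- compare_groups(c(a, b), rep(c("A", "B"), each = 100))
  expect_true(all(rep1$pairwise$significant))
  obs_diff <- abs(mean(a) - mean(b))
  pooled <- c(a, b)
  perm <- replicate(500, {
    idx <- sample(200, 100)
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  })
  perm_p <- mean(perm >= obs_diff)
  expect_identical(perm_p < rep1$cutoff, rep1$pairwise$significant[1])
  expect_error(compare_groups(c(1, 2, 3, 4), c("A", "A", "A", "B")),
               "at least 3")
})

test_that("the comparison report serializes to JSON", {
  set.seed(32)
  rep1 <- compare_groups(rnorm(30), rep(c("A", "B", "C"), each = 10))
  path <- tempfile(fileext = ".json")
  write_comparison(rep1, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$cutoff, rep1$cutoff)
  expect_identical(back$omnibus$test, "kruskal-wallis")
  expect_identical(nrow(back$pairwise), 3L)
  unlink(path)
})

test_that("population PK reproduces the qualitative genotype ordering", {
  spec <- population_spec(n_per_genotype = 10, seed = 33)
  pop <- sample_population(spec, dose = 50, t_end = 24,
                           output_step = 0.05)
  med <- stats::aggregate(pop$pk[c("Cmax_losartan_nM", "tmax_losartan_h",
                                   "tmax_E3174_h")],
                          list(genotype = pop$pk$genotype), stats::median)
  tt <- med[med$genotype == "TT/TT", ]
  others <- med[med$genotype != "TT/TT", ]
  expect_true(all(tt$Cmax_losartan_nM > others$Cmax_losartan_nM))
  expect_true(all(tt$tmax_losartan_h <= others$tmax_losartan_h))
  expect_true(all(tt$tmax_E3174_h < others$tmax_E3174_h))
})

test_that("population outputs write to long-format CSV", {
  pop <- sample_population(population_spec(n_per_genotype = 3, seed = 34),
                           compute_pk = FALSE)
  path <- tempfile(fileext = ".csv")
  write_population(pop, path)
  expect_identical(readLines(path, n = 1L),
                   "draw_id,genotype,parameter,value")
  back <- utils::read.csv(path)
  expect_identical(nrow(back), nrow(pop$draws))
  unlink(path)
})
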