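test_that("generate_design enumerates the full factorial", {
  expect_equal(nrow(generate_design(design_spec())), 15 * 2 * 7 * 2)
  expect_equal(
    nrow(generate_design(design_spec(ages = c(3, 10, 24, 36, 51, 66)))),
    15 * 2 * 6 * 2
  )
  d <- generate_design(design_spec(n_lines = 3, replicates_per_cell = 1))
  expect_false(anyDuplicated(d$sample_id) > 0)
})

test_that("design and effect specifications reject invalid values", {
  expect_error(design_spec(n_lines = 1), class = "flymetab_config_error")
  expect_error(design_spec(ages = c(10, 3)), class = "flymetab_config_error")
  expect_error(design_spec(overlap_frac = 1.2), class = "flymetab_config_error")
  expect_error(effect_spec(frac_sex = -0.1), class = "flymetab_config_error")
  expect_error(effect_spec(sigma2_within = 0), class = "flymetab_config_error")
  expect_error(
    effect_spec(missingness = list(quantile = 1.5, steepness = 1)),
    class = "flymetab_config_error"
  )
})

test_that("same seed gives identical tables, different seeds differ", {
  spec <- design_spec(n_lines = 3, columns = c(AE = 20, C18 = 25))
  a <- generate_table(spec, effect_spec(seed = 5))
  b <- generate_table(spec, effect_spec(seed = 5))
  c <- generate_table(spec, effect_spec(seed = 6))
  expect_identical(a$table$intensities, b$table$intensities)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$table$intensities, c$table$intensities))
})

test_that("ground truth flags exactly the nonzero planted magnitudes", {
  sim <- generate_table(
    design_spec(columns = c(AE = 400), overlap_frac = 0),
    effect_spec(seed = 2)
  )
  tr <- sim$truth
  expect_true(all((tr$age_sign != 0) == (tr$age_mag != 0)))
  expect_true(all(tr$has_genotype == (tr$sigma2_between_true > 0)))
  expect_true(all(tr$true_icc[!tr$has_genotype] == 0))
  expect_true(all(tr$true_icc >= 0 & tr$true_icc < 1))
})

test_that("noise-only generation matches the configured residual variance", {
  sim <- generate_table(
    design_spec(columns = c(AE = 50), overlap_frac = 0),
    effect_spec(
      frac_age_up = 0, frac_age_down = 0, frac_sex = 0, frac_genotype = 0,
      frac_age_sex = 0, frac_age_geno = 0, frac_sex_geno = 0,
      sigma2_between = 0, sigma2_within = 2, seed = 3
    )
  )
  v <- apply(log(sim$table$intensities), 1, var) # 420 samples per feature
  expect_true(all(abs(v - 2) / 2 < 0.30))
  expect_lt(abs(mean(v) - 2) / 2, 0.05)
})

test_that("true intraclass correlation is recorded from the variance ratio", {
  sim <- generate_table(
    design_spec(n_lines = 3, ages = c(3, 10), columns = c(AE = 10),
                overlap_frac = 0),
    effect_spec(frac_genotype = 1, sigma2_between = 1, sigma2_within = 3,
                seed = 1)
  )
  expect_true(all(sim$truth$true_icc == 0.25))
})

test_that("realized between-line variance is unbiased for sigma2_between", {
  sim <- generate_table(
    design_spec(columns = c(AE = 600), overlap_frac = 0),
    effect_spec(frac_genotype = 1, sigma2_between = 0.5, seed = 8)
  )
  expect_lt(abs(mean(sim$truth$sigma2_between_realized) - 0.5) / 0.5, 0.05)
})

test_that("overlapping features share ground truth with independent noise", {
  spec <- design_spec(n_lines = 3, columns = c(AE = 40, C18 = 50),
                      overlap_frac = 0.30)
  sim <- generate_table(spec, effect_spec(seed = 4))
  tr <- sim$truth
  shared <- tr |>
    dplyr::count(chem_id) |>
    dplyr::filter(n == 2)
  expect_equal(nrow(shared), round(0.30 * 40))
  pair <- tr[tr$chem_id == shared$chem_id[1], ]
  expect_equal(pair$age_sign[1], pair$age_sign[2])
  expect_equal(pair$sex_effect[1], pair$sex_effect[2])
  expect_equal(pair$line_effects[1], pair$line_effects[2])
  x <- sim$table$intensities[match(pair$feature_id, rownames(sim$table$intensities)), ]
  expect_false(identical(x[1, ], x[2, ])) # independent residual noise
})

test_that("missingness limits behave as censoring and as uniform dropout", {
  spec <- design_spec(n_lines = 5, columns = c(AE = 100), overlap_frac = 0)
  base_eff <- effect_spec(seed = 9)

  # hard threshold: exactly the lowest 10% of values censored
  eff_inf <- effect_spec(missingness = list(quantile = 0.1, steepness = Inf),
                         seed = 9)
  tab <- generate_table(spec, base_eff)$table
  miss <- inject_missingness(tab, eff_inf)
  n_cells <- length(tab$intensities)
  expect_equal(sum(is.na(miss$intensities)), floor(0.1 * n_cells))
  cutoff <- quantile(tab$intensities, 0.1, names = FALSE)
  expect_true(all(tab$intensities[is.na(miss$intensities)] <= cutoff * 1.0001))

  # steepness 0: dropout independent of intensity (flat rate 1/2)
  eff0 <- effect_spec(missingness = list(quantile = 0.5, steepness = 0), seed = 9)
  miss0 <- inject_missingness(tab, eff0)
  gone <- is.na(miss0$intensities)
  expect_lt(abs(mean(gone) - 0.5), 0.02)
  lo <- tab$intensities < median(tab$intensities)
  expect_lt(abs(mean(gone[lo]) - mean(gone[!lo])), 0.02)

  # default steepness: realized rate within 2 points of the target quantile
  eff_d <- effect_spec(seed = 9) # quantile 0.05, steepness 10
  miss_d <- inject_missingness(tab, eff_d)
  expect_gt(n_cells, 1e4)
  expect_lt(abs(mean(is.na(miss_d$intensities)) - 0.05), 0.02)
})

test_that("plant_pathways rewrites host m/z and handles edge cases", {
  sim <- generate_table(
    design_spec(n_lines = 3, columns = c(AE = 60), overlap_frac = 0),
    effect_spec(frac_age_up = 0.3, seed = 6)
  )
  p <- plant_pathways(sim$table, sim$truth, n_pathways = 3,
                      size_range = c(4, 6), seed = 2)
  planted <- !is.na(p$truth$compound_id)
  expect_gt(sum(planted), 0)
  masses <- p$db$compounds$mass[match(
    p$truth$compound_id[planted], p$db$compounds$compound_id
  )]
  got_mz <- p$table$feature_meta$mz[match(
    p$truth$feature_id[planted], p$table$feature_meta$feature_id
  )]
  expect_equal(got_mz, masses + 1.007276)
  expect_true(all(lengths(p$db$members) >= 4 & lengths(p$db$members) <= 6))

  none <- plant_pathways(sim$table, sim$truth, n_pathways = 0)
  expect_equal(nrow(none$db$compounds), 0)
  expect_identical(none$truth, sim$truth)

  expect_error(
    plant_pathways(sim$table, sim$truth, n_pathways = 20,
                   size_range = c(50, 60), seed = 2),
    class = "flymetab_config_error"
  )
})
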