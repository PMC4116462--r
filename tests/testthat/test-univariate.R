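meta_360 <- function() {
  d <- generate_design(design_spec(ages = c(3, 10, 24, 36, 51, 66)))
  d
}

test_that("design encoding has the expected block structure and full rank", {
  enc <- encode_design(meta_360(), model_spec())
  a <- attr(terms(~ age + sex + line + age:sex + age:line + sex:line), "term.labels")
  cols_of <- function(ti) sum(enc$assign == ti)
  expect_equal(cols_of(match("age", a)), 5) # 6 levels - 1
  expect_equal(cols_of(match("sex", a)), 1)
  expect_equal(cols_of(match("line", a)), 14) # 15 lines - 1
  expect_equal(cols_of(match("age:line", a)), 70) # 5 x 14
  expect_equal(qr(enc$X)$rank, ncol(enc$X))
  expect_false(is.na(enc$age_linear_col))
})

test_that("rank-deficient designs are rejected with the aliased terms named", {
  # sex perfectly confounded with line: the sex contrast is aliased
  meta <- tibble::tibble(
    line = rep(c("L01", "L02"), each = 12),
    sex = rep(c("F", "M"), each = 12),
    age = rep(c(3, 10, 24), 8)
  )
  expect_error(encode_design(meta, model_spec()), "aliased")
})

test_that("single-feature fits agree with normal equations and lrtest", {
  meta <- generate_design(design_spec(n_lines = 4, ages = c(3, 10, 24)))
  enc <- encode_design(meta, model_spec(drop_ages = numeric(0)))
  set.seed(21)
  y <- rnorm(nrow(enc$X))
  fit <- fit_feature(y, enc)

  beta_oracle <- solve(crossprod(enc$X), crossprod(enc$X, y))
  expect_equal(unname(fit$coefficients), unname(drop(beta_oracle)),
               tolerance = 1e-8)

  # genotype likelihood-ratio statistic against lmtest::lrtest on explicit
  # nested lm fits over the same column spaces (full design vs full minus
  # the genotype block); the asymptotic chi-squared p matches lrtest, the
  # decision p uses the exact F reference
  line_term <- match("line", enc$term_labels)
  Xf <- enc$X
  Xr <- Xf[, enc$assign != line_term, drop = FALSE]
  lr <- lmtest::lrtest(lm(y ~ Xr - 1), lm(y ~ Xf - 1))
  ours <- fit$terms[fit$terms$factor == "genotype", ]
  expect_equal(ours$statistic, lr$Chisq[2], tolerance = 1e-6)
  expect_equal(ours$p_chisq, lr$`Pr(>Chisq)`[2], tolerance = 1e-6)
  expect_equal(ours$df, lr$Df[2])
  # exact reference agrees with the drop-term F test computed by anova()
  av <- anova(lm(y ~ Xr - 1), lm(y ~ Xf - 1))
  expect_equal(ours$p, av$`Pr(>F)`[2], tolerance = 1e-10)
})

test_that("null responses give uniform per-term p-values", {
  sim <- small_study(seed = 31, n_features = 1500)
  tab <- sim$table
  tab$intensities <- log(tab$intensities)
  tab$log_scale <- TRUE
  res <- fit_features(tab, model_spec(drop_ages = 81))
  for (fac in c("age", "sex", "genotype", "age_geno")) {
    p <- res$p[res$factor == fac]
    ks <- suppressWarnings(stats::ks.test(p, "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("a planted two-sigma sex shift is detected overwhelmingly", {
  meta <- meta_360()
  enc <- encode_design(meta, model_spec())
  set.seed(5)
  y <- rnorm(nrow(enc$X)) + ifelse(meta$sex == "F", 1, -1) # 2 sigma gap
  fit <- fit_feature(y, enc)
  expect_lt(fit$terms$p[fit$terms$factor == "sex"], 1e-6)
})

test_that("direction labels follow the linear trend contrast", {
  meta <- meta_360()
  enc <- encode_design(meta, model_spec())
  ages <- sort(unique(meta$age))
  rank_z <- (match(meta$age, ages) - 3.5) / 5

  up <- fit_feature(2 * rank_z + rnorm(nrow(enc$X), 0, 0.01), enc)
  expect_equal(unname(classify_direction(up)["age"]), "up")
  down <- fit_feature(-2 * rank_z + rnorm(nrow(enc$X), 0, 0.01), enc)
  expect_equal(unname(classify_direction(down)["age"]), "down")

  # symmetric hump: orthogonal to the linear contrast, hence "flat"
  hump <- -(rank_z^2)
  hump <- hump - mean(hump)
  # project out any numeric leakage into the linear contrast column
  xl <- enc$X[, enc$age_linear_col]
  hump <- hump - drop(crossprod(xl, hump) / crossprod(xl)) * xl
  flat <- fit_feature(hump, enc)
  expect_equal(unname(classify_direction(flat)["age"]), "flat")

  males <- fit_feature(ifelse(meta$sex == "M", 1, 0) + rnorm(nrow(enc$X), 0, 0.01), enc)
  expect_equal(unname(classify_direction(males)["sex"]), "M")
})

test_that("degenerate nesting with no dropped columns errors", {
  meta <- meta_360()
  enc <- encode_design(meta, model_spec())
  enc$term_labels <- c(enc$term_labels, "phantom")
  enc$factor_of_term <- c(enc$factor_of_term, phantom = "genotype")
  expect_error(fit_feature(rnorm(nrow(enc$X)), enc), "degenerate nesting")
})

test_that("Benjamini-Hochberg step-up matches the hand-applied rule", {
  expect_equal(
    bh_adjust(c(0.001, 0.004, 0.02, 0.8), alpha = 0.01),
    c(TRUE, TRUE, FALSE, FALSE)
  )
  expect_true(all(bh_adjust(rep(0.005, 10), alpha = 0.01)))
  expect_false(any(bh_adjust(rep(1, 10), alpha = 0.01)))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  # decisions are monotone in p
  p <- c(0.001, 0.002, 0.005, 0.3, 0.9)
  d <- bh_adjust(p, 0.05)
  expect_true(all(diff(as.integer(d[order(p)])) <= 0))
})

test_that("age-81 removal leaves the balanced design minus one age", {
  sim <- small_study(seed = 2, n_features = 5)
  spec7 <- design_spec(columns = c(AE = 5), overlap_frac = 0)
  expect_equal(nrow(generate_design(spec7)), 420)
  res <- fit_features(sim$table, model_spec(drop_ages = 81))
  # identical to fitting the manually filtered table
  keep <- !(sim$table$sample_meta$age %in% 81)
  res2 <- fit_features(ft_subset(sim$table, samples = keep),
                       model_spec(drop_ages = numeric(0)))
  expect_equal(res$p, res2$p)
})

test_that("factor summary counts planted effects and reports percentages", {
  sim <- small_study(
    seed = 13, n_features = 400,
    fracs = list(frac_age_up = 0.10)
  )
  tab <- sim$table
  tab$intensities <- log(tab$intensities)
  tab$log_scale <- TRUE
  res <- fit_features(tab, model_spec())
  s <- summarize_table1(res)
  up <- s$n_AE[s$parameter == "Increase with age"]
  expect_gt(up / 400, 0.07)
  expect_lt(up / 400, 0.13)
  expect_equal(s$pct_AE, 100 * s$n_AE / 400)
  # and near-zero counts for unplanted factors
  expect_lt(s$n_AE[s$parameter == "Age x sex"] / 400, 0.02)
})

test_that("the optional three-way interaction term is honoured", {
  meta <- generate_design(design_spec(n_lines = 3, ages = c(3, 10, 24)))
  enc3 <- encode_design(meta, model_spec(three_way = TRUE, drop_ages = numeric(0)))
  enc2 <- encode_design(meta, model_spec(drop_ages = numeric(0)))
  expect_gt(ncol(enc3$X), ncol(enc2$X))
  expect_true("age_sex_geno" %in% enc3$factor_of_term)
  y <- rnorm(nrow(enc3$X))
  fit <- fit_feature(y, enc3, model_spec(three_way = TRUE))
  expect_true("age_sex_geno" %in% fit$terms$factor)
})
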