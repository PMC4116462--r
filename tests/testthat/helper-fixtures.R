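# Fixtures built in code. All values deterministic unless a seed is taken.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal valid table: nf features x ns samples, constant-free values.
tiny_table <- function(nf = 4, ns = 6, log_scale = FALSE) {
  m <- matrix(seq_len(nf * ns) + 100, nf, ns)
  feature_table(
    m,
    tibble::tibble(
      feature_id = sprintf("f%02d", seq_len(nf)),
      mz = seq(100, 200, length.out = nf),
      rt = seq(30, 60, length.out = nf),
      column = "AE"
    ),
    tibble::tibble(
      sample_id = sprintf("s%02d", seq_len(ns)),
      line = rep(c("L01", "L02"), length.out = ns),
      sex = rep(c("F", "M"), each = ceiling(ns / 2))[seq_len(ns)],
      age = 3,
      replicate = rep(1:2, length.out = ns)
    ),
    log_scale = log_scale
  )
}

# Hand-built six-feature QC fixture over 40 samples (20 F + 20 M).
# Designed so that exactly one feature fails each of the SNR, sex-wise
# missingness, and m/z filters, and three survive:
#   qf1  passes everything (low CV, mz 200, complete)
#   qf2  passes with exactly 5% missing among females (boundary: kept)
#   qf3  passes, strongly correlated with qf1 (imputation neighbour)
#   qf4  fails SNR (alternating 10 / 1000 -> mean/SD ~ 1)
#   qf5  fails missingness (15% missing among females)
#   qf6  fails m/z (mz = 900, strict < 900 removes it)
qc_fixture <- function() {
  ns <- 40
  base <- 1000 + 2 * sin(seq_len(ns)) # CV ~0.14%, SNR >> 15
  m <- rbind(
    qf1 = base,
    qf2 = base * 1.2,
    qf3 = base + 5, # exact linear function of qf1
    qf4 = rep(c(10, 1000), ns / 2),
    qf5 = base * 0.8,
    qf6 = base * 2
  )
  sex <- rep(c("F", "M"), each = ns / 2)
  m["qf2", 1] <- NA # 1/20 female samples = 5% (boundary, kept)
  m["qf5", 2:4] <- NA # 3/20 female samples = 15% (removed)
  feature_table(
    m,
    tibble::tibble(
      feature_id = rownames(m),
      mz = c(200, 150, 300, 400, 500, 900),
      rt = 10 * seq_len(6),
      column = "AE"
    ),
    tibble::tibble(
      sample_id = sprintf("s%02d", seq_len(ns)),
      line = rep(sprintf("L%02d", 1:4), each = 10),
      sex = sex,
      age = rep(c(3, 10), 20),
      replicate = rep(1:2, 20)
    )
  )
}

# Balanced one-random-effect sample: n_lines lines x n_per obs.
one_way_sample <- function(n_lines, n_per, s2b, s2w, seed) {
  set.seed(seed)
  line <- rep(sprintf("L%02d", seq_len(n_lines)), each = n_per)
  y <- rep(rnorm(n_lines, 0, sqrt(s2b)), each = n_per) +
    rnorm(n_lines * n_per, 0, sqrt(s2w))
  list(
    y = y,
    meta = tibble::tibble(
      line = line,
      sex = rep_len(c("F", "M"), length(line)),
      age = rep_len(c(3, 10, 24), length(line))
    )
  )
}

# Small simulated study used by several univariate tests.
small_study <- function(seed = 1, n_features = 200, fixed_effect = 2,
                        fracs = list()) {
  spec <- design_spec(columns = c(AE = n_features), overlap_frac = 0)
  defaults <- list(
    frac_age_up = 0, frac_age_down = 0, frac_sex = 0, frac_genotype = 0,
    frac_age_sex = 0, frac_age_geno = 0, frac_sex_geno = 0
  )
  defaults[names(fracs)] <- fracs
  eff <- do.call(effect_spec, c(defaults, list(
    effect_size_dist = list(dist = "fixed", value = fixed_effect),
    sigma2_between = 1, sigma2_within = 1, seed = seed
  )))
  generate_table(spec, eff)
}

expect_tibble_equal <- function(a, b, tol = 1e-12) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
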