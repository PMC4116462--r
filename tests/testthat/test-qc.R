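make_table <- function(m, mz = NULL, sex = NULL) {
  nf <- nrow(m)
  ns <- ncol(m)
  feature_table(
    m,
    tibble::tibble(
      feature_id = sprintf("f%02d", seq_len(nf)),
      mz = mz %||% rep(200, nf),
      rt = seq_len(nf),
      column = "AE"
    ),
    tibble::tibble(
      sample_id = sprintf("s%02d", seq_len(ns)),
      line = "L01",
      sex = sex %||% rep(c("F", "M"), length.out = ns),
      age = 3,
      replicate = 1
    )
  )
}

test_that("signal-to-noise filter is inclusive at the threshold", {
  # integer triples make mean and SD exact in floating point:
  # f1: mean 30, SD 2 -> SNR 15 (kept); f2: mean 14, SD 1 -> SNR 14 (removed)
  f1 <- c(28, 30, 32)
  f2 <- c(13, 14, 15)
  stopifnot(mean(f1) / sd(f1) == 15, mean(f2) / sd(f2) == 14)
  tab <- make_table(rbind(f1, f2))
  out <- filter_snr(tab, qc_config(snr_threshold = 15))
  expect_equal(out$table$feature_meta$feature_id, "f01")
  expect_equal(out$report$removed, 1L)
})

test_that("constant features have infinite SNR and are kept but flagged", {
  tab <- make_table(rbind(rep(5, 4), c(1, 50, 1, 50)))
  out <- filter_snr(tab, qc_config(snr_threshold = 15))
  expect_equal(out$table$feature_meta$feature_id, "f01")
  expect_match(out$report$detail, "1 constant feature")
})

test_that("features with fewer than two observed cells are removed and logged", {
  m <- rbind(c(10, NA, NA, NA), c(10, 10.1, 9.9, 10))
  out <- filter_snr(make_table(m), qc_config())
  expect_equal(out$table$feature_meta$feature_id, "f02")
  expect_match(out$report$detail, "1 with <2 observed cells removed")
})

test_that("log transform honours the base and rejects nonpositive values", {
  tab <- make_table(rbind(c(exp(1), exp(2), exp(3), exp(4))))
  expect_equal(
    log_transform(tab, qc_config())$intensities[1, ],
    setNames(1:4, tab$sample_meta$sample_id)
  )
  tab2 <- make_table(rbind(c(8, 8, 8, 8)))
  expect_equal(unname(log_transform(tab2, qc_config(log_base = "2"))$intensities[1, 1]), 3)
  tab3 <- make_table(rbind(c(0, 1, 2, 3)))
  expect_error(log_transform(tab3, qc_config()), "f01")
})

test_that("sex-wise missingness filter applies a strict 5% bound per sex", {
  ns <- 40
  sex <- rep(c("F", "M"), each = 20)
  m <- matrix(100 + seq_len(3 * ns) %% 7, 3, ns)
  m[1, 1:2] <- NA # 10% of females -> removed
  m[2, c(1, 21)] <- NA # exactly 5% in each sex -> kept
  # f3: about 4% would need 25 samples; with 20 per sex use 1 missing in males only
  m[3, 21] <- NA # 5% males, 0% females -> kept
  tab <- make_table(m, sex = sex)
  out <- filter_missing_by_sex(log_transform(tab, qc_config()), qc_config())
  expect_equal(out$table$feature_meta$feature_id, c("f02", "f03"))
  expect_equal(out$report$removed, 1L)
})

test_that("m/z filter is strict at the upper bound", {
  mz <- c(899.9999, 900.0, 147.0764)
  tab <- make_table(matrix(100, 3, 4), mz = mz)
  out <- filter_mz(tab, qc_config())
  expect_setequal(out$table$feature_meta$mz, c(899.9999, 147.0764))
  fm <- tab$feature_meta
  fm$mz[2] <- NA
  tab$feature_meta <- fm
  expect_error(filter_mz(tab, qc_config()), "missing m/z")
})

test_that("sample centering gives zero means, is idempotent, and degenerates", {
  tab <- log_transform(tiny_table(4, 6), qc_config())
  cen <- center_samples(tab)
  expect_true(all(abs(colMeans(cen$intensities)) < 1e-10))
  again <- center_samples(cen)
  expect_equal(again$intensities, cen$intensities, tolerance = 1e-10)
  single <- log_transform(tiny_table(1, 3), qc_config())
  expect_true(all(center_samples(single)$intensities == 0))
})

test_that("the six-step cascade removes exactly the designed failures", {
  fx <- qc_fixture()
  out <- run_qc(fx, qc_config())
  expect_equal(sort(out$table$feature_meta$feature_id), c("qf1", "qf2", "qf3"))
  rep <- out$report
  expect_equal(rep$removed[rep$action == "snr_filter"], 1L)
  expect_equal(rep$removed[rep$action == "missingness_filter"], 1L)
  expect_equal(rep$removed[rep$action == "mz_filter"], 1L)
  expect_equal(rep$step, 1:6)
  expect_equal(attr(rep, "final_features"), 3L)
  # bookkeeping: features_in/out chain across steps
  expect_equal(rep$features_in[1], 6L)
  expect_equal(rep$features_out[nrow(rep)], 3L)
})

test_that("after the cascade no missing cells remain and all m/z < 900", {
  fx <- qc_fixture()
  out <- run_qc(fx, qc_config())
  expect_false(anyNA(out$table$intensities))
  expect_true(all(out$table$feature_meta$mz < 900))
  expect_true(out$table$log_scale)
})

test_that("step order matters: imputing before the missingness filter rescues a feature", {
  fx <- qc_fixture()
  cfg <- qc_config()
  # permuted cascade: SNR -> log -> impute -> missingness filter -> mz -> center
  s1 <- filter_snr(fx, cfg)
  t2 <- log_transform(s1$table, cfg)
  s4 <- impute_ls(t2, cfg)
  s3 <- filter_missing_by_sex(s4$table, cfg)
  s5 <- filter_mz(s3$table, cfg)
  permuted_survivors <- s5$table$feature_meta$feature_id
  proper <- run_qc(fx, cfg)$table$feature_meta$feature_id
  expect_false(setequal(permuted_survivors, proper))
  expect_true("qf5" %in% permuted_survivors) # rescued only under the wrong order
})

test_that("an all-pass table and an empty table pass through unchanged", {
  good <- qc_fixture()
  keep <- c("qf1", "qf3") # complete, low-CV, low-mz features
  good <- ft_subset(good, features = keep)
  out <- run_qc(good, qc_config())
  expect_equal(sum(out$report$removed), 0L)
  expect_equal(nrow(out$table$intensities), 2)

  empty <- ft_subset(qc_fixture(), features = integer(0))
  oute <- run_qc(empty, qc_config())
  expect_equal(nrow(oute$table$intensities), 0)
  expect_equal(nrow(oute$report), 0)
})
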