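#' Quality-control configuration
#'
#' Parameters of the six-step QC cascade: signal-to-noise filtering on raw
#' intensities, log transform, sex-wise missingness filtering, least-squares
#' imputation, mass-charge filtering, and per-sample centering.
#'
#' @param snr_threshold Minimum signal-to-noise ratio (mean / sample SD of
#'   the observed raw intensities of a feature); features below are removed,
#'   at or above are kept.
#' @param max_missing_frac_per_sex A feature is removed when its missing
#'   fraction exceeds this value in either sex (strictly greater).
#' @param mz_max Features with m/z at or above this value are removed
#'   (strict `<` keeps).
#' @param impute_neighbors Number of correlated neighbour features used by
#'   the least-squares imputation.
#' @param log_base Base of the log transform: `"natural"`, `"2"` or `"10"`.
#' @return A `qc_config` list.
#' @export
qc_config <- function(snr_threshold = 15,
                      max_missing_frac_per_sex = 0.05,
                      mz_max = 900,
                      impute_neighbors = 10,
                      log_base = c("natural", "2", "10")) {
  if (snr_threshold <= 0) abort("snr_threshold must be > 0", class = "flymetab_config_error")
  if (max_missing_frac_per_sex < 0 || max_missing_frac_per_sex >= 1) {
    abort("max_missing_frac_per_sex must lie in [0, 1)", class = "flymetab_config_error")
  }
  if (mz_max <= 85) abort("mz_max must exceed 85", class = "flymetab_config_error")
  if (impute_neighbors < 1) abort("impute_neighbors must be >= 1", class = "flymetab_config_error")
  structure(
    list(
      snr_threshold = snr_threshold,
      max_missing_frac_per_sex = max_missing_frac_per_sex,
      mz_max = mz_max,
      impute_neighbors = as.integer(impute_neighbors),
      log_base = match.arg(log_base)
    ),
    class = "qc_config"
  )
}

qc_entry <- function(step, action, removed, detail = NA_character_) {
  tibble::tibble(step = step, action = action, removed = as.integer(removed), detail = detail)
}

#' Filter features by signal-to-noise ratio
#'
#' SNR of a feature is mean / sample standard deviation over its observed
#' raw-scale cells; features with SNR at or above the threshold are kept.
#' Constant features (SD 0, infinite SNR) are kept and flagged; features
#' with fewer than two observed cells have no defined SD and are removed.
#'
#' @param table A raw-scale [feature_table()].
#' @param cfg A [qc_config()].
#' @return List: `table` (filtered) and `report` (one-row tibble).
#' @export
filter_snr <- function(table, cfg = qc_config()) {
  stopifnot(inherits(table, "feature_table"))
  if (table$log_scale) abort("filter_snr expects raw-scale intensities")
  x <- table$intensities
  n_obs <- rowSums(!is.na(x))
  mu <- rowMeans(x, na.rm = TRUE)
  s <- apply(x, 1, sd, na.rm = TRUE)
  snr <- ifelse(s == 0, Inf, mu / s)
  keep <- n_obs >= 2 & snr >= cfg$snr_threshold
  keep[is.na(keep)] <- FALSE
  n_const <- sum(s == 0 & n_obs >= 2, na.rm = TRUE)
  detail <- sprintf(
    "snr >= %g; %d constant feature(s) kept; %d with <2 observed cells removed",
    cfg$snr_threshold, n_const, sum(n_obs < 2)
  )
  list(
    table = ft_subset(table, features = keep),
    report = qc_entry(1L, "snr_filter", sum(!keep), detail)
  )
}

#' Log-transform intensities
#'
#' @param table A raw-scale [feature_table()] with strictly positive
#'   observed intensities.
#' @param cfg A [qc_config()]; `log_base` selects the base.
#' @return The table on the log scale; missing cells stay missing.
#' @export
log_transform <- function(table, cfg = qc_config()) {
  stopifnot(inherits(table, "feature_table"))
  if (table$log_scale) abort("table is already log transformed")
  x <- table$intensities
  bad <- which(x <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "nonpositive intensity at feature %s, sample %s",
      rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]]
    ))
  }
  base <- switch(cfg$log_base, natural = exp(1), `2` = 2, `10` = 10)
  table$intensities <- log(x, base = base)
  table$log_scale <- TRUE
  table
}

#' Filter features by sex-wise missingness
#'
#' A feature is removed iff its fraction of missing cells exceeds the
#' configured limit among all samples of either sex (the bound is strict:
#' a fraction exactly at the limit keeps the feature).
#'
#' @param table A [feature_table()] whose sample metadata includes sex.
#' @param cfg A [qc_config()].
#' @return List: `table` and `report`.
#' @export
filter_missing_by_sex <- function(table, cfg = qc_config()) {
  stopifnot(inherits(table, "feature_table"))
  sexes <- unique(table$sample_meta$sex)
  if (length(sexes) < 1) abort("sample metadata has no sex labels")
  miss_frac <- vapply(sexes, function(sx) {
    idx <- table$sample_meta$sex == sx
    if (!any(idx)) abort(sprintf("no samples for sex %s", sx))
    rowMeans(is.na(table$intensities[, idx, drop = FALSE]))
  }, numeric(nrow(table$intensities)))
  miss_frac <- matrix(miss_frac, nrow = nrow(table$intensities))
  keep <- apply(miss_frac, 1, max) <= cfg$max_missing_frac_per_sex
  list(
    table = ft_subset(table, features = keep),
    report = qc_entry(
      3L, "missingness_filter", sum(!keep),
      sprintf("missing > %g in either sex", cfg$max_missing_frac_per_sex)
    )
  )
}

#' Filter features by mass-charge ratio
#'
#' Keeps features with m/z strictly below `mz_max` (acquisition parameters
#' are optimised for the low-mass range; higher masses are unreliable).
#'
#' @param table A [feature_table()].
#' @param cfg A [qc_config()].
#' @return List: `table` and `report`.
#' @export
filter_mz <- function(table, cfg = qc_config()) {
  stopifnot(inherits(table, "feature_table"))
  mz <- table$feature_meta$mz
  if (anyNA(mz)) abort("feature metadata has missing m/z values")
  keep <- mz < cfg$mz_max
  list(
    table = ft_subset(table, features = keep),
    report = qc_entry(5L, "mz_filter", sum(!keep), sprintf("m/z < %g", cfg$mz_max))
  )
}

#' Center each sample at mean zero
#'
#' @param table A complete (imputed) log-scale [feature_table()].
#' @return The table with every sample's mean over features equal to 0.
#' @export
center_samples <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$intensities
  if (nrow(x) > 0) {
    x <- sweep(x, 2, colMeans(x, na.rm = TRUE), `-`)
  }
  table$intensities <- x
  table
}

#' Run the full quality-control cascade
#'
#' Applies, in order: (1) signal-to-noise filtering on raw intensities,
#' (2) log transform, (3) sex-wise missingness filtering, (4) least-squares
#' imputation of the remaining missing cells, (5) m/z filtering, and
#' (6) per-sample mean centering. The order matters: SNR is a raw-scale
#' quantity, imputation needs the missingness filter to have removed
#' hopeless features first, and centering requires a complete table.
#'
#' @param table A raw-scale [feature_table()].
#' @param cfg A [qc_config()].
#' @return List: `table` (QC'd, log-scale, complete) and `report` (a
#'   `qc_report` tibble with one row per step plus totals).
#' @export
run_qc <- function(table, cfg = qc_config()) {
  stopifnot(inherits(table, "feature_table"))
  n0 <- nrow(table$intensities)
  if (n0 == 0) {
    rep0 <- qc_entry(integer(0), character(0), integer(0))
    return(list(table = table, report = structure(rep0, class = c("qc_report", class(rep0)))))
  }
  s1 <- filter_snr(table, cfg)
  t2 <- log_transform(s1$table, cfg)
  rep2 <- qc_entry(2L, "log_transform", 0L, sprintf("base %s", cfg$log_base))
  s3 <- filter_missing_by_sex(t2, cfg)
  s4 <- impute_ls(s3$table, cfg)
  s5 <- filter_mz(s4$table, cfg)
  t6 <- center_samples(s5$table)
  rep6 <- qc_entry(6L, "center_samples", 0L, "per-sample mean 0")

  report <- dplyr::bind_rows(s1$report, rep2, s3$report, s4$report, s5$report, rep6)
  report$features_in <- NA_integer_
  report$features_out <- NA_integer_
  n_in <- n0
  for (i in seq_len(nrow(report))) {
    report$features_in[i] <- n_in
    n_in <- n_in - report$removed[i]
    report$features_out[i] <- n_in
  }
  attr(report, "final_features") <- nrow(t6$intensities)
  attr(report, "final_samples") <- ncol(t6$intensities)
  class(report) <- c("qc_report", class(report))
  list(table = t6, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf(
      "  step %d %-20s removed %4d  (%s)\n",
      x$step[i], x$action[i], x$removed[i], x$detail[i]
    ))
  }
  cat(sprintf(
    "  final: %d features x %d samples\n",
    attr(x, "final_features"), attr(x, "final_samples")
  ))
  invisible(x)
}
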