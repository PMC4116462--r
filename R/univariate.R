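#' Model specification for the per-feature factorial analysis
#'
#' The per-feature model is an ordinary least-squares fit of log intensity
#' on age (an ordered factor with orthogonal polynomial contrasts), sex,
#' genotype line, and their pairwise interactions, optionally plus the
#' three-way interaction. Age, sex and the age x sex interaction are
#' tested with F-tests; genotype and every genotype-containing interaction
#' with likelihood-ratio tests of nested fits. Significance per factor is
#' controlled by Benjamini-Hochberg FDR across all features, separately
#' for each factor (and chromatography column).
#'
#' @param drop_ages Ages excluded before fitting (late ages with missing
#'   design cells; default 81).
#' @param fdr_alpha FDR level per factor.
#' @param three_way Include the age x sex x genotype term?
#' @return A `model_spec` list.
#' @export
model_spec <- function(drop_ages = 81, fdr_alpha = 0.01, three_way = FALSE) {
  if (fdr_alpha <= 0 || fdr_alpha >= 1) {
    abort("fdr_alpha must lie in (0, 1)", class = "flymetab_config_error")
  }
  structure(
    list(
      drop_ages = drop_ages, fdr_alpha = fdr_alpha,
      three_way = isTRUE(three_way)
    ),
    class = "model_spec"
  )
}

factor_labels <- function(spec) {
  c(
    age = "age", sex = "sex", line = "genotype",
    `age:sex` = "age_sex", `age:line` = "age_geno", `sex:line` = "sex_geno",
    if (spec$three_way) c(`age:sex:line` = "age_sex_geno")
  )
}

#' Encode the factorial design matrix
#'
#' Age is encoded with orthogonal polynomial contrasts over its ordered
#' levels, sex with a single sum contrast column (+1 for the first level,
#' -1 for the second), genotype with sum contrasts (lines - 1 columns);
#' interaction blocks are column products.
#'
#' @param sample_meta Sample metadata tibble (`line`, `sex`, `age`), with
#'   dropped ages already removed.
#' @param spec A [model_spec()].
#' @return A list with the design matrix `X`, the term `assign` vector,
#'   term labels, the factor label of each term, and the column indices of
#'   the linear age contrast and the sex contrast.
#' @export
encode_design <- function(sample_meta, spec = model_spec()) {
  if (any(sample_meta$age %in% spec$drop_ages)) {
    abort("sample metadata still contains dropped ages; remove them first")
  }
  df <- data.frame(
    age = factor(sample_meta$age, levels = sort(unique(sample_meta$age)), ordered = TRUE),
    sex = factor(sample_meta$sex),
    line = factor(sample_meta$line)
  )
  fml <- if (spec$three_way) {
    ~ age + sex + line + age:sex + age:line + sex:line + age:sex:line
  } else {
    ~ age + sex + line + age:sex + age:line + sex:line
  }
  X <- model.matrix(
    fml, df,
    contrasts.arg = list(age = "contr.poly", sex = "contr.sum", line = "contr.sum")
  )
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    abort(paste0(
      "design is rank deficient; aliased columns: ",
      paste(aliased, collapse = ", ")
    ))
  }
  assign <- attr(X, "assign")
  labels <- attr(terms(fml), "term.labels")
  list(
    X = X, assign = assign, term_labels = labels,
    factor_of_term = factor_labels(spec)[labels],
    age_linear_col = match("age.L", colnames(X)),
    sex_col = match("sex1", colnames(X)),
    sex_positive_level = levels(df$sex)[1],
    sex_negative_level = levels(df$sex)[2]
  )
}

# Residual sums of squares of Y (n x p) under the design X, via QR.
rss_of <- function(X, Y) {
  qx <- qr(X)
  res <- qr.resid(qx, Y)
  colSums(res^2)
}

#' Fit the factorial model to every feature
#'
#' Ordinary least squares per feature (vectorised across features through
#' a shared QR decomposition), with per-term marginal tests: F-tests for
#' age, sex and age x sex; likelihood-ratio tests (2 x log-likelihood
#' difference of nested OLS fits against chi-squared) for genotype and all
#' genotype-containing terms.
#'
#' @param table A QC'd (log-scale, complete) [feature_table()].
#' @param spec A [model_spec()].
#' @return A `factor_results` tibble: `feature_id`, `column`, `factor`,
#'   `p`, `estimate` (the direction-carrying contrast coefficient where
#'   one exists), `significant` (per-factor BH at `fdr_alpha`, within
#'   column), and `direction` (`"up"`/`"down"` for age,
#'   sex label for sex, `NA` elsewhere; only set where significant).
#' @export
fit_features <- function(table, spec = model_spec()) {
  stopifnot(inherits(table, "feature_table"))
  keep <- !(table$sample_meta$age %in% spec$drop_ages)
  tab <- ft_subset(table, samples = keep)
  enc <- encode_design(tab$sample_meta, spec)
  X <- enc$X
  n <- nrow(X)
  Y <- t(tab$intensities)

  qx <- qr(X)
  df_res <- n - qx$rank
  if (df_res <= 0) abort("no residual degrees of freedom")
  rss_full <- colSums(qr.resid(qx, Y)^2)
  B <- qr.coef(qx, Y)

  res_list <- vector("list", length(enc$term_labels))
  for (ti in seq_along(enc$term_labels)) {
    fac <- enc$factor_of_term[[ti]]
    cols <- enc$assign != ti
    df_term <- sum(!cols)
    rss_red <- rss_of(X[, cols, drop = FALSE], Y)
    # In the Gaussian linear model the likelihood-ratio statistic
    # n log(RSSr/RSSf) is an exact monotone function of the drop-term F
    # statistic, so both tests share the exact F reference; the asymptotic
    # chi-squared reference is badly anticonservative at this parameter
    # count (see the methods vignette) and is not used for decisions.
    fstat <- ((rss_red - rss_full) / df_term) / (rss_full / df_res)
    p <- pf(fstat, df_term, df_res, lower.tail = FALSE)
    est <- switch(fac,
      age = B[enc$age_linear_col, ],
      sex = B[enc$sex_col, ],
      rep(NA_real_, ncol(Y))
    )
    res_list[[ti]] <- tibble::tibble(
      feature_id = tab$feature_meta$feature_id,
      column = tab$feature_meta$column,
      factor = fac,
      p = pmin(pmax(as.numeric(p), 0), 1),
      estimate = as.numeric(est)
    )
  }
  out <- dplyr::bind_rows(res_list)

  out <- out |>
    dplyr::group_by(.data$column, .data$factor) |>
    dplyr::mutate(significant = bh_adjust(.data$p, spec$fdr_alpha)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      direction = dplyr::case_when(
        !.data$significant ~ NA_character_,
        .data$factor == "age" & .data$estimate > 0 ~ "up",
        .data$factor == "age" & .data$estimate < 0 ~ "down",
        .data$factor == "age" ~ "flat",
        .data$factor == "sex" & .data$estimate > 0 ~ enc$sex_positive_level,
        .data$factor == "sex" & .data$estimate < 0 ~ enc$sex_negative_level,
        .data$factor == "sex" ~ "flat",
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::arrange(.data$factor, .data$column, .data$feature_id)
  class(out) <- c("factor_results", class(out))
  out
}

#' Fit the factorial model to a single feature
#'
#' The single-feature counterpart of [fit_features()], returning the full
#' fit: coefficients (including the intercept, the grand mean under sum
#' contrasts), residuals, per-term p-values and nested log-likelihoods.
#'
#' @param y Numeric response (log intensity), one value per design row.
#' @param enc An encoded design from [encode_design()].
#' @param spec A [model_spec()].
#' @return A `feature_fit` object.
#' @export
fit_feature <- function(y, enc, spec = model_spec()) {
  X <- enc$X
  if (length(y) != nrow(X)) abort("length(y) must equal the design row count")
  n <- length(y)
  qx <- qr(X)
  df_res <- n - qx$rank
  if (df_res <= 0) abort("no residual degrees of freedom")
  coefs <- qr.coef(qx, y)
  residuals <- qr.resid(qx, y)
  rss_full <- sum(residuals^2)
  loglik_full <- -n / 2 * (log(2 * pi) + log(rss_full / n) + 1)

  terms_tbl <- purrr::map_dfr(seq_along(enc$term_labels), function(ti) {
    fac <- enc$factor_of_term[[ti]]
    cols <- enc$assign != ti
    df_term <- sum(!cols)
    if (df_term == 0) abort("degenerate nesting: term contributes no columns")
    rss_red <- as.numeric(rss_of(X[, cols, drop = FALSE], cbind(y)))
    ll_red <- -n / 2 * (log(2 * pi) + log(rss_red / n) + 1)
    fstat <- ((rss_red - rss_full) / df_term) / (rss_full / df_res)
    p_exact <- as.numeric(pf(fstat, df_term, df_res, lower.tail = FALSE))
    if (fac %in% c("age", "sex", "age_sex")) {
      tibble::tibble(
        factor = fac, test = "F", statistic = as.numeric(fstat), df = df_term,
        p = p_exact, p_chisq = NA_real_, loglik_reduced = ll_red
      )
    } else {
      lr <- 2 * (loglik_full - ll_red)
      # p: exact small-sample reference via the monotone F equivalence;
      # p_chisq: the asymptotic chi-squared reference of a classical
      # likelihood-ratio test, reported for comparison only
      tibble::tibble(
        factor = fac, test = "LRT", statistic = as.numeric(lr), df = df_term,
        p = p_exact,
        p_chisq = as.numeric(pchisq(lr, df_term, lower.tail = FALSE)),
        loglik_reduced = ll_red
      )
    }
  })

  structure(
    list(
      coefficients = coefs, residuals = residuals, df_residual = df_res,
      loglik = loglik_full, terms = terms_tbl, enc = enc
    ),
    class = "feature_fit"
  )
}

#' Direction labels of a single-feature fit
#'
#' Age direction is the sign of the linear (degree-1) orthogonal
#' polynomial contrast coefficient; sex direction is the sign of the sex
#' contrast coefficient, reported as the higher sex's label. An exactly
#' zero coefficient yields `"flat"`.
#'
#' @param fit A `feature_fit` from [fit_feature()].
#' @param tol Coefficients within `tol` (relative to the response scale)
#'   of zero are labelled `"flat"`; covers responses constructed exactly
#'   orthogonal to a contrast, where floating point leaves a residue.
#' @return Named character vector with elements `age` and `sex`.
#' @export
classify_direction <- function(fit, tol = 1e-10) {
  stopifnot(inherits(fit, "feature_fit"))
  enc <- fit$enc
  scale_y <- max(sd(fit$residuals), 1)
  a <- fit$coefficients[enc$age_linear_col]
  s <- fit$coefficients[enc$sex_col]
  a <- if (abs(a) <= tol * scale_y) 0 else a
  s <- if (abs(s) <= tol * scale_y) 0 else s
  c(
    age = if (a > 0) "up" else if (a < 0) "down" else "flat",
    sex = if (s > 0) {
      enc$sex_positive_level
    } else if (s < 0) {
      enc$sex_negative_level
    } else {
      "flat"
    }
  )
}

#' @method tidy feature_fit
#' @export
tidy.feature_fit <- function(x, ...) x$terms

#' @method glance feature_fit
#' @export
glance.feature_fit <- function(x, ...) {
  tibble::tibble(
    df_residual = x$df_residual,
    sigma = sqrt(sum(x$residuals^2) / x$df_residual),
    logLik = x$loglik
  )
}

#' Benjamini-Hochberg step-up decisions
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return Logical vector: `TRUE` where the hypothesis is rejected at FDR
#'   `alpha`.
#' @export
bh_adjust <- function(p, alpha = 0.01) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH") <= alpha
}

#' Factor-by-column summary of significant features
#'
#' Counts and percentages of features significantly associated with each
#' factor, split by chromatography column and, for age and sex, by
#' direction (increase/decrease with age; higher in which sex).
#'
#' @param results A `factor_results` tibble from [fit_features()].
#' @return A tibble: `parameter`, then per column `n_<col>` and
#'   `pct_<col>` (percentage of that column's feature total).
#' @export
summarize_table1 <- function(results) {
  totals <- results |>
    dplyr::distinct(.data$feature_id, .data$column) |>
    dplyr::count(.data$column, name = "total")

  sexes <- results |>
    dplyr::filter(.data$factor == "sex", !is.na(.data$direction)) |>
    dplyr::pull(.data$direction) |>
    unique() |>
    sort()

  count_of <- function(fac, dir = NULL) {
    r <- dplyr::filter(results, .data$factor == fac, .data$significant)
    if (!is.null(dir)) r <- dplyr::filter(r, .data$direction == dir)
    dplyr::count(r, .data$column)
  }
  rows <- list(
    `Increase with age` = count_of("age", "up"),
    `Decrease with age` = count_of("age", "down")
  )
  for (sx in sexes) {
    rows[[sprintf("Higher in %s", sx)]] <- count_of("sex", sx)
  }
  rows <- c(rows, list(
    Genotype = count_of("genotype"),
    `Age x sex` = count_of("age_sex"),
    `Age x genotype` = count_of("age_geno"),
    `Sex x genotype` = count_of("sex_geno")
  ))
  if ("age_sex_geno" %in% results$factor) {
    rows[["Age x sex x genotype"]] <- count_of("age_sex_geno")
  }

  out <- purrr::imap_dfr(rows, function(cnt, nm) {
    wide <- totals |>
      dplyr::left_join(cnt, by = "column") |>
      dplyr::mutate(
        n = dplyr::coalesce(.data$n, 0L),
        pct = 100 * .data$n / .data$total
      )
    tibble::tibble(
      parameter = nm,
      column = wide$column, n = wide$n, pct = wide$pct
    )
  })
  out |>
    tidyr::pivot_wider(
      names_from = "column", values_from = c("n", "pct"),
      names_glue = "{.value}_{column}"
    )
}
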