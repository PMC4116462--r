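#' Variance components of a single feature
#'
#' Decomposes log intensity into between-line and within-line variance
#' under a one-random-effect mixed model with age and sex as fixed
#' effects and genotype line as a random intercept. Two estimators are
#' provided: `"REML"` (restricted maximum likelihood via [nlme::lme()],
#' the default) and `"MoM"` (ANOVA method of moments: equate between- and
#' within-line mean squares of the fixed-effect-adjusted residuals;
#' independently verifiable by hand and kept as the cross-check oracle).
#' Negative method-of-moments estimates of the between-line variance are
#' truncated to zero and flagged.
#'
#' @param y Numeric response (log intensity).
#' @param sample_meta Tibble with `line`, `sex`, `age` for each element
#'   of `y`.
#' @param estimator `"REML"` or `"MoM"`.
#' @return A `variance_components` list: `sigma2_between`, `sigma2_within`,
#'   `estimator`, `truncated` (logical).
#' @export
estimate_components <- function(y, sample_meta, estimator = c("REML", "MoM")) {
  estimator <- match.arg(estimator)
  line <- factor(sample_meta$line)
  if (nlevels(line) < 2) abort("at least 2 lines are required")
  if (any(table(line) < 2)) abort("at least 2 samples per line are required")
  df <- data.frame(
    y = y,
    age = factor(sample_meta$age),
    sex = factor(sample_meta$sex),
    line = line
  )
  has_sex <- nlevels(df$sex) > 1
  has_age <- nlevels(df$age) > 1

  if (estimator == "REML") {
    fixed <- if (has_age && has_sex) {
      y ~ age + sex
    } else if (has_age) {
      y ~ age
    } else if (has_sex) {
      y ~ sex
    } else {
      y ~ 1
    }
    fit <- tryCatch(
      nlme::lme(fixed, random = ~ 1 | line, data = df, method = "REML",
                control = nlme::lmeControl(returnObject = TRUE)),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      # degenerate likelihood surface (e.g. zero residual variance):
      # fall back to the moment estimator, which is always defined
      return(estimate_components(y, sample_meta, "MoM"))
    }
    vc <- as.numeric(nlme::VarCorr(fit)[, "Variance"])
    s2b <- vc[1]
    s2w <- vc[2]
    truncated <- FALSE
  } else {
    fixed_terms <- c(if (has_age) "age", if (has_sex) "sex")
    r <- if (length(fixed_terms) > 0) {
      resid(lm(stats::reformulate(fixed_terms, "y"), data = df))
    } else {
      y - mean(y)
    }
    ni <- as.numeric(table(line))
    a <- length(ni)
    N <- sum(ni)
    gm <- mean(r)
    gmeans <- tapply(r, line, mean)
    ssb <- sum(ni * (gmeans - gm)^2)
    ssw <- sum((r - gmeans[line])^2)
    msb <- ssb / (a - 1)
    msw <- ssw / (N - a)
    n0 <- (N - sum(ni^2) / N) / (a - 1)
    s2b_raw <- (msb - msw) / n0
    truncated <- s2b_raw < 0
    s2b <- max(s2b_raw, 0)
    s2w <- msw
  }
  structure(
    list(
      sigma2_between = s2b, sigma2_within = s2w,
      estimator = estimator, truncated = truncated
    ),
    class = "variance_components"
  )
}

#' Intraclass correlation among lines
#'
#' The heritability proxy for line-structured data:
#' t = sigma^2_B / (sigma^2_B + sigma^2_W). A within-sample variant
#' t_n = sigma^2_B / (sigma^2_B + sigma^2_W / n), with n the number of
#' pooled individuals per sample, is available behind `per_individual`;
#' the plain intraclass correlation is the default and the reported
#' quantity.
#'
#' @param components A `variance_components` object.
#' @param per_individual Use the within-sample variant?
#' @param n_individuals Individuals pooled per sample (used only by the
#'   variant).
#' @return The intraclass correlation in `[0, 1)`. Zero within-line
#'   variance yields the boundary value just below 1 with a warning; both
#'   variances zero is undefined and yields `NA` with a warning.
#' @export
icc <- function(components, per_individual = FALSE, n_individuals = 3) {
  stopifnot(inherits(components, "variance_components"))
  s2b <- components$sigma2_between
  s2w <- components$sigma2_within
  if (s2b == 0 && s2w == 0) {
    warn("both variance components are zero; intraclass correlation undefined")
    return(NA_real_)
  }
  denom_w <- if (per_individual) s2w / n_individuals else s2w
  if (denom_w == 0) {
    # boundary case: kept strictly below 1 so t stays in [0, 1)
    warn("zero within-line variance; intraclass correlation at boundary")
    return(1 - .Machine$double.eps)
  }
  s2b / (s2b + denom_w)
}

#' Heritability screen across all features
#'
#' Per-feature variance components and intraclass correlation, ranked
#' within chromatography column, with flags for t >= 0.05 and membership
#' in the column's 150 most heritable features (the hand-off list for
#' pathway enrichment).
#'
#' @param table A QC'd [feature_table()].
#' @param estimator `"REML"` (default) or `"MoM"`.
#' @param top_n Size of the most-heritable hand-off list per column.
#' @param t_flag Threshold for the heritable-feature flag.
#' @return A `heritability_result` tibble: `feature_id`, `column`,
#'   `sigma2_between`, `sigma2_within`, `t`, `rank` (descending t within
#'   column, ties broken by feature id), `heritable` (t >= `t_flag`),
#'   `top150` (within the column's top `top_n`).
#' @export
heritability_screen <- function(table, estimator = c("REML", "MoM"),
                                top_n = 150, t_flag = 0.05) {
  stopifnot(inherits(table, "feature_table"))
  estimator <- match.arg(estimator)
  x <- table$intensities
  meta <- table$sample_meta
  if (nrow(x) == 0) {
    out <- tibble::tibble(
      feature_id = character(), column = character(),
      sigma2_between = numeric(), sigma2_within = numeric(), t = numeric(),
      rank = integer(), heritable = logical(), top150 = logical()
    )
    class(out) <- c("heritability_result", class(out))
    return(out)
  }
  comps <- purrr::map(seq_len(nrow(x)), function(i) {
    vc <- estimate_components(x[i, ], meta, estimator)
    t_val <- suppressWarnings(icc(vc))
    tibble::tibble(
      feature_id = table$feature_meta$feature_id[i],
      column = table$feature_meta$column[i],
      sigma2_between = vc$sigma2_between,
      sigma2_within = vc$sigma2_within,
      t = t_val
    )
  })
  out <- dplyr::bind_rows(comps) |>
    dplyr::group_by(.data$column) |>
    dplyr::arrange(dplyr::desc(.data$t), .data$feature_id, .by_group = TRUE) |>
    dplyr::mutate(
      rank = dplyr::row_number(),
      heritable = !is.na(.data$t) & .data$t >= t_flag,
      top150 = .data$rank <= top_n
    ) |>
    dplyr::ungroup()
  class(out) <- c("heritability_result", class(out))
  out
}

#' @method glance heritability_result
#' @export
glance.heritability_result <- function(x, ...) {
  x |>
    dplyr::group_by(.data$column) |>
    dplyr::summarise(
      n_features = dplyr::n(),
      n_heritable = sum(.data$heritable),
      max_t = max(.data$t, na.rm = TRUE),
      median_t = median(.data$t, na.rm = TRUE),
      .groups = "drop"
    )
}
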