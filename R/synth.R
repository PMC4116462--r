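#' Study design specification for the simulator
#'
#' Describes the factorial sampling design the generator emulates: a panel
#' of fully inbred genotype lines, both sexes, a fixed ladder of collection
#' ages, and replicate pools of flies per design cell, measured on two
#' chromatography columns with partially overlapping feature sets.
#'
#' @param n_lines Number of inbred lines (>= 2).
#' @param sexes Character vector of sex labels.
#' @param ages Strictly increasing vector of collection ages in days.
#' @param replicates_per_cell Replicate sample pools per line x sex x age cell.
#' @param flies_per_sample Individuals pooled per sample (kept as metadata;
#'   it enters the within-sample heritability variant, see [icc()]).
#' @param columns Named integer vector: feature count per column label.
#' @param overlap_frac Fraction of the smaller column's features whose
#'   underlying chemical is also detected on the other column.
#' @return A `design_spec` list.
#' @export
design_spec <- function(n_lines = 15,
                        sexes = c("F", "M"),
                        ages = c(3, 10, 24, 36, 51, 66, 81),
                        replicates_per_cell = 2,
                        flies_per_sample = 3,
                        columns = c(AE = 3091, C18 = 3714),
                        overlap_frac = 0.30) {
  if (n_lines < 2) abort("n_lines must be >= 2", class = "flymetab_config_error")
  if (length(sexes) < 1 || anyDuplicated(sexes)) {
    abort("sexes must be distinct labels", class = "flymetab_config_error")
  }
  if (length(ages) < 1 || is.unsorted(ages, strictly = TRUE)) {
    abort("ages must be strictly increasing", class = "flymetab_config_error")
  }
  if (replicates_per_cell < 1) {
    abort("replicates_per_cell must be >= 1", class = "flymetab_config_error")
  }
  if (overlap_frac < 0 || overlap_frac > 1) {
    abort("overlap_frac must lie in [0, 1]", class = "flymetab_config_error")
  }
  if (is.null(names(columns)) || any(!nzchar(names(columns))) || any(columns < 1)) {
    abort("columns must be a named vector of positive feature counts",
      class = "flymetab_config_error"
    )
  }
  structure(
    list(
      n_lines = as.integer(n_lines), sexes = sexes, ages = ages,
      replicates_per_cell = as.integer(replicates_per_cell),
      flies_per_sample = as.integer(flies_per_sample),
      columns = columns, overlap_frac = overlap_frac
    ),
    class = "design_spec"
  )
}

#' Planted-effect specification for the simulator
#'
#' All effects act additively on the log-intensity scale. Fractions give
#' the probability that a feature carries the corresponding effect;
#' assignments are independent, so a feature can carry several.
#'
#' @param frac_age_up,frac_age_down Fractions of features with a monotone
#'   increasing / decreasing age trend.
#' @param frac_sex Fraction with a sex shift (sign random per feature).
#' @param frac_genotype Fraction with line effects drawn at variance
#'   `sigma2_between` (features without it have zero between-line variance).
#' @param frac_age_sex,frac_age_geno,frac_sex_geno Interaction fractions:
#'   sex-specific age slopes, line-specific age slopes, line-specific sex
#'   shifts.
#' @param effect_size_dist Named list: `dist` (one of `"lognormal"`,
#'   `"fixed"`) plus its parameters (`meanlog`/`sdlog`, or `value`).
#'   Magnitudes are log-scale shifts.
#' @param sigma2_between Between-line variance for genotype-carrying
#'   features (sigma^2_B >= 0).
#' @param sigma2_within Residual log-scale variance (sigma^2_W > 0).
#' @param baseline_mean,baseline_sd Log-scale feature baseline distribution.
#' @param missingness List: `quantile` in (0, 1), the detection-threshold
#'   quantile (and the target overall missing rate), and `steepness`, the
#'   logistic slope per log-intensity unit (`Inf` for a hard threshold,
#'   `0` for intensity-independent missingness).
#' @param age_mode `"monotone"` (linear in age rank) or `"hump"`
#'   (non-monotone, symmetric in age rank; zero linear trend component).
#' @param seed Integer seed; the single entropy source for this module.
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(frac_age_up = 0.025,
                        frac_age_down = 0.04,
                        frac_sex = 0.18,
                        frac_genotype = 0.11,
                        frac_age_sex = 0.035,
                        frac_age_geno = 0.09,
                        frac_sex_geno = 0.006,
                        effect_size_dist = list(dist = "lognormal", meanlog = 0, sdlog = 0.4),
                        sigma2_between = 0.10,
                        sigma2_within = 1,
                        baseline_mean = 13.8,
                        baseline_sd = 1.5,
                        missingness = list(quantile = 0.05, steepness = 10),
                        age_mode = c("monotone", "hump"),
                        seed = 1L) {
  fr <- c(
    frac_age_up, frac_age_down, frac_sex, frac_genotype,
    frac_age_sex, frac_age_geno, frac_sex_geno
  )
  if (any(fr < 0 | fr > 1)) {
    abort("effect fractions must lie in [0, 1]", class = "flymetab_config_error")
  }
  if (sigma2_between < 0) abort("sigma2_between must be >= 0", class = "flymetab_config_error")
  if (sigma2_within <= 0) abort("sigma2_within must be > 0", class = "flymetab_config_error")
  if (!is.null(missingness$quantile) &&
      (missingness$quantile <= 0 || missingness$quantile >= 1)) {
    abort("missingness quantile must lie in (0, 1)", class = "flymetab_config_error")
  }
  structure(
    list(
      frac_age_up = frac_age_up, frac_age_down = frac_age_down,
      frac_sex = frac_sex, frac_genotype = frac_genotype,
      frac_age_sex = frac_age_sex, frac_age_geno = frac_age_geno,
      frac_sex_geno = frac_sex_geno,
      effect_size_dist = effect_size_dist,
      sigma2_between = sigma2_between, sigma2_within = sigma2_within,
      baseline_mean = baseline_mean, baseline_sd = baseline_sd,
      missingness = missingness,
      age_mode = match.arg(age_mode),
      seed = as.integer(seed)
    ),
    class = "effect_spec"
  )
}

#' Enumerate the samples of a design
#'
#' @param spec A [design_spec()].
#' @return A tibble with one row per line x sex x age x replicate:
#'   `sample_id`, `line`, `sex`, `age`, `replicate`.
#' @examples
#' nrow(generate_design(design_spec())) # 15 * 2 * 7 * 2 = 420
#' @export
generate_design <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  d <- tidyr::expand_grid(
    line = sprintf("L%02d", seq_len(spec$n_lines)),
    sex = spec$sexes,
    age = spec$ages,
    replicate = seq_len(spec$replicates_per_cell)
  )
  d |>
    dplyr::mutate(
      sample_id = sprintf("%s_%s_a%02d_r%d", .data$line, .data$sex, .data$age, .data$replicate),
      .before = 1
    )
}

draw_magnitudes <- function(n, dist) {
  if (n == 0) return(numeric(0))
  switch(dist$dist,
    lognormal = exp(rnorm(n, dist$meanlog %||% 0, dist$sdlog %||% 0.4)),
    fixed = rep(dist$value, n),
    abort(paste0("unknown effect size distribution: ", dist$dist),
      class = "flymetab_config_error"
    )
  )
}

# Centered age covariate on the rank scale, range 1 (so an age-effect
# magnitude equals the young-to-old swing). "hump" is symmetric in rank,
# hence orthogonal to the linear trend contrast.
age_covariate <- function(ages, mode) {
  k <- length(ages)
  r <- (seq_len(k) - (k + 1) / 2) / max(k - 1, 1)
  z <- switch(mode,
    monotone = r,
    hump = {
      h <- -(r^2)
      h <- h - mean(h)
      h / max(diff(range(h)), .Machine$double.eps)
    }
  )
  setNames(z, as.character(ages))
}

#' Simulate a feature table with known planted structure
#'
#' Generates log-normal intensities under the factorial design: per-feature
#' log-scale signal = baseline + age trend + sex shift + line effect +
#' interactions + residual noise; raw intensities are the exponentiated
#' signal. Chemicals shared between columns (the overlap fraction) carry
#' identical ground truth and baseline but independent residual noise.
#'
#' @param spec A [design_spec()].
#' @param effects An [effect_spec()].
#' @return A list with elements `table` (a raw-scale [feature_table()]) and
#'   `truth` (tibble of per-feature planted effects: signs, magnitudes,
#'   per-line shifts, interaction flags, the true intraclass correlation
#'   `true_icc`, and placeholders `compound_id`/`pathway_id` filled by
#'   [plant_pathways()]).
#' @export
generate_table <- function(spec, effects) {
  stopifnot(inherits(spec, "design_spec"), inherits(effects, "effect_spec"))
  design <- generate_design(spec)
  n_s <- nrow(design)

  counts <- spec$columns
  n_shared <- if (length(counts) >= 2) {
    as.integer(round(spec$overlap_frac * min(counts)))
  } else {
    0L
  }
  # chemicals: shared ones appear on the first two columns; the rest are
  # column-private
  n_chem <- as.integer(sum(counts)) - n_shared
  with_seed(derive_seed(effects$seed, "table"), {
    chem <- simulate_chemistry(spec, effects, n_chem, n_shared)
    feature_meta <- chem$feature_meta
    truth_chem <- chem$truth_chem
    chem_of_feature <- feature_meta$chem_id

    z_by_age <- age_covariate(spec$ages, effects$age_mode)
    z <- z_by_age[as.character(design$age)]
    xsex <- ifelse(design$sex == spec$sexes[1], 0.5, -0.5)
    line_idx <- match(design$line, sprintf("L%02d", seq_len(spec$n_lines)))

    n_f <- nrow(feature_meta)
    ci <- match(chem_of_feature, truth_chem$chem_id)
    baseline <- truth_chem$baseline[ci]
    age_eff <- (truth_chem$age_sign * truth_chem$age_mag)[ci]
    sex_eff <- truth_chem$sex_effect[ci]
    line_mat <- chem$line_effects[ci, , drop = FALSE]
    as_eff <- truth_chem$age_sex_mag[ci]
    ag_mat <- chem$age_line_slopes[ci, , drop = FALSE]
    sg_mat <- chem$sex_line_shifts[ci, , drop = FALSE]

    sig <- baseline +
      outer(age_eff, z) +
      outer(sex_eff, xsex) +
      line_mat[, line_idx, drop = FALSE] +
      outer(as_eff, z * xsex) +
      sweep(ag_mat[, line_idx, drop = FALSE], 2, z, `*`) +
      sweep(sg_mat[, line_idx, drop = FALSE], 2, xsex, `*`) +
      matrix(rnorm(n_f * n_s, 0, sqrt(effects$sigma2_within)), n_f, n_s)

    table <- feature_table(exp(sig), feature_meta, design)
    truth <- truth_of_features(feature_meta, truth_chem, chem$line_effects, effects)
  })
  list(table = table, truth = truth)
}

# Draw per-chemical ground truth and map chemicals onto column features.
simulate_chemistry <- function(spec, effects, n_chem, n_shared) {
  cols <- names(spec$columns)
  dist <- effects$effect_size_dist

  chem_id <- sprintf("chem%05d", seq_len(n_chem))
  flag <- function(frac) runif(n_chem) < frac
  up <- flag(effects$frac_age_up)
  down <- flag(effects$frac_age_down) & !up
  age_sign <- ifelse(up, 1L, ifelse(down, -1L, 0L))
  has_sex <- flag(effects$frac_sex)
  has_geno <- flag(effects$frac_genotype)
  has_as <- flag(effects$frac_age_sex)
  has_ag <- flag(effects$frac_age_geno)
  has_sg <- flag(effects$frac_sex_geno)

  age_mag <- ifelse(age_sign != 0, draw_magnitudes(n_chem, dist), 0)
  sex_effect <- ifelse(
    has_sex,
    draw_magnitudes(n_chem, dist) * sample(c(-1, 1), n_chem, replace = TRUE),
    0
  )
  age_sex_mag <- ifelse(
    has_as,
    draw_magnitudes(n_chem, dist) * sample(c(-1, 1), n_chem, replace = TRUE),
    0
  )

  nl <- spec$n_lines
  line_effects <- matrix(0, n_chem, nl)
  line_effects[has_geno, ] <- rnorm(sum(has_geno) * nl, 0, sqrt(effects$sigma2_between))
  ag_sd <- ifelse(has_ag, draw_magnitudes(n_chem, dist), 0)
  age_line_slopes <- matrix(rnorm(n_chem * nl), n_chem, nl) * ag_sd
  sg_sd <- ifelse(has_sg, draw_magnitudes(n_chem, dist), 0)
  sex_line_shifts <- matrix(rnorm(n_chem * nl), n_chem, nl) * sg_sd

  truth_chem <- tibble::tibble(
    chem_id = chem_id,
    baseline = rnorm(n_chem, effects$baseline_mean, effects$baseline_sd),
    age_sign = age_sign, age_mag = age_mag,
    sex_effect = sex_effect,
    has_genotype = has_geno,
    age_sex_mag = age_sex_mag,
    has_age_geno = has_ag, age_geno_sd = ag_sd,
    has_sex_geno = has_sg, sex_geno_sd = sg_sd
  )

  # assignment of chemicals to column features: the first n_shared
  # chemicals sit on both of the first two columns, the remainder are
  # split among the columns to reach the requested per-column counts
  shared <- if (length(cols) >= 2) seq_len(n_shared) else integer(0)
  remaining <- setdiff(seq_len(n_chem), shared)
  fm <- list()
  taken <- 0L
  for (j in seq_along(cols)) {
    n_private <- spec$columns[[j]] - if (j <= 2) length(shared) else 0L
    idx <- c(if (j <= 2) shared else integer(0), remaining[taken + seq_len(n_private)])
    taken <- taken + n_private
    fm[[j]] <- tibble::tibble(
      feature_id = sprintf("%s_f%05d", cols[j], seq_along(idx)),
      chem_id = chem_id[idx],
      column = cols[j]
    )
  }
  feature_meta <- dplyr::bind_rows(fm)
  n_f <- nrow(feature_meta)
  mz_chem <- setNames(runif(n_chem, 85, 1100), chem_id)
  feature_meta$mz <- as.numeric(mz_chem[feature_meta$chem_id])
  feature_meta$rt <- round(runif(n_f, 10, 600), 1)
  feature_meta <- feature_meta[, c("feature_id", "mz", "rt", "column", "chem_id")]

  list(
    feature_meta = feature_meta, truth_chem = truth_chem,
    line_effects = line_effects, age_line_slopes = age_line_slopes,
    sex_line_shifts = sex_line_shifts
  )
}

truth_of_features <- function(feature_meta, truth_chem, line_effects, effects) {
  ci <- match(feature_meta$chem_id, truth_chem$chem_id)
  le <- line_effects[ci, , drop = FALSE]
  # realized between-line variance of the drawn shifts (unbiased sample
  # variance); nominal sigma2_between defines true_icc
  s2b_nominal <- ifelse(truth_chem$has_genotype[ci], effects$sigma2_between, 0)
  tibble::tibble(
    feature_id = feature_meta$feature_id,
    column = feature_meta$column,
    chem_id = feature_meta$chem_id,
    age_sign = truth_chem$age_sign[ci],
    age_mag = truth_chem$age_mag[ci],
    sex_effect = truth_chem$sex_effect[ci],
    has_genotype = truth_chem$has_genotype[ci],
    has_age_sex = truth_chem$age_sex_mag[ci] != 0,
    has_age_geno = truth_chem$has_age_geno[ci],
    has_sex_geno = truth_chem$has_sex_geno[ci],
    sigma2_between_true = s2b_nominal,
    sigma2_between_realized = apply(le, 1, var),
    sigma2_within_true = effects$sigma2_within,
    true_icc = s2b_nominal / (s2b_nominal + effects$sigma2_within),
    line_effects = apply(le, 1, function(v) paste(signif(v, 8), collapse = ",")),
    compound_id = NA_character_,
    pathway_id = NA_character_
  )
}

#' Censor low-intensity cells
#'
#' Applies intensity-dependent missingness to a raw-scale table: the
#' probability that a cell goes missing follows a decreasing logistic in
#' log intensity centred at the configured detection-threshold quantile.
#' Missing cells become `NA`, never zero.
#'
#' @param table A raw-scale [feature_table()].
#' @param effects An [effect_spec()]; uses its `missingness` and `seed`.
#' @return The table with censored cells set to `NA`.
#' @export
inject_missingness <- function(table, effects) {
  stopifnot(inherits(table, "feature_table"), inherits(effects, "effect_spec"))
  if (table$log_scale) abort("inject_missingness expects a raw-scale table")
  q <- effects$missingness$quantile
  s <- effects$missingness$steepness
  if (is.null(q) || q <= 0 || q >= 1) {
    abort("missingness quantile must lie in (0, 1)", class = "flymetab_config_error")
  }
  x <- table$intensities
  obs <- !is.na(x)
  lx <- log(x[obs])
  with_seed(derive_seed(effects$seed, "missingness"), {
    if (is.infinite(s)) {
      k <- floor(q * length(lx))
      drop <- rank(lx, ties.method = "first") <= k
    } else {
      thr <- quantile(lx, q, names = FALSE)
      p <- plogis(s * (thr - lx))
      drop <- runif(length(lx)) < p
    }
  })
  xo <- x[obs]
  xo[drop] <- NA_real_
  x[obs] <- xo
  table$intensities <- x
  table
}

#' Plant compound identities and pathways into a simulated table
#'
#' Assigns synthetic compounds (with randomly drawn monoisotopic masses)
#' to a subset of features, rewrites those features' m/z to the
#' protonated-adduct mass of their compound so that downstream annotation
#' can recover them, and groups the compounds into pathways. When
#' `enriched = TRUE` the first pathway's compounds are hosted
#' preferentially on age-affected features, creating a truly enriched
#' pathway for calibration and recovery tests; all other pathways draw
#' hosts uniformly.
#'
#' @param table,truth Output of [generate_table()].
#' @param n_pathways Number of pathways (0 allowed: returns an empty db).
#' @param size_range Length-2 integer range of pathway sizes (compounds).
#' @param enriched Plant one truly age-enriched pathway first?
#' @param enriched_hit_frac Fraction of the enriched pathway's hosts drawn
#'   from age-affected features.
#' @param seed Integer seed.
#' @return List: `table` (m/z rewritten for planted hosts), `truth`
#'   (`compound_id`/`pathway_id` filled), `db` (a [compound_db()]).
#' @export
plant_pathways <- function(table, truth, n_pathways = 5,
                           size_range = c(5, 15), enriched = TRUE,
                           enriched_hit_frac = 1, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  if (n_pathways == 0) {
    return(list(
      table = table, truth = truth,
      db = compound_db(
        tibble::tibble(
          compound_id = character(), name = character(), mass = numeric()
        ),
        tibble::tibble(
          pathway_id = character(), name = character(), members = character()
        )
      )
    ))
  }
  with_seed(derive_seed(seed, "pathways"), {
    sizes <- sample(seq(size_range[1], size_range[2]), n_pathways, replace = TRUE)
    n_cmp <- sum(sizes)
    # host features, chemical-level so shared features stay consistent
    chems <- unique(truth$chem_id)
    if (n_cmp > length(chems)) {
      abort("pathway sizes exceed available chemicals", class = "flymetab_config_error")
    }
    age_chems <- unique(truth$chem_id[truth$age_sign != 0])
    hosts <- character(0)
    if (enriched) {
      n_hit <- min(round(enriched_hit_frac * sizes[1]), length(age_chems))
      hosts <- resample(age_chems, n_hit)
      hosts <- c(hosts, resample(setdiff(chems, hosts), sizes[1] - n_hit))
    }
    pool <- setdiff(chems, hosts)
    rest <- sum(sizes) - length(hosts)
    hosts <- c(hosts, resample(pool, rest))

    compound_id <- sprintf("cpd%04d", seq_len(n_cmp))
    mass <- runif(n_cmp, 100, 850)
    pathway_id <- rep(sprintf("pw%02d", seq_len(n_pathways)), times = sizes)

    cmp_of_chem <- setNames(compound_id, hosts)
    pw_of_chem <- setNames(pathway_id, hosts)
    mass_of_chem <- setNames(mass, hosts)

    hit <- truth$chem_id %in% hosts
    truth$compound_id[hit] <- cmp_of_chem[truth$chem_id[hit]]
    truth$pathway_id[hit] <- pw_of_chem[truth$chem_id[hit]]
    fhit <- table$feature_meta$chem_id %in% hosts
    table$feature_meta$mz[fhit] <-
      mass_of_chem[table$feature_meta$chem_id[fhit]] + 1.007276

    pw_ids <- sprintf("pw%02d", seq_len(n_pathways))
    members_by_pw <- vapply(
      split(compound_id, pathway_id),
      paste,
      collapse = ",", FUN.VALUE = character(1)
    )[pw_ids]
    db <- compound_db(
      tibble::tibble(
        compound_id = compound_id,
        name = paste0("synthetic compound ", seq_len(n_cmp)),
        mass = mass
      ),
      tibble::tibble(
        pathway_id = pw_ids,
        name = c(
          if (enriched) "synthetic age-enriched pathway" else NULL,
          paste0(
            "synthetic background pathway ",
            seq_len(n_pathways - as.integer(enriched))
          )
        ),
        members = unname(members_by_pw)
      )
    )
  })
  list(table = table, truth = truth, db = db)
}

#' Write simulator ground truth as TSV
#'
#' @param truth Truth tibble from [generate_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) write_tsv_file(truth, path)
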