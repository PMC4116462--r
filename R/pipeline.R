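#' Default pipeline configuration
#'
#' A nested key-value configuration covering every stage: the simulated
#' design, planted effects, QC parameters, the factorial model, the
#' heritability screen, the multivariate analyses and the enrichment
#' stage, plus a single global seed from which every stage derives an
#' independent substream. Any subset of keys may be overridden; unknown
#' keys are rejected.
#'
#' @param ... Named sections (or `seed`) overriding the defaults, e.g.
#'   `design = list(n_lines = 5)`.
#' @return A `pipeline_config` nested list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1,
    design = list(
      n_lines = 15,
      sexes = c("F", "M"),
      ages = c(3, 10, 24, 36, 51, 66, 81),
      replicates_per_cell = 2,
      flies_per_sample = 3,
      columns = list(AE = 3091, C18 = 3714),
      overlap_frac = 0.30
    ),
    effects = list(
      frac_age_up = 0.025, frac_age_down = 0.04, frac_sex = 0.18,
      frac_genotype = 0.11, frac_age_sex = 0.035, frac_age_geno = 0.09,
      frac_sex_geno = 0.006,
      effect_size_dist = list(dist = "lognormal", meanlog = 0, sdlog = 0.4),
      sigma2_between = 0.10, sigma2_within = 1,
      baseline_mean = 13.8, baseline_sd = 1.5,
      missingness = list(quantile = 0.05, steepness = 10),
      age_mode = "monotone"
    ),
    # snr_threshold differs from the qc_config() default: across
    # biological samples a log-normal feature with sigma2_within = 1 has
    # raw-scale SNR (mean/SD) of at most ~0.76, so the technical-replicate
    # style threshold of 15 would empty the simulated table; 0.3 removes
    # only variance-dominated features (see the methods vignette)
    qc = list(
      snr_threshold = 0.3, max_missing_frac_per_sex = 0.05, mz_max = 900,
      impute_neighbors = 10, log_base = "natural"
    ),
    model = list(drop_ages = 81, fdr_alpha = 0.01, three_way = FALSE),
    heritability = list(estimator = "REML", top_n = 150, t_flag = 0.05),
    multivariate = list(
      grid = c(1, 2, 3, 4, 5, 10, 25, 50), folds = 10, n_perm = 10,
      repeats = 20, fraction = 2 / 3, max_components = 10
    ),
    enrichment = list(
      n_pathways = 5, size_range = c(5, 15), enriched = TRUE,
      n_perm = 999, tol_ppm = 10, top_n = 250
    )
  )
  overrides <- list(...)
  cfg <- merge_config(defaults, overrides, path = "")
  structure(cfg, class = c("pipeline_config", "list"))
}

# Recursive default/override merge; any key absent from the defaults is a
# configuration error.
merge_config <- function(defaults, overrides, path) {
  if (length(overrides) == 0) return(defaults)
  nm <- names(overrides)
  if (is.null(nm) || any(!nzchar(nm))) {
    abort(sprintf("unnamed configuration entries under '%s'", path),
      class = "flymetab_config_error"
    )
  }
  unknown <- setdiff(nm, names(defaults))
  if (length(unknown) > 0) {
    abort(
      sprintf(
        "unknown configuration key(s) under '%s': %s", path,
        paste(unknown, collapse = ", ")
      ),
      class = "flymetab_config_error"
    )
  }
  for (k in nm) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        is.list(overrides[[k]])) {
      defaults[[k]] <- merge_config(
        defaults[[k]], overrides[[k]],
        paste0(path, "/", k)
      )
    } else {
      defaults[[k]] <- overrides[[k]]
    }
  }
  defaults
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with any subset of the keys of
#'   [pipeline_config()]; unknown keys are rejected.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path), class = "flymetab_io_error")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(pipeline_config, raw)
}

design_from_config <- function(cfg) {
  design_spec(
    n_lines = cfg$design$n_lines,
    sexes = unlist(cfg$design$sexes),
    ages = unlist(cfg$design$ages),
    replicates_per_cell = cfg$design$replicates_per_cell,
    flies_per_sample = cfg$design$flies_per_sample,
    columns = unlist(cfg$design$columns),
    overlap_frac = cfg$design$overlap_frac
  )
}

effects_from_config <- function(cfg, seed) {
  args <- cfg$effects
  args$seed <- seed
  do.call(effect_spec, args)
}

#' Run the analysis pipeline
#'
#' Chains the stages in analysis order: `simulate` (synthetic feature
#' table with planted effects, missingness, and pathway structure), `qc`
#' (the six-step cascade), `univariate` (per-feature factorial models and
#' the factor summary), `heritability` (intraclass-correlation screen),
#' `multivariate` (sex classification by sparse PLS-DA with permutation
#' CER, and age prediction by PLS regression with train/test R^2), and
#' `enrich` (top-list and heritability pathway enrichment). Stages
#' communicate through TSV artifacts in `outdir`, so later stages can be
#' re-run alone against existing outputs; a JSON run manifest records the
#' configuration hash, the seed, and every file written.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if missing).
#' @param stages `"all"` or a subset of
#'   `c("simulate", "qc", "univariate", "heritability", "multivariate",
#'   "enrich")`.
#' @param seed Global seed; default from the configuration.
#' @param verbose Print stage progress?
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir,
                         stages = "all", seed = config$seed,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c(
    "simulate", "qc", "univariate", "heritability", "multivariate", "enrich"
  )
  if (identical(stages, "all")) stages <- all_stages
  if (!all(stages %in% all_stages)) {
    abort(paste0(
      "unknown stage(s): ", paste(setdiff(stages, all_stages), collapse = ", ")
    ), class = "flymetab_config_error")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) inform(sprintf(...))
  artifacts <- list()
  need <- function(path, stage) {
    if (!file.exists(path)) {
      abort(
        sprintf("stage '%s' needs missing input %s", stage, path),
        class = "flymetab_io_error"
      )
    }
    path
  }
  pth <- function(...) file.path(outdir, paste0(...))

  if ("simulate" %in% stages) {
    say("stage simulate")
    spec <- design_from_config(config)
    effects <- effects_from_config(config, derive_seed(seed, "simulate"))
    sim <- generate_table(spec, effects)
    tab <- inject_missingness(sim$table, effects)
    planted <- plant_pathways(
      tab, sim$truth,
      n_pathways = config$enrichment$n_pathways,
      size_range = unlist(config$enrichment$size_range),
      enriched = isTRUE(config$enrichment$enriched),
      seed = derive_seed(seed, "pathways")
    )
    write_feature_table(planted$table, pth("sim"))
    write_truth(planted$truth, pth("truth.tsv"))
    write_compound_db(planted$db, pth("db_compounds.tsv"), pth("db_pathways.tsv"))
    artifacts$simulate <- c(
      paste0("sim", c("_intensities.tsv", "_features.tsv", "_samples.tsv")),
      "truth.tsv", "db_compounds.tsv", "db_pathways.tsv"
    )
  }

  if ("qc" %in% stages) {
    say("stage qc")
    need(pth("sim_intensities.tsv"), "qc")
    tab <- read_feature_table(pth("sim"))
    qcd <- run_qc(tab, do.call(qc_config, config$qc))
    write_feature_table(qcd$table, pth("qc"))
    write_tsv_file(tibble::as_tibble(qcd$report), pth("qc_report.tsv"))
    artifacts$qc <- c(
      paste0("qc", c("_intensities.tsv", "_features.tsv", "_samples.tsv")),
      "qc_report.tsv"
    )
  }

  if ("univariate" %in% stages) {
    say("stage univariate")
    need(pth("qc_intensities.tsv"), "univariate")
    tab <- read_feature_table(pth("qc"), log_scale = TRUE)
    spec <- do.call(model_spec, config$model)
    res <- fit_features(tab, spec)
    write_tsv_file(res, pth("factor_results.tsv"))
    write_tsv_file(summarize_table1(res), pth("factor_summary.tsv"))
    artifacts$univariate <- c("factor_results.tsv", "factor_summary.tsv")
  }

  if ("heritability" %in% stages) {
    say("stage heritability")
    need(pth("qc_intensities.tsv"), "heritability")
    tab <- read_feature_table(pth("qc"), log_scale = TRUE)
    her <- heritability_screen(
      tab,
      estimator = config$heritability$estimator,
      top_n = config$heritability$top_n,
      t_flag = config$heritability$t_flag
    )
    write_tsv_file(her, pth("heritability.tsv"))
    artifacts$heritability <- "heritability.tsv"
  }

  if ("multivariate" %in% stages) {
    say("stage multivariate")
    need(pth("qc_intensities.tsv"), "multivariate")
    tab <- read_feature_table(pth("qc"), log_scale = TRUE)
    mv <- config$multivariate
    rows <- list()
    pred_rows <- list()
    for (cl in unique(tab$feature_meta$column)) {
      sub <- ft_subset(tab, features = tab$feature_meta$column == cl)
      X <- t(sub$intensities)
      sex <- sub$sample_meta$sex

      sel <- select_keep_by_cv(
        X, sex,
        grid = unlist(mv$grid), folds = mv$folds,
        seed = derive_seed(seed, paste0("sexcv", cl))
      )
      # "selection" mirrors the observed statistic (the grid-minimum CV
      # error), so observed and permuted values are directly comparable
      perm <- permutation_null(
        X, sex,
        n_perm = mv$n_perm, metric = "cer",
        grid = unlist(mv$grid), folds = mv$folds,
        evaluation = "selection",
        seed = derive_seed(seed, paste0("sexperm", cl))
      )
      rows[[length(rows) + 1]] <- tibble::tibble(
        column = cl, analysis = "sex_classification",
        metric = c("cer", "permuted_cer"),
        value = c(sel$cer, perm$mean),
        se = c(NA_real_, perm$se),
        keep = c(sel$keep, NA_real_)
      )

      for (sx in unique(sub$sample_meta$sex)) {
        ssub <- ft_subset(sub, samples = sub$sample_meta$sex == sx)
        tt <- train_test_r2(
          t(ssub$intensities), ssub$sample_meta$age,
          fraction = mv$fraction, repeats = mv$repeats,
          max_components = mv$max_components, folds = mv$folds,
          seed = derive_seed(seed, paste0("age", cl, sx))
        )
        permr <- permutation_null(
          t(ssub$intensities), ssub$sample_meta$age,
          n_perm = mv$n_perm, metric = "r2",
          fraction = mv$fraction, max_components = mv$max_components,
          folds = mv$folds,
          seed = derive_seed(seed, paste0("ageperm", cl, sx))
        )
        rows[[length(rows) + 1]] <- tibble::tibble(
          column = cl, analysis = paste0("age_regression_", sx),
          metric = c("r2", "permuted_r2"),
          value = c(tt$mean, permr$mean),
          se = c(tt$se, permr$se),
          keep = NA_real_
        )
        pred_rows[[length(pred_rows) + 1]] <- tt$predictions |>
          dplyr::mutate(
            sample_id = ssub$sample_meta$sample_id[.data$sample],
            column = cl, sex = sx
          ) |>
          dplyr::select(
            "column", "sex", "sample_id", "observed", "predicted", "rep"
          )
      }
    }
    write_tsv_file(dplyr::bind_rows(rows), pth("multivariate_summary.tsv"))
    write_tsv_file(dplyr::bind_rows(pred_rows), pth("age_predictions.tsv"))
    artifacts$multivariate <- c("multivariate_summary.tsv", "age_predictions.tsv")
  }

  if ("enrich" %in% stages) {
    say("stage enrich")
    need(pth("factor_results.tsv"), "enrich")
    need(pth("db_compounds.tsv"), "enrich")
    res <- read_tsv_file(pth("factor_results.tsv"))
    class(res) <- c("factor_results", class(res))
    db <- read_compound_db(pth("db_compounds.tsv"), pth("db_pathways.tsv"))
    fmeta <- read_tsv_file(pth("qc_features.tsv"))
    en <- config$enrichment
    out <- list()
    if (nrow(db$compounds) > 0) {
      specs <- list(
        list(factor = "age", sign = "pos"),
        list(factor = "age", sign = "neg"),
        list(factor = "sex", sign = "pos"),
        list(factor = "sex", sign = "neg"),
        list(factor = "age_sex", sign = "all"),
        list(factor = "age_geno", sign = "all")
      )
      for (sp in specs) {
        sel <- suppressWarnings(
          select_top(res, sp$factor, n = en$top_n, sign = sp$sign)
        )
        for (cl in unique(fmeta$column)) {
          uni <- dplyr::filter(fmeta, .data$column == cl)
          ids <- sel$feature_id[sel$column == cl]
          if (length(ids) == 0) next
          er <- enrich(
            ids, uni, db,
            n_perm = en$n_perm, tol_ppm = en$tol_ppm,
            seed = derive_seed(seed, paste0("enr", sp$factor, sp$sign, cl))
          )
          out[[length(out) + 1]] <- dplyr::mutate(
            er,
            column = cl, selection = paste0(sp$factor, "_", sp$sign),
            .before = 1
          )
        }
      }
      if (file.exists(pth("heritability.tsv"))) {
        her <- read_tsv_file(pth("heritability.tsv"))
        class(her) <- c("heritability_result", class(her))
        hr <- suppressWarnings(heritable_enrichment(
          her, fmeta, db,
          n_perm = en$n_perm, tol_ppm = en$tol_ppm,
          seed = derive_seed(seed, "enrher")
        ))
        out[[length(out) + 1]] <- dplyr::mutate(
          hr,
          selection = "heritability_top", .after = 1
        )
      }
    }
    enr_tbl <- if (length(out) > 0) {
      dplyr::bind_rows(out)
    } else {
      tibble::tibble(
        column = character(), selection = character(),
        pathway_id = character(), name = character(),
        pathway_size = integer(), n_annotated = integer(),
        observed = integer(), p_hyper = numeric(), p_emp = numeric()
      )
    }
    write_tsv_file(enr_tbl, pth("enrichment.tsv"))
    artifacts$enrich <- "enrichment.tsv"
  }

  manifest <- list(
    seed = seed,
    config_hash = content_hash(unclass(config)),
    stages = artifacts
  )
  jsonlite::write_json(
    manifest, file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(manifest)
}
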