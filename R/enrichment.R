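#' Compound and pathway database
#'
#' A minimal metabolite knowledge base: compounds with monoisotopic
#' masses, and pathways listing member compounds. The package bundles a
#' small synthetic fixture database (see
#' `system.file("extdata", package = "flymetab")`); user-supplied
#' compound/pathway TSV tables load through [read_compound_db()].
#'
#' @param compounds Tibble: `compound_id`, `name`, `mass` (monoisotopic
#'   Da, > 0).
#' @param pathways Tibble: `pathway_id`, `name`, `members`
#'   (comma-separated compound ids).
#' @return A `compound_db` list with `compounds`, `pathways`, and the
#'   unpacked `members` list.
#' @export
compound_db <- function(compounds, pathways) {
  compounds <- tibble::as_tibble(compounds)
  pathways <- tibble::as_tibble(pathways)
  stopifnot(
    all(c("compound_id", "name", "mass") %in% names(compounds)),
    all(c("pathway_id", "name", "members") %in% names(pathways))
  )
  if (any(compounds$mass <= 0)) abort("compound masses must be positive")
  members <- lapply(strsplit(pathways$members, ","), trimws)
  names(members) <- pathways$pathway_id
  unknown <- setdiff(unlist(members), compounds$compound_id)
  if (length(unknown) > 0) {
    abort(paste0(
      "pathway members missing from compound table: ",
      paste(head(unknown, 5), collapse = ", ")
    ))
  }
  structure(
    list(compounds = compounds, pathways = pathways, members = members),
    class = "compound_db"
  )
}

#' @export
print.compound_db <- function(x, ...) {
  cat(sprintf(
    "<compound_db> %d compounds, %d pathways\n",
    nrow(x$compounds), nrow(x$pathways)
  ))
  invisible(x)
}

#' Read a compound database from two TSV files
#'
#' @param compounds_path TSV with columns `compound_id`, `name`, `mass`.
#' @param pathways_path TSV with columns `pathway_id`, `name`, `members`.
#' @return A [compound_db()].
#' @export
read_compound_db <- function(compounds_path, pathways_path) {
  compound_db(read_tsv_file(compounds_path), read_tsv_file(pathways_path))
}

#' Write a compound database as two TSV files
#'
#' @param db A [compound_db()].
#' @param compounds_path,pathways_path Output paths.
#' @return The paths, invisibly.
#' @export
write_compound_db <- function(db, compounds_path, pathways_path) {
  write_tsv_file(db$compounds, compounds_path)
  write_tsv_file(db$pathways, pathways_path)
  invisible(c(compounds_path, pathways_path))
}

#' Load the bundled synthetic compound database
#'
#' A small fixture database of common metabolites with genuine
#' monoisotopic masses and synthetic pathway groupings, for examples and
#' tests; it is not a curated metabolic model.
#'
#' @return A [compound_db()].
#' @export
synthetic_compound_db <- function() {
  read_compound_db(
    system.file("extdata", "synthetic_compounds.tsv", package = "flymetab"),
    system.file("extdata", "synthetic_pathways.tsv", package = "flymetab")
  )
}

#' Positive-mode adduct rules
#'
#' Mass shifts of the common positive-mode electrospray adducts. Shifts
#' account for the electron mass; e.g. the protonated molecule M+H adds
#' 1.007276 Da to the neutral monoisotopic mass.
#'
#' @return A tibble: `adduct`, `shift` (Da), `charge`.
#' @export
adduct_rules <- function() {
  tibble::tibble(
    adduct = c("M+H", "M+Na", "M+K", "M+H-H2O"),
    shift = c(1.007276, 22.989218, 38.963158, -17.003289),
    charge = 1L
  )
}

#' Annotate m/z features against a compound database
#'
#' For every feature m/z, lists all (compound, adduct) pairs whose
#' theoretical m/z (neutral mass + adduct shift) lies within the relative
#' tolerance. A feature may match several compounds — the inherent
#' ambiguity of one-step annotation — and downstream enrichment handles
#' that ambiguity by flowing it identically through observed and null
#' statistics.
#'
#' @param mz Numeric vector of observed m/z values; names (or
#'   `feature_id`) identify features.
#' @param db A [compound_db()].
#' @param rules Adduct rule tibble, default [adduct_rules()].
#' @param tol_ppm Relative tolerance in parts per million (default 10).
#' @param feature_id Optional feature identifiers (defaults to
#'   `names(mz)` or an index).
#' @return A `match_set` tibble: `feature_id`, `mz`, `compound_id`,
#'   `adduct`, `theoretical_mz`, `ppm_error`.
#' @export
annotate <- function(mz, db, rules = adduct_rules(), tol_ppm = 10,
                     feature_id = NULL) {
  stopifnot(inherits(db, "compound_db"))
  if (nrow(db$compounds) == 0) abort("compound database is empty")
  if (is.null(feature_id)) {
    feature_id <- names(mz) %||% as.character(seq_along(mz))
  }
  theo <- tidyr::expand_grid(
    compound_id = db$compounds$compound_id,
    adduct = rules$adduct
  ) |>
    dplyr::left_join(
      dplyr::select(db$compounds, "compound_id", "mass"),
      by = "compound_id"
    ) |>
    dplyr::left_join(dplyr::select(rules, "adduct", "shift"), by = "adduct") |>
    dplyr::mutate(theoretical_mz = .data$mass + .data$shift) |>
    dplyr::arrange(.data$theoretical_mz)

  tm <- theo$theoretical_mz
  out <- purrr::map_dfr(seq_along(mz), function(i) {
    lim <- tm * tol_ppm * 1e-6
    hit <- which(abs(mz[i] - tm) <= lim)
    if (length(hit) == 0) return(NULL)
    tibble::tibble(
      feature_id = feature_id[i],
      mz = mz[i],
      compound_id = theo$compound_id[hit],
      adduct = theo$adduct[hit],
      theoretical_mz = tm[hit],
      ppm_error = (mz[i] - tm[hit]) / tm[hit] * 1e6
    )
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      feature_id = character(), mz = numeric(), compound_id = character(),
      adduct = character(), theoretical_mz = numeric(), ppm_error = numeric()
    )
  }
  class(out) <- c("match_set", class(out))
  out
}

#' Select top-associated features for enrichment
#'
#' The hand-off lists for pathway enrichment: per chromatography column,
#' the `n` features with the smallest p-values for a factor among the
#' positively associated (`sign = "pos"`), among the negatively
#' associated (`sign = "neg"`), or regardless of sign (`sign = "all"`,
#' used for likelihood-ratio-tested interaction terms which carry no
#' direction). Ties at the cutoff break by feature id for determinism;
#' when fewer than `n` features qualify, all are returned with a warning.
#'
#' @param results A `factor_results` tibble from [fit_features()].
#' @param factor Factor label (e.g. `"age"`, `"sex"`, `"age_sex"`,
#'   `"age_geno"`).
#' @param n List size (default 250).
#' @param sign `"pos"`, `"neg"` or `"all"`.
#' @param column Optional column label; default selects within each
#'   column separately and binds the results.
#' @return Tibble: `column`, `feature_id`, `p`, `estimate`.
#' @export
select_top <- function(results, factor, n = 250, sign = c("all", "pos", "neg"),
                       column = NULL) {
  sign <- match.arg(sign)
  fac <- factor
  r <- dplyr::filter(results, .data$factor == fac)
  if (!is.null(column)) {
    cl <- column
    r <- dplyr::filter(r, .data$column %in% cl)
  }
  if (sign == "pos") r <- dplyr::filter(r, .data$estimate > 0)
  if (sign == "neg") r <- dplyr::filter(r, .data$estimate < 0)
  out <- r |>
    dplyr::group_by(.data$column) |>
    dplyr::arrange(.data$p, .data$feature_id, .by_group = TRUE) |>
    dplyr::slice_head(n = n) |>
    dplyr::ungroup() |>
    dplyr::select("column", "feature_id", "p", "estimate")
  short <- r |>
    dplyr::count(.data$column) |>
    dplyr::filter(.data$n < !!n)
  if (nrow(short) > 0) {
    warn(sprintf(
      "fewer than %d features available in column(s): %s",
      n, paste(short$column, collapse = ", ")
    ))
  }
  out
}

# feature -> pathway incidence over a feature universe: TRUE where the
# feature has at least one candidate compound in the pathway
pathway_incidence <- function(feature_id, mz, db, rules, tol_ppm) {
  ann <- annotate(mz, db, rules = rules, tol_ppm = tol_ppm, feature_id = feature_id)
  inc <- matrix(FALSE, length(feature_id), length(db$members),
    dimnames = list(feature_id, names(db$members))
  )
  if (nrow(ann) > 0) {
    for (pw in names(db$members)) {
      hits <- unique(ann$feature_id[ann$compound_id %in% db$members[[pw]]])
      inc[hits, pw] <- TRUE
    }
  }
  inc
}

#' Pathway enrichment with a permutation null over feature selections
#'
#' The observed statistic per pathway is the number of selected features
#' with at least one candidate compound in the pathway. The null
#' distribution repeats the statistic on random same-size draws from the
#' feature universe, so annotation ambiguity (features matching several
#' compounds) flows through the null exactly as through the observed
#' statistic, preserving calibration. The empirical p-value uses the
#' add-one estimator (1 + #null >= observed) / (1 + n_perm); a
#' hypergeometric p-value on annotated-feature counts is reported
#' alongside as the parametric reference.
#'
#' @param selected Tibble with `feature_id` (from [select_top()] or the
#'   heritability screen) or a character vector of feature ids.
#' @param universe Tibble with `feature_id` and `mz` covering all
#'   features the selection was drawn from.
#' @param db A [compound_db()].
#' @param rules Adduct rules.
#' @param n_perm Number of permutations (a warning below 100: coarse p
#'   resolution).
#' @param tol_ppm Annotation tolerance.
#' @param seed Integer seed for the permutation draws.
#' @return An `enrichment_result` tibble: `pathway_id`, `name`,
#'   `pathway_size` (compounds), `n_annotated` (universe features hitting
#'   the pathway), `observed` (selected features hitting it), `p_hyper`,
#'   `p_emp`, ordered by `p_emp`.
#' @export
enrich <- function(selected, universe, db, rules = adduct_rules(),
                   n_perm = 999, tol_ppm = 10, seed = 1L) {
  stopifnot(inherits(db, "compound_db"))
  if (n_perm < 100) warn("n_perm < 100 gives coarse empirical p-values")
  sel_ids <- if (is.character(selected)) selected else selected$feature_id
  if (!all(sel_ids %in% universe$feature_id)) {
    abort("selected features must be part of the universe")
  }
  if (length(db$members) == 0) {
    out <- tibble::tibble(
      pathway_id = character(), name = character(),
      pathway_size = integer(), n_annotated = integer(),
      observed = integer(), p_hyper = numeric(), p_emp = numeric()
    )
    class(out) <- c("enrichment_result", class(out))
    return(out)
  }
  inc <- pathway_incidence(universe$feature_id, universe$mz, db, rules, tol_ppm)
  sel_rows <- match(sel_ids, universe$feature_id)
  observed <- colSums(inc[sel_rows, , drop = FALSE])

  n_univ <- nrow(inc)
  n_sel <- length(sel_rows)
  with_seed(derive_seed(seed, "enrich"), {
    exceed <- integer(ncol(inc))
    for (b in seq_len(n_perm)) {
      draw <- sample.int(n_univ, n_sel)
      null_stat <- colSums(inc[draw, , drop = FALSE])
      exceed <- exceed + (null_stat >= observed)
    }
  })
  p_emp <- (1 + exceed) / (1 + n_perm)

  n_annot <- colSums(inc)
  p_hyper <- phyper(observed - 1, n_annot, n_univ - n_annot, n_sel,
    lower.tail = FALSE
  )
  out <- tibble::tibble(
    pathway_id = names(db$members),
    name = db$pathways$name[match(names(db$members), db$pathways$pathway_id)],
    pathway_size = lengths(db$members),
    n_annotated = as.integer(n_annot),
    observed = as.integer(observed),
    p_hyper = as.numeric(p_hyper),
    p_emp = as.numeric(p_emp)
  ) |>
    dplyr::arrange(.data$p_emp, .data$pathway_id)
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Pathway enrichment of the most heritable features
#'
#' Applies the [enrich()] machinery to the heritability screen's
#' most-heritable hand-off list, per chromatography column.
#'
#' @param herit A `heritability_result` from [heritability_screen()].
#' @param universe Tibble with `feature_id`, `mz`, `column` for all
#'   screened features (e.g. the QC'd table's feature metadata).
#' @param db A [compound_db()].
#' @param rules,n_perm,tol_ppm,seed Passed to [enrich()].
#' @return An `enrichment_result` tibble with a `column` prefix column.
#' @export
heritable_enrichment <- function(herit, universe, db, rules = adduct_rules(),
                                 n_perm = 999, tol_ppm = 10, seed = 1L) {
  stopifnot(inherits(herit, "heritability_result"))
  purrr::map_dfr(unique(herit$column), function(cl) {
    top <- dplyr::filter(herit, .data$column == cl, .data$top150)
    if (nrow(top) < 150) {
      warn(sprintf("column %s has only %d screened features", cl, nrow(top)))
    }
    uni <- dplyr::filter(universe, .data$column == cl)
    res <- enrich(top$feature_id, uni, db,
      rules = rules, n_perm = n_perm,
      tol_ppm = tol_ppm, seed = derive_seed(seed, cl)
    )
    dplyr::mutate(res, column = cl, .before = 1)
  })
}
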