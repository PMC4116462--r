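#' Feature table: intensities plus feature and sample metadata
#'
#' The container every pipeline stage consumes and produces. It holds a
#' numeric matrix of ion intensities (rows = features, columns = samples;
#' nonnegative on the raw scale, real-valued after log transform, `NA` for
#' non-detected cells) together with per-feature metadata (mass-charge
#' ratio, retention time, chromatography column label) and per-sample
#' metadata (genotype line, sex, age in days, replicate index).
#'
#' @param intensities Numeric matrix, features x samples. Row names are
#'   feature ids, column names sample ids (supplied via metadata if absent).
#' @param feature_meta Tibble with columns `feature_id`, `mz`, `rt`,
#'   `column`; one row per matrix row, in order.
#' @param sample_meta Tibble with columns `sample_id`, `line`, `sex`,
#'   `age`, `replicate`; one row per matrix column, in order.
#' @param log_scale Logical; `TRUE` once intensities are log transformed.
#' @return An object of class `feature_table`.
#' @examples
#' ft <- feature_table(
#'   matrix(1:4, 2, dimnames = list(c("f1", "f2"), c("s1", "s2"))),
#'   tibble::tibble(feature_id = c("f1", "f2"), mz = c(100, 200),
#'                  rt = c(30, 60), column = "AE"),
#'   tibble::tibble(sample_id = c("s1", "s2"), line = "L1",
#'                  sex = c("F", "M"), age = 3, replicate = 1:2)
#' )
#' dim(ft)
#' @export
feature_table <- function(intensities, feature_meta, sample_meta,
                          log_scale = FALSE) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  feature_meta <- tibble::as_tibble(feature_meta)
  sample_meta <- tibble::as_tibble(sample_meta)

  need_f <- c("feature_id", "mz", "rt", "column")
  need_s <- c("sample_id", "line", "sex", "age", "replicate")
  if (!all(need_f %in% names(feature_meta))) {
    abort(paste0("feature_meta must have columns: ", paste(need_f, collapse = ", ")))
  }
  if (!all(need_s %in% names(sample_meta))) {
    abort(paste0("sample_meta must have columns: ", paste(need_s, collapse = ", ")))
  }
  if (nrow(feature_meta) != nrow(intensities)) {
    abort("feature_meta rows must match intensity matrix rows")
  }
  if (nrow(sample_meta) != ncol(intensities)) {
    abort("sample_meta rows must match intensity matrix columns")
  }
  if (anyDuplicated(sample_meta$sample_id)) abort("sample ids must be unique")
  if (anyDuplicated(feature_meta$feature_id)) abort("feature ids must be unique")
  if (nrow(feature_meta) > 0 &&
      (any(feature_meta$mz < 85) || any(feature_meta$mz > 2000))) {
    abort("feature m/z must lie in [85, 2000]")
  }
  if (!log_scale && any(intensities < 0, na.rm = TRUE)) {
    abort("raw-scale intensities must be nonnegative")
  }
  rownames(intensities) <- feature_meta$feature_id
  colnames(intensities) <- sample_meta$sample_id

  structure(
    list(
      intensities = intensities,
      feature_meta = feature_meta,
      sample_meta = sample_meta,
      log_scale = log_scale
    ),
    class = "feature_table"
  )
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d features x %d samples (%s scale)\n",
    nrow(x$intensities), ncol(x$intensities),
    if (x$log_scale) "log" else "raw"
  ))
  cat(sprintf(
    "  columns: %s | missing cells: %d\n",
    paste(unique(x$feature_meta$column), collapse = ", "),
    sum(is.na(x$intensities))
  ))
  invisible(x)
}

#' Subset a feature table by feature and/or sample
#'
#' @param x A [feature_table()].
#' @param features Logical, integer or character index over features.
#' @param samples Logical, integer or character index over samples.
#' @return A `feature_table` restricted to the selection.
#' @export
ft_subset <- function(x, features = NULL, samples = NULL) {
  stopifnot(inherits(x, "feature_table"))
  fi <- if (is.null(features)) seq_len(nrow(x$intensities)) else features
  si <- if (is.null(samples)) seq_len(ncol(x$intensities)) else samples
  if (is.character(fi)) fi <- match(fi, x$feature_meta$feature_id)
  if (is.character(si)) si <- match(si, x$sample_meta$sample_id)
  feature_table(
    x$intensities[fi, si, drop = FALSE],
    x$feature_meta[fi, , drop = FALSE],
    x$sample_meta[si, , drop = FALSE],
    log_scale = x$log_scale
  )
}

#' Tidy a feature table into a long tibble
#'
#' @param x A [feature_table()].
#' @param ... Unused.
#' @return A tibble with one row per feature-sample cell (missing cells
#'   retained as `NA` intensities), joined to both metadata tables.
#' @method tidy feature_table
#' @export
tidy.feature_table <- function(x, ...) {
  long <- tibble::tibble(
    feature_id = rep(x$feature_meta$feature_id, times = ncol(x$intensities)),
    sample_id = rep(x$sample_meta$sample_id, each = nrow(x$intensities)),
    intensity = as.vector(x$intensities)
  )
  long |>
    dplyr::left_join(x$feature_meta, by = "feature_id") |>
    dplyr::left_join(x$sample_meta, by = "sample_id")
}

#' Write a feature table as a trio of TSV files
#'
#' Emits `<prefix>_intensities.tsv` (rows = features, first column
#' `feature_id`, remaining columns one per sample id; missing cells empty),
#' `<prefix>_features.tsv` and `<prefix>_samples.tsv`.
#'
#' @param x A [feature_table()].
#' @param prefix Path prefix for the three files.
#' @return The three paths, invisibly.
#' @export
write_feature_table <- function(x, prefix) {
  stopifnot(inherits(x, "feature_table"))
  paths <- paste0(prefix, c("_intensities.tsv", "_features.tsv", "_samples.tsv"))
  inten <- tibble::as_tibble(x$intensities)
  inten <- dplyr::bind_cols(
    tibble::tibble(feature_id = x$feature_meta$feature_id), inten
  )
  write_tsv_file(inten, paths[1])
  write_tsv_file(x$feature_meta, paths[2])
  write_tsv_file(x$sample_meta, paths[3])
  invisible(paths)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param prefix Path prefix used at write time.
#' @param log_scale Whether the stored intensities are on the log scale.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(prefix, log_scale = FALSE) {
  inten <- read_tsv_file(paste0(prefix, "_intensities.tsv"))
  fmeta <- read_tsv_file(paste0(prefix, "_features.tsv"))
  smeta <- read_tsv_file(paste0(prefix, "_samples.tsv"))
  m <- as.matrix(inten[, -1, drop = FALSE])
  rownames(m) <- inten$feature_id
  feature_table(m, fmeta, smeta, log_scale = log_scale)
}
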