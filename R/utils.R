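# Internal helpers: seed derivation and delimited-text round-tripping.

# sample() that never falls into the scalar-x shortcut
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# Deterministically derive an independent substream seed from a global seed
# and a stage label. Kept below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Write a tibble as tab-separated text
#'
#' All pipeline artifacts are TSV with a header row; missing cells are
#' written as empty fields, never as `"NA"` or `0`.
#'
#' @param x A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tsv_file <- function(x, path) {
  utils::write.table(x, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    na = "", fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Read a tab-separated file written by [write_tsv_file()]
#'
#' @param path File path.
#' @return A tibble; empty fields become `NA`.
#' @export
read_tsv_file <- function(path) {
  tibble::as_tibble(utils::read.table(path,
    sep = "\t", header = TRUE, na.strings = "",
    check.names = FALSE, stringsAsFactors = FALSE,
    colClasses = NA, fileEncoding = "UTF-8", comment.char = ""
  ))
}

# Stable non-cryptographic content hash of an R object (FNV-1a over its
# serialized bytes); used in run manifests.
content_hash <- function(x) {
  bytes <- serialize(x, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}
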