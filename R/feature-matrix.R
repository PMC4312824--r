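#' Feature matrices with a processing-scale tag
#'
#' A `feature_matrix` is a plain numeric matrix (samples in rows, features in
#' columns, dimnames required) carrying a scale tag that records where it sits
#' in the pre-treatment chain `raw -> normalized -> log2 -> corrected ->
#' imputed`. Every pipeline step checks the tag of its input and stamps its
#' output, so out-of-order calls fail loudly instead of silently producing
#' nonsense (e.g. log2-transforming twice). Missing intensities are `NA`.
#'
#' @param x numeric matrix, samples x features, with row and column names.
#' @param scale one of `"raw"`, `"normalized"`, `"log2"`, `"corrected"`,
#'   `"imputed"`. Raw and normalized matrices must be strictly positive where
#'   present; imputed matrices must be complete.
#' @return `x` with class `feature_matrix` and the scale tag attached.
#' @examples
#' m <- matrix(2^rnorm(12, 14), 3, 4,
#'             dimnames = list(paste0("S", 1:3), paste0("mz", 1:4)))
#' fm <- feature_matrix(m, "raw")
#' fm_scale(fm)
#' @export
feature_matrix <- function(x, scale = c("raw", "normalized", "log2",
                                        "corrected", "imputed")) {
  scale <- match.arg(scale)
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("`x` must be a numeric matrix (samples x features).")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort("`x` must have sample (row) and feature (column) names.")
  }
  present <- x[!is.na(x)]
  if (scale %in% c("raw", "normalized") && any(present <= 0)) {
    abort(paste0("A ", scale, "-scale matrix must be strictly positive ",
                 "where present; found non-positive values."))
  }
  if (scale == "imputed" && anyNA(x)) {
    abort("An imputed matrix cannot contain missing values.")
  }
  structure(x, fm_scale = scale,
            class = c("feature_matrix", "matrix", "array"))
}

#' @rdname feature_matrix
#' @export
fm_scale <- function(x) {
  s <- attr(x, "fm_scale")
  if (is.null(s)) abort("Not a `feature_matrix` (no scale tag).")
  s
}

# internal: retag without re-validating positivity (used after transforms)
retag <- function(x, scale) {
  attr(x, "fm_scale") <- scale
  class(x) <- c("feature_matrix", "matrix", "array")
  x
}

assert_scale <- function(x, expected, op) {
  s <- fm_scale(x)
  if (!s %in% expected) {
    abort(sprintf(
      "%s() expects a matrix on the %s scale, got '%s'. Pipeline order is raw -> normalized -> log2 -> corrected -> imputed.",
      op, paste(sQuote(expected), collapse = " or "), s))
  }
  invisible(s)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features, scale = %s, %.1f%% missing\n",
              nrow(x), ncol(x), fm_scale(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' @export
`[.feature_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) out <- retag(out, attr(x, "fm_scale"))
  out
}

#' Read / write a feature matrix as CSV
#'
#' The on-disk layout matches what LC-MS alignment software exports: a header
#' row of feature ids, a first column `sample_id`, one row per sample, missing
#' intensities empty or `NA`.
#'
#' @param path file path.
#' @param scale scale tag to stamp on the matrix read (default `"raw"`).
#' @return `read_feature_matrix()` a [feature_matrix()];
#'   `write_feature_matrix()` the input, invisibly.
#' @export
read_feature_matrix <- function(path, scale = "raw") {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1] != "sample_id") {
    abort("First column of a feature-matrix CSV must be `sample_id`.")
  }
  m <- as.matrix(df[-1])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  feature_matrix(m, scale)
}

#' @rdname read_feature_matrix
#' @param x a [feature_matrix()].
#' @export
write_feature_matrix <- function(x, path) {
  df <- tibble::as_tibble(unclass(x), .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble(sample_id = rownames(x)), df)
  readr::write_csv(df, path, na = "NA")
  invisible(x)
}
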