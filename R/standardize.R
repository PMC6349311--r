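#' Feature matrices
#'
#' A `feature_matrix` is one subject-epoch's data block: one row per
#' timestamp, one column per feature, stored as a plain numeric matrix with a
#' `standardized` flag. Most users never construct one directly; [caa()]
#' accepts a data frame or matrix and standardizes it on the way in.
#'
#' @param x A numeric matrix or data frame of numeric columns.
#' @param standardized Logical; has each column already been centred and
#'   scaled to unit sample variance?
#' @return A `feature_matrix` object.
#' @export
as_feature_matrix <- function(x, standardized = FALSE) {
  if (inherits(x, "feature_matrix")) return(x)
  if (is.data.frame(x)) {
    not_num <- names(x)[!vapply(x, is.numeric, logical(1))]
    if (length(not_num)) {
      abort(paste0("non-numeric feature columns: ", toString(not_num)),
            class = "cae_data_error")
    }
    x <- as.matrix(x)
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("`x` must be a numeric matrix or data frame", class = "cae_data_error")
  }
  if (nrow(x) < 2 || ncol(x) < 2) {
    abort("a feature matrix needs at least 2 rows and 2 columns",
          class = "cae_data_error")
  }
  if (!all(is.finite(x))) {
    abort("feature matrix contains non-finite entries", class = "cae_data_error")
  }
  if (is.null(colnames(x))) {
    colnames(x) <- sprintf("f%03d", seq_len(ncol(x)) - 1L)
  }
  structure(x, standardized = standardized, class = c("feature_matrix", "matrix", "array"))
}

#' Standardize feature columns
#'
#' Centres every column to mean zero and scales to unit *sample* variance
#' (denominator n - 1), so that the cross-product of the result is (n - 1)
#' times the sample correlation matrix. Constant columns cannot be
#' standardized and raise an error naming the offending columns; callers that
#' prefer to drop them (the command-line path does) must do so beforehand.
#'
#' @param m A numeric matrix or data frame (rows = timestamps, columns =
#'   features).
#' @return A standardized [feature_matrix][as_feature_matrix].
#' @examples
#' standardize_columns(cbind(a = c(1, 2, 3), b = c(2, 4, 6)))
#' @export
standardize_columns <- function(m) {
  fm <- as_feature_matrix(m)
  if (isTRUE(attr(fm, "standardized"))) return(fm)
  sds <- apply(fm, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("constant column(s) cannot be standardized: ",
                 toString(colnames(fm)[sds == 0])),
          class = "cae_constant_column")
  }
  out <- scale(unclass(fm), center = TRUE, scale = sds)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  colnames(out) <- colnames(fm)
  as_feature_matrix(out, standardized = TRUE)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: %d timestamps x %d features%s>\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "standardized"))) ", standardized" else ""))
  invisible(x)
}

# internal: coerce + standardize in one step
.as_standardized <- function(x) {
  fm <- as_feature_matrix(x)
  if (!isTRUE(attr(fm, "standardized"))) fm <- standardize_columns(fm)
  fm
}
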