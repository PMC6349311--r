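#' Stratified subject-level folds
#'
#' Partitions subjects into folds, stratified by class: within each class
#' subjects are shuffled under `seed` and dealt round-robin. All of a
#' subject's correlations therefore stay on one side of every split. When a
#' class has fewer subjects than folds, stratification is necessarily
#' relaxed and a warning is emitted.
#'
#' @param labels Data frame with columns `subject_id` and `label` (binary).
#' @param n_folds Number of folds.
#' @param seed Integer seed; the same seed yields the identical plan.
#' @return A tibble with columns `subject_id`, `label`, `fold`.
#' @export
make_folds <- function(labels, n_folds = 10L, seed = 1L) {
  n_folds <- as.integer(n_folds)
  if (length(unique(labels$label)) < 2) {
    abort("cannot build stratified folds for a single-class cohort",
          class = "cae_data_error")
  }
  tab <- table(labels$label)
  if (any(tab < n_folds)) {
    warn(sprintf("fewer than %d subjects in some class; stratification relaxed",
                 n_folds))
  }
  withr::with_seed(seed, {
    out <- labels |>
      dplyr::group_by(.data$label) |>
      dplyr::group_modify(function(df, key) {
        df <- df[sample.int(nrow(df)), , drop = FALSE]
        df$fold <- rep_len(seq_len(n_folds), nrow(df))
        df
      }) |>
      dplyr::ungroup()
  })
  dplyr::arrange(dplyr::select(out, "subject_id", "label", "fold"),
                 .data$subject_id)
}

#' Quartile featurization of a window
#'
#' Summarizes each feature column by its first quartile, median and third
#' quartile (linear-interpolation convention, `stats::quantile` type 7),
#' yielding a `3 m` vector per subject window — the "sets" baseline input.
#'
#' @param X Numeric matrix or data frame (rows = timestamps).
#' @return A named numeric vector of length `3 * ncol(X)`.
#' @examples
#' quartile_featurize(cbind(a = 1:9))
#' @export
quartile_featurize <- function(X) {
  X <- as.matrix(X)
  if (!nrow(X)) abort("empty window", class = "cae_data_error")
  qs <- apply(X, 2, quantile, probs = c(0.25, 0.5, 0.75), names = FALSE,
              type = 7)
  nm <- colnames(X) %||% sprintf("f%03d", seq_len(ncol(X)) - 1L)
  stats::setNames(as.vector(qs),
                  as.vector(outer(c("q1", "q2", "q3"), nm, function(a, b) paste(b, a, sep = "_"))))
}

#' Last-point featurization
#'
#' The final row of the window — the "points" baseline input: the snapshot
#' recorded at the prediction time.
#'
#' @param X Numeric matrix or data frame.
#' @return A named numeric vector of length `ncol(X)`.
#' @export
last_point_featurize <- function(X) {
  X <- as.matrix(X)
  if (!nrow(X)) abort("empty matrix", class = "cae_data_error")
  v <- X[nrow(X), ]
  names(v) <- colnames(X) %||% sprintf("f%03d", seq_len(ncol(X)) - 1L)
  v
}
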