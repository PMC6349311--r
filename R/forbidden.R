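#' Forbidden-correlation sets
#'
#' CAA's disjoint-support constraint generalizes from "a feature may not
#' correlate with itself" to "a feature may not correlate with any feature in
#' its forbidden set". `forbidden_sets(m)` builds the default sets
#' S_i = \{i\} (self-correlation always forbidden); `groups` adds mutually
#' forbidden groups, e.g. a feature together with its polynomial powers.
#' Symmetric closure (j in S_i implies i in S_j) is enforced by construction.
#'
#' @param m Number of features.
#' @param groups Optional list of integer vectors; all features within a
#'   group are mutually forbidden as correlates of one another.
#' @return A `forbidden_sets` object: a list of length `m` whose i-th element
#'   is the sorted integer vector S_i.
#' @examples
#' forbidden_sets(4, groups = list(c(1, 3)))
#' @export
forbidden_sets <- function(m, groups = NULL) {
  m <- as.integer(m)
  if (m < 2) abort("`m` must be >= 2", class = "cae_data_error")
  sets <- lapply(seq_len(m), function(i) i)
  for (g in groups) {
    g <- sort(unique(as.integer(g)))
    if (any(g < 1L | g > m)) {
      abort("forbidden group indices out of range", class = "cae_data_error")
    }
    for (i in g) sets[[i]] <- union(sets[[i]], g)
  }
  # symmetric closure (groups are symmetric already; guard anyway)
  for (i in seq_len(m)) {
    for (j in sets[[i]]) sets[[j]] <- union(sets[[j]], i)
  }
  sets <- lapply(sets, function(s) sort(unique(as.integer(s))))
  structure(sets, class = "forbidden_sets", m = m)
}

#' @export
print.forbidden_sets <- function(x, ...) {
  extra <- sum(lengths(x) > 1L)
  cat(sprintf("<forbidden_sets: %d features, %d with non-trivial sets>\n",
              attr(x, "m"), extra))
  invisible(x)
}

.check_forbidden <- function(forbidden, m) {
  if (is.null(forbidden)) return(forbidden_sets(m))
  if (!inherits(forbidden, "forbidden_sets")) {
    abort("`forbidden` must be built with forbidden_sets()", class = "cae_data_error")
  }
  if (attr(forbidden, "m") != m) {
    abort(sprintf("forbidden sets are for %d features, data has %d",
                  attr(forbidden, "m"), m), class = "cae_data_error")
  }
  forbidden
}

#' Polynomial feature expansion
#'
#' Appends powers x_i^2 ... x_i^degree of every original feature (each power
#' re-standardized) so that CAA can pick up non-linear, e.g. quadratic,
#' relations between *distinct* features. The returned forbidden sets place
#' each original feature and all of its powers in one mutual group, so a
#' feature can never be reported as "correlated" with its own powers — a
#' relation that holds by construction and would otherwise dominate.
#'
#' @param X A matrix, data frame or [feature_matrix][as_feature_matrix];
#'   standardized on the way in.
#' @param degree Largest power to append; 2 or 3 in practice.
#' @return A list with elements `x` (the expanded, standardized
#'   `feature_matrix` with `m * degree` columns) and `forbidden` (the matching
#'   `forbidden_sets`).
#' @examples
#' ex <- expand_polynomial_features(matrix(rnorm(40), 20, 2), degree = 2)
#' ncol(ex$x)
#' @export
expand_polynomial_features <- function(X, degree = 2L) {
  degree <- as.integer(degree)
  if (degree < 2L) abort("`degree` must be >= 2", class = "cae_data_error")
  fm <- .as_standardized(X)
  m <- ncol(fm)
  blocks <- list(unclass(fm))
  for (p in 2:degree) {
    pow <- unclass(fm)^p
    if (any(!is.finite(pow)) || max(abs(pow)) > 1e150) {
      abort("overflow in polynomial powers; clip extreme values first",
            class = "cae_data_error")
    }
    colnames(pow) <- paste0(colnames(fm), "^", p)
    blocks[[p]] <- pow
  }
  xx <- do.call(cbind, blocks)
  xx <- standardize_columns(xx)
  groups <- lapply(seq_len(m), function(i) i + m * (0:(degree - 1L)))
  list(x = xx, forbidden = forbidden_sets(m * degree, groups = groups))
}
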