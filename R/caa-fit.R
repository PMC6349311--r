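#' Canonical Autocorrelation Analysis
#'
#' Fits a CAA model to one subject-epoch: finds sparse unit vectors `u`, `v`
#' with disjoint (forbidden-set-respecting) supports maximizing `u' G v`,
#' where `G` is the sample correlation matrix of the data, then deflates `G`
#' and repeats. Extraction stops at `max_pairs`, on a degenerate step, or at
#' the first pair whose projection R^2 does not exceed `r2_min` (that pair is
#' discarded): deflating past noise-level structure is meaningless.
#'
#' @param data A data frame or numeric matrix, one row per timestamp and one
#'   column per feature; standardized internally (constant columns are an
#'   error — drop them first).
#' @param config A [caa_config()].
#' @param forbidden A [forbidden_sets()] object, or `NULL` for the default
#'   self-correlation-only sets.
#' @param subject_id Optional identifier stored on the retained pairs.
#' @return An object of class `caa_fit` with elements `pairs` (list of
#'   [canonical_pair()]), `config`, `forbidden`, `objective_trace` (one
#'   numeric vector per retained pair, non-decreasing), `feature_names`,
#'   `subject_id` and `n_obs`. Use [tidy()] for a per-pair tibble and
#'   [glance()] for a one-row fit summary.
#' @examples
#' set.seed(1)
#' z <- rnorm(500)
#' x <- cbind(z + rnorm(500, sd = 0.3), z + rnorm(500, sd = 0.3),
#'            matrix(rnorm(500 * 3), 500, 3))
#' fit <- caa(x, caa_config(max_pairs = 2))
#' tidy(fit)
#' @export
caa <- function(data, config = caa_config(), forbidden = NULL,
                subject_id = NA_character_) {
  fm <- .as_standardized(data)
  n <- nrow(fm)
  m <- ncol(fm)
  if (config$c1 > sqrt(m) + 1e-12 || config$c2 > sqrt(m) + 1e-12) {
    abort("L1 budgets c1, c2 must lie in [1, sqrt(m)]", class = "cae_data_error")
  }
  forbidden <- .check_forbidden(forbidden, m)
  G <- crossprod(unclass(fm)) / (n - 1)
  pairs <- list()
  traces <- list()
  for (idx in seq_len(config$max_pairs)) {
    cfg_k <- config
    cfg_k$seed <- config$seed + idx - 1L
    pair <- tryCatch(
      alternate_convex_search(G, cfg_k, forbidden),
      cae_degenerate_step = function(e) NULL
    )
    if (is.null(pair)) break
    pair$r_squared <- compute_r_squared(fm, pair)
    if (pair$r_squared <= config$r2_min) break
    pair$subject_id <- subject_id
    pair$pair_index <- idx - 1L
    G <- deflate_gram(G, pair)
    traces[[length(traces) + 1]] <- attr(pair, "trace")
    pairs[[length(pairs) + 1]] <- pair
  }
  structure(list(pairs = pairs, config = config, forbidden = forbidden,
                 objective_trace = traces, feature_names = colnames(fm),
                 subject_id = subject_id, n_obs = n),
            class = "caa_fit")
}

#' @export
print.caa_fit <- function(x, ...) {
  cat(sprintf("<caa_fit%s: %d retained pair(s) over %d features>\n",
              if (is.na(x$subject_id)) "" else paste0(" [", x$subject_id, "]"),
              length(x$pairs), length(x$feature_names)))
  if (length(x$pairs)) print(tidy(x))
  invisible(x)
}

#' Tidy a CAA fit
#'
#' @param x A `caa_fit`.
#' @param ... Unused.
#' @return A tibble with one row per retained pair: `pair_index`, `d`,
#'   `r_squared`, support sizes, iteration count, winning restart, and the
#'   supports as list-columns of feature names.
#' @export
tidy.caa_fit <- function(x, ...) {
  if (!length(x$pairs)) {
    return(tibble::tibble(pair_index = integer(), d = numeric(),
                          r_squared = numeric(), size_u = integer(),
                          size_v = integer(), iterations = integer(),
                          restart = integer(), support_u = list(),
                          support_v = list()))
  }
  purrr::map_dfr(x$pairs, function(p) {
    tibble::tibble(
      pair_index = p$pair_index,
      d = p$d,
      r_squared = p$r_squared,
      size_u = sum(p$u != 0),
      size_v = sum(p$v != 0),
      iterations = attr(p, "iters") %||% NA_integer_,
      restart = attr(p, "restart") %||% NA_integer_,
      support_u = list(x$feature_names[p$u != 0]),
      support_v = list(x$feature_names[p$v != 0])
    )
  })
}

#' Glance at a CAA fit
#'
#' @param x A `caa_fit`.
#' @param ... Unused.
#' @return A one-row tibble: number of pairs, total and top `d`, R^2 range,
#'   observation and feature counts.
#' @export
glance.caa_fit <- function(x, ...) {
  r2 <- vapply(x$pairs, function(p) p$r_squared, numeric(1))
  d <- vapply(x$pairs, function(p) p$d, numeric(1))
  tibble::tibble(
    n_pairs = length(x$pairs),
    d_max = if (length(d)) max(d) else NA_real_,
    r_squared_max = if (length(r2)) max(r2) else NA_real_,
    r_squared_min = if (length(r2)) min(r2) else NA_real_,
    n_obs = x$n_obs,
    n_features = length(x$feature_names)
  )
}

#' Plot CAA pair loadings
#'
#' Bar chart of the non-zero loadings of each retained pair, faceted by pair
#' and axis.
#'
#' @param object A `caa_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.caa_fit <- function(object, ...) {
  if (!length(object$pairs)) abort("no retained pairs to plot", class = "cae_data_error")
  df <- purrr::map_dfr(object$pairs, function(p) {
    dplyr::bind_rows(
      tibble::tibble(pair = paste0("pair ", p$pair_index), axis = "u",
                     feature = object$feature_names, loading = p$u),
      tibble::tibble(pair = paste0("pair ", p$pair_index), axis = "v",
                     feature = object$feature_names, loading = p$v)
    )
  })
  df <- dplyr::filter(df, .data$loading != 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$loading,
                                   fill = .data$axis)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~pair, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "loading") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
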