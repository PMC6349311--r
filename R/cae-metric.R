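#' Distance between two canonical spaces
#'
#' Chord distance between correlation structures:
#' `min(||u1-u2|| + ||v1-v2||, ||u1-v2|| + ||v1-u2||)`, additionally
#' minimized over the joint sign flip of one argument. A canonical pair is
#' only defined up to the axis swap (u, v) <-> (v, u) and the joint flip
#' (u, v) <-> (-u, -v) — both encode the same correlation — so the metric is
#' taken over the 4-element group generated by the two, which acts by
#' isometries; distances are then well-defined on equivalence classes and the
#' triangle inequality survives. Zero iff the two spaces coincide up to
#' swap/sign; at most 4 for unit vectors.
#'
#' @param c1,c2 [canonical_pair()] objects of the same dimension,
#'   sign-canonicalized (as produced by [caa()]).
#' @return A non-negative number.
#' @examples
#' p1 <- canonical_pair(c(1, 0, 0), c(0, 1, 0), 1)
#' p2 <- canonical_pair(c(1, 0, 0), c(0, 0, 1), 1)
#' canonical_distance(p1, p2) # sqrt(2)
#' @export
canonical_distance <- function(c1, c2) {
  if (length(c1$u) != length(c2$u)) {
    abort("canonical pairs have different dimensions", class = "cae_data_error")
  }
  e <- function(a, b) sqrt(sum((a - b)^2))
  min(e(c1$u, c2$u) + e(c1$v, c2$v),
      e(c1$u, c2$v) + e(c1$v, c2$u),
      e(c1$u, -c2$u) + e(c1$v, -c2$v),
      e(c1$u, -c2$v) + e(c1$v, -c2$u))
}

# vectorized pairwise distances between two sets of pairs, given stacked
# loading matrices (rows = pairs). Unit norms let chord distances come from
# inner products: ||a-b|| = sqrt(2 - 2 a.b).
.pair_dist_mat <- function(U1, V1, U2, V2) {
  chord <- function(A, B) {
    ip <- pmin(pmax(tcrossprod(A, B), -1), 1)
    sqrt(pmax(2 - 2 * ip, 0))
  }
  duu <- chord(U1, U2)
  dvv <- chord(V1, V2)
  duv <- chord(U1, V2)
  dvu <- chord(V1, U2)
  nuu <- chord(U1, -U2)
  nvv <- chord(V1, -V2)
  nuv <- chord(U1, -V2)
  nvu <- chord(V1, -U2)
  pmin(duu + dvv, duv + dvu, nuu + nvv, nuv + nvu)
}

#' Build a Canonical Autocorrelation Embedding
#'
#' Pools the retained canonical pairs of several fitted subjects into one
#' labeled point set under the canonical distance. Pairs must pass the
#' strict R^2 filter (`r_squared > r2_min`); subjects contributing no
#' admissible pair are recorded in the `deferred` element — downstream
#' classification defers on them rather than fabricating a point.
#'
#' @param models A named list of [caa()] fits (names = subject ids), or a
#'   list of fits carrying `subject_id`s.
#' @param labels Optional labels: a data frame with columns `subject_id` and
#'   `label` (0/1), or a named vector. Unlabeled subjects get `NA`.
#' @param r2_min Strict admission threshold on pair R^2.
#' @param prune_radius Neighbor search radius; the default 2 matches a
#'   quarter-turn-scale rotation of the structure.
#' @return A `cae_embedding`: `points` (tibble with `subject_id`,
#'   `pair_index`, `label`, `r_squared`, `d`), stacked loading matrices,
#'   `deferred` (subject ids with no admissible pair), `prune_radius`,
#'   `metric_version`.
#' @export
build_embedding <- function(models, labels = NULL, r2_min = 0.25,
                            prune_radius = 2) {
  if (prune_radius <= 0) abort("`prune_radius` must be positive", class = "cae_data_error")
  if (inherits(models, "caa_fit")) models <- list(models)
  ids <- names(models) %||% vapply(models, function(f) f$subject_id, character(1))
  if (any(is.na(ids))) abort("subjects must be identified (name the list)", class = "cae_data_error")
  lab <- .label_lookup(labels)
  m <- length(models[[1]]$feature_names)
  rows <- list()
  pairs <- list()
  deferred <- character(0)
  for (s in seq_along(models)) {
    fit <- models[[s]]
    if (length(fit$feature_names) != m) {
      abort("models mix feature spaces of different dimension", class = "cae_data_error")
    }
    kept <- Filter(function(p) p$r_squared > r2_min, fit$pairs)
    if (!length(kept)) {
      deferred <- c(deferred, ids[s])
      next
    }
    for (p in kept) {
      p$subject_id <- ids[s]
      pairs[[length(pairs) + 1]] <- p
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = ids[s], pair_index = p$pair_index,
        label = lab(ids[s]), r_squared = p$r_squared, d = p$d)
    }
  }
  points <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(subject_id = character(), pair_index = integer(),
                   label = numeric(), r_squared = numeric(), d = numeric())
  U <- if (length(pairs)) do.call(rbind, lapply(pairs, `[[`, "u")) else matrix(0, 0, m)
  V <- if (length(pairs)) do.call(rbind, lapply(pairs, `[[`, "v")) else matrix(0, 0, m)
  structure(list(points = points, pairs = pairs, U = U, V = V, m = m,
                 deferred = deferred, prune_radius = prune_radius,
                 r2_min = r2_min, metric_version = "cae-chord-1"),
            class = "cae_embedding")
}

.label_lookup <- function(labels) {
  if (is.null(labels)) return(function(id) NA_real_)
  if (is.data.frame(labels)) {
    v <- stats::setNames(as.numeric(labels$label), labels$subject_id)
  } else {
    v <- as.numeric(labels)
    names(v) <- names(labels)
  }
  function(id) unname(v[id])
}

#' @export
print.cae_embedding <- function(x, ...) {
  cat(sprintf("<cae_embedding: %d points from %d subject(s), %d deferred, radius %.2f>\n",
              nrow(x$points), length(unique(x$points$subject_id)),
              length(x$deferred), x$prune_radius))
  invisible(x)
}

#' @export
tidy.cae_embedding <- function(x, ...) x$points

#' Pairwise distance matrix of an embedding
#'
#' @param e A `cae_embedding`.
#' @return A symmetric matrix of canonical distances between all points.
#' @export
embedding_distances <- function(e) {
  D <- .pair_dist_mat(e$U, e$V, e$U, e$V)
  diag(D) <- 0
  dimnames(D) <- list(paste(e$points$subject_id, e$points$pair_index, sep = ":"),
                      paste(e$points$subject_id, e$points$pair_index, sep = ":"))
  D
}

#' Nearest correlation structures within the pruning radius
#'
#' Exact (brute-force) nearest-neighbor query under the canonical distance.
#' Only points strictly inside `prune_radius` qualify; the result may hold
#' fewer than `k` points, including none. Ties are broken by
#' `(subject_id, pair_index)` for determinism.
#'
#' @param e A `cae_embedding`.
#' @param query A [canonical_pair()].
#' @param k Maximum number of neighbors.
#' @return A tibble of up to `k` rows: the point columns plus `distance`,
#'   ascending.
#' @export
neighbors_within <- function(e, query, k) {
  stopifnot(k >= 1)
  if (length(query$u) != e$m) {
    abort("query dimension does not match the embedding", class = "cae_data_error")
  }
  if (!nrow(e$points)) return(dplyr::mutate(e$points, distance = numeric(0)))
  dist <- as.vector(.pair_dist_mat(matrix(query$u, 1), matrix(query$v, 1), e$U, e$V))
  out <- dplyr::mutate(e$points, distance = dist)
  out <- dplyr::filter(out, .data$distance < e$prune_radius)
  out <- dplyr::arrange(out, .data$distance, .data$subject_id, .data$pair_index)
  head(out, k)
}

#' Plot an embedding
#'
#' Classical multidimensional scaling of the canonical distance matrix,
#' colored by label.
#'
#' @param object A `cae_embedding`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cae_embedding <- function(object, ...) {
  if (nrow(object$points) < 3) abort("need at least 3 points to plot", class = "cae_data_error")
  D <- embedding_distances(object)
  xy <- stats::cmdscale(D, k = 2)
  df <- dplyr::mutate(object$points, x = xy[, 1], y = xy[, 2],
                      label = factor(.data$label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   color = .data$label)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$r_squared), alpha = 0.8) +
    ggplot2::scale_size_continuous(range = c(1, 4)) +
    ggplot2::labs(x = "MDS 1", y = "MDS 2",
                  title = "Canonical autocorrelation embedding") +
    ggplot2::theme_minimal()
}
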