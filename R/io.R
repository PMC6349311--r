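## JSON serialization: models and embeddings travel as sparse index:value
## maps so the files stay small and diff-able.

.sparse_vec <- function(v) {
  idx <- which(v != 0)
  list(index = idx, value = v[idx])
}

.dense_vec <- function(sv, m) {
  v <- numeric(m)
  v[unlist(sv$index)] <- unlist(sv$value)
  v
}

#' Write a CAA model to JSON
#'
#' Per pair: sparse `u`, `v`, `d`, `r_squared`, iteration count and winning
#' restart; the configuration is echoed for reproducibility.
#'
#' @param fit A [caa()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_caa_model <- function(fit, path) {
  pairs <- lapply(fit$pairs, function(p) {
    list(u = .sparse_vec(p$u), v = .sparse_vec(p$v), d = p$d,
         r_squared = p$r_squared, pair_index = p$pair_index,
         iterations = attr(p, "iters"), restart = attr(p, "restart"))
  })
  jsonlite::write_json(
    list(subject_id = fit$subject_id, n_features = length(fit$feature_names),
         feature_names = fit$feature_names, n_obs = fit$n_obs,
         config = unclass(fit$config), pairs = pairs),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a CAA model from JSON
#'
#' @param path A file written by [write_caa_model()].
#' @return A `caa_fit` (without objective traces, which are not serialized).
#' @export
read_caa_model <- function(path) {
  j <- jsonlite::read_json(path)
  m <- j$n_features
  pairs <- lapply(j$pairs, function(p) {
    cp <- canonical_pair(.dense_vec(p$u, m), .dense_vec(p$v, m), p$d,
                         r_squared = p$r_squared, subject_id = j$subject_id,
                         pair_index = p$pair_index)
    .validate_pair(cp)
    cp
  })
  cfg <- do.call(caa_config, j$config)
  structure(list(pairs = pairs, config = cfg,
                 forbidden = forbidden_sets(max(m, 2)),
                 objective_trace = list(),
                 feature_names = unlist(j$feature_names),
                 subject_id = j$subject_id, n_obs = j$n_obs),
            class = "caa_fit")
}

.validate_pair <- function(p) {
  for (nm in c("u", "v")) {
    nrm <- sqrt(sum(p[[nm]]^2))
    if (abs(nrm - 1) > 1e-6) {
      abort(sprintf("invalid canonical pair: ||%s||_2 = %.8f (expected 1)", nm, nrm),
            class = "cae_validation_error")
    }
  }
  if (!is.na(p$d) && p$d < 0) {
    abort("invalid canonical pair: d < 0", class = "cae_validation_error")
  }
  invisible(p)
}

#' Write an embedding to JSON
#'
#' @param e A [build_embedding()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_embedding <- function(e, path) {
  pts <- lapply(seq_along(e$pairs), function(i) {
    p <- e$pairs[[i]]
    list(subject_id = p$subject_id, pair_index = p$pair_index,
         label = e$points$label[i], r_squared = p$r_squared, d = p$d,
         u = .sparse_vec(p$u), v = .sparse_vec(p$v))
  })
  jsonlite::write_json(
    list(m = e$m, prune_radius = e$prune_radius, r2_min = e$r2_min,
         metric_version = e$metric_version, deferred = e$deferred,
         points = pts),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an embedding from JSON, validating pair invariants
#'
#' @param path A file written by [write_embedding()].
#' @return A `cae_embedding`.
#' @export
read_embedding <- function(path) {
  j <- jsonlite::read_json(path)
  m <- j$m
  pairs <- lapply(j$points, function(p) {
    cp <- canonical_pair(.dense_vec(p$u, m), .dense_vec(p$v, m), p$d,
                         r_squared = p$r_squared, subject_id = p$subject_id,
                         pair_index = p$pair_index)
    .validate_pair(cp)
    cp
  })
  points <- purrr::map_dfr(j$points, function(p) {
    tibble::tibble(subject_id = p$subject_id, pair_index = p$pair_index,
                   label = p$label %||% NA_real_, r_squared = p$r_squared,
                   d = p$d)
  })
  U <- if (length(pairs)) do.call(rbind, lapply(pairs, `[[`, "u")) else matrix(0, 0, m)
  V <- if (length(pairs)) do.call(rbind, lapply(pairs, `[[`, "v")) else matrix(0, 0, m)
  structure(list(points = points, pairs = pairs, U = U, V = V, m = m,
                 deferred = unlist(j$deferred) %||% character(0),
                 prune_radius = j$prune_radius, r2_min = j$r2_min,
                 metric_version = j$metric_version),
            class = "cae_embedding")
}

#' Export the pairwise distance matrix as CSV
#'
#' @param e A `cae_embedding`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_distance_matrix <- function(e, path) {
  D <- embedding_distances(e)
  write.csv(as.data.frame(D), path, row.names = TRUE)
  invisible(path)
}
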