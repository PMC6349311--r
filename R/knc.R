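#' k-nearest-correlations configuration
#'
#' @param k Number of neighbors per correlation structure.
#' @param t Discriminativeness threshold in `[0, 0.5)`: a vote with class
#'   probability `q` only enters the subject's log-odds when `|q - 0.5| > t`.
#' @param epsilon Probability clip in `(0, 0.5)` keeping log-odds finite;
#'   defaults to `1/(2k)` (capped at 1/4 so `k = 1` still yields finite,
#'   non-degenerate odds), a Laplace-style stabilization that preserves the
#'   ordering of votes.
#' @param prune_radius Neighbor search radius.
#' @return A `knc_config` object.
#' @export
knc_config <- function(k = 5L, t = 0.1, epsilon = NULL, prune_radius = 2) {
  k <- as.integer(k)
  if (is.null(epsilon)) epsilon <- 1 / (2 * max(k, 2L))
  stopifnot(k >= 1, t >= 0, t < 0.5, epsilon > 0, epsilon < 0.5,
            prune_radius > 0)
  structure(list(k = k, t = t, epsilon = epsilon, prune_radius = prune_radius),
            class = "knc_config")
}

#' Class probability of one correlation structure
#'
#' The vote of a query structure is the mean label of its (up to) `k`
#' nearest labeled structures within the pruning radius. Points sharing the
#' query's `subject_id` are excluded — a structure never votes on its own
#' subject. With fewer than `k` neighbors the available ones are used and
#' counted; with none, the vote is marked non-discriminative regardless of
#' `t`.
#'
#' @param query A [canonical_pair()].
#' @param training A labeled [build_embedding()] result.
#' @param cfg A [knc_config()].
#' @return A one-row tibble: `q`, `n_neighbors_used`, `discriminative`.
#' @export
correlation_vote <- function(query, training, cfg = knc_config()) {
  if (any(is.na(training$points$label))) {
    abort("training embedding contains unlabeled points", class = "cae_data_error")
  }
  e <- training
  e$prune_radius <- cfg$prune_radius
  if (!is.na(query$subject_id) && query$subject_id %in% e$points$subject_id) {
    keep <- which(e$points$subject_id != query$subject_id)
    e$points <- e$points[keep, , drop = FALSE]
    e$pairs <- e$pairs[keep]
    e$U <- e$U[keep, , drop = FALSE]
    e$V <- e$V[keep, , drop = FALSE]
  }
  nb <- neighbors_within(e, query, cfg$k)
  if (!nrow(nb)) {
    return(tibble::tibble(q = 0.5, n_neighbors_used = 0L, discriminative = FALSE))
  }
  q <- mean(nb$label)
  tibble::tibble(q = q, n_neighbors_used = nrow(nb),
                 discriminative = abs(q - 0.5) > cfg$t)
}

#' Aggregate votes into a subject score
#'
#' Thresholded log-odds aggregation: the subject score is the sum, over
#' discriminative votes only, of `log(q~ / (1 - q~))` with `q~` clipped to
#' `[epsilon, 1 - epsilon]`. A subject with no discriminative vote (or no
#' retained correlation at all) is deferred: the system issues no
#' recommendation for it at any threshold.
#'
#' @param votes A tibble of votes as returned by [correlation_vote()]
#'   (possibly zero rows).
#' @param cfg A [knc_config()].
#' @param subject_id Optional identifier carried through.
#' @return A one-row tibble: `subject_id`, `score`, `m_p` (number of
#'   correlations), `n_discriminative`, `deferred`.
#' @export
subject_score <- function(votes, cfg = knc_config(), subject_id = NA_character_) {
  m_p <- if (is.null(votes)) 0L else nrow(votes)
  if (m_p == 0L) {
    return(tibble::tibble(subject_id = subject_id, score = 0, m_p = 0L,
                          n_discriminative = 0L, deferred = TRUE))
  }
  disc <- votes[votes$discriminative, , drop = FALSE]
  if (!nrow(disc)) {
    return(tibble::tibble(subject_id = subject_id, score = 0, m_p = m_p,
                          n_discriminative = 0L, deferred = TRUE))
  }
  qc <- pmin(pmax(disc$q, cfg$epsilon), 1 - cfg$epsilon)
  tibble::tibble(subject_id = subject_id, score = sum(log(qc / (1 - qc))),
                 m_p = m_p, n_discriminative = nrow(disc), deferred = FALSE)
}

#' Score subjects against a training embedding
#'
#' Convenience wrapper: every admissible pair (R^2 filter) of each model
#' votes via [correlation_vote()] against the training embedding, and votes
#' are aggregated with [subject_score()]. Subjects with no admissible pair
#' are deferred.
#'
#' @param models Named list of [caa()] fits to score.
#' @param training A labeled [build_embedding()] result; must not contain
#'   points from the scored subjects (same-subject points are excluded
#'   defensively).
#' @param cfg A [knc_config()].
#' @param r2_min Admission threshold for the scored subjects' pairs.
#' @return A tibble with one row per subject.
#' @export
knc_score <- function(models, training, cfg = knc_config(), r2_min = 0.25) {
  ids <- names(models) %||% vapply(models, function(f) f$subject_id, character(1))
  purrr::map_dfr(seq_along(models), function(s) {
    kept <- Filter(function(p) p$r_squared > r2_min, models[[s]]$pairs)
    votes <- purrr::map_dfr(kept, function(p) {
      p$subject_id <- ids[s]
      correlation_vote(p, training, cfg)
    })
    subject_score(votes, cfg, subject_id = ids[s])
  })
}

#' Deferral-aware decisions
#'
#' @param scores A tibble from [subject_score()] / [knc_score()].
#' @param threshold Operating threshold on the log-odds score.
#' @return `scores` with a `decision` column: `"recommend_positive"` iff the
#'   subject is not deferred and its score exceeds the threshold, else
#'   `"defer"`.
#' @export
predict_with_deferral <- function(scores, threshold) {
  stopifnot(is.finite(threshold))
  dplyr::mutate(scores, decision = ifelse(
    !.data$deferred & .data$score > threshold, "recommend_positive", "defer"))
}

## ---- fast internal scoring on a precomputed distance matrix ----
## points: tibble(subject_id, pair_index, label); D: full pairwise distances.
## For each query point, neighbor candidates are a training subset; ordering
## by (distance, subject_id, pair_index) matches neighbors_within().

.neighbor_labels <- function(D, points, train_idx, q, kmax, radius) {
  cand <- train_idx[points$subject_id[train_idx] != points$subject_id[q]]
  if (!length(cand)) return(numeric(0))
  d <- D[q, cand]
  keep <- d < radius
  cand <- cand[keep]
  d <- d[keep]
  if (!length(cand)) return(numeric(0))
  ord <- order(d, points$subject_id[cand], points$pair_index[cand])
  points$label[cand[ord[seq_len(min(kmax, length(ord)))]]]
}

# scores for a set of query subjects for every (k, t) in a grid, reusing one
# neighbor-label computation at kmax per query point
.knc_scores_grid <- function(D, points, train_idx, query_idx, grid, radius) {
  kmax <- max(grid$k)
  nls <- lapply(query_idx, function(q)
    .neighbor_labels(D, points, train_idx, q, kmax, radius))
  subj <- points$subject_id[query_idx]
  out <- vector("list", nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    k <- grid$k[gi]
    t <- grid$t[gi]
    eps <- 1 / (2 * max(k, 2L))
    q_i <- vapply(nls, function(nl) {
      if (!length(nl)) return(NA_real_)
      mean(nl[seq_len(min(k, length(nl)))])
    }, numeric(1))
    df <- tibble::tibble(subject_id = subj, q = q_i)
    sc <- df |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(
        m_p = dplyr::n(),
        n_discriminative = sum(!is.na(.data$q) & abs(.data$q - 0.5) > t),
        score = {
          qq <- .data$q[!is.na(.data$q) & abs(.data$q - 0.5) > t]
          qq <- pmin(pmax(qq, eps), 1 - eps)
          sum(log(qq / (1 - qq)))
        },
        .groups = "drop") |>
      dplyr::mutate(deferred = .data$n_discriminative == 0L,
                    score = ifelse(.data$deferred, 0, .data$score),
                    k = k, t = t)
    out[[gi]] <- sc
  }
  dplyr::bind_rows(out)
}

#' Tune k and t by inner cross-validation
#'
#' Subject-stratified inner folds are carved from the training cohort; for
#' every `(k, t)` on the grid, inner out-of-fold subject scores are pooled
#' and the configuration maximizing TPR at `FPR <= target_fpr` is selected
#' (deployment-aligned criterion). Ties go to higher AUC, then smaller `k`,
#' then smaller `t`. All of a subject's correlations stay on one side of
#' every split.
#'
#' @param models Named list of [caa()] fits for the training subjects.
#' @param labels Data frame with `subject_id`, `label` (both classes
#'   present).
#' @param grid Data frame of candidate `k`, `t` values; default
#'   `k in {1,3,5,7,9,15}` crossed with `t in {0, 0.05, ..., 0.45}`.
#' @param inner_folds Number of inner folds.
#' @param target_fpr FPR bound defining the tuning criterion.
#' @param r2_min,prune_radius Embedding admission threshold and radius.
#' @param seed Integer seed for the fold split.
#' @return A [knc_config()] with attributes `results` (the per-configuration
#'   tuning table) and `criterion`.
#' @export
tune_k_t <- function(models, labels, grid = knc_default_grid(),
                     inner_folds = 10L, target_fpr = 0.025, r2_min = 0.25,
                     prune_radius = 2, seed = 1L) {
  if (!nrow(grid)) abort("empty tuning grid", class = "cae_data_error")
  if (length(unique(labels$label)) < 2) {
    abort("both classes must be present for tuning", class = "cae_data_error")
  }
  emb <- build_embedding(models, labels = labels, r2_min = r2_min,
                         prune_radius = prune_radius)
  if (nrow(grid) == 1L) {
    return(knc_config(k = grid$k[1], t = grid$t[1], prune_radius = prune_radius))
  }
  D <- .pair_dist_mat(emb$U, emb$V, emb$U, emb$V)
  pts <- emb$points
  folds <- make_folds(labels, n_folds = inner_folds, seed = seed)
  fold_of <- stats::setNames(folds$fold, folds$subject_id)
  pooled <- vector("list", inner_folds)
  for (f in sort(unique(folds$fold))) {
    val_subj <- folds$subject_id[folds$fold == f]
    train_idx <- which(!(pts$subject_id %in% val_subj))
    query_idx <- which(pts$subject_id %in% val_subj)
    if (!length(query_idx)) next
    pooled[[f]] <- .knc_scores_grid(D, pts, train_idx, query_idx, grid,
                                    prune_radius)
  }
  pooled <- dplyr::bind_rows(pooled)
  # subjects with zero admissible pairs never enter the embedding; they are
  # deferred by construction and must still count in the tuning statistic
  missing_subj <- setdiff(labels$subject_id, unique(pts$subject_id))
  if (length(missing_subj)) {
    pooled <- dplyr::bind_rows(
      pooled,
      tidyr::expand_grid(dplyr::distinct(grid, .data$k, .data$t),
                         subject_id = missing_subj) |>
        dplyr::mutate(m_p = 0L, n_discriminative = 0L, score = 0,
                      deferred = TRUE))
  }
  # deferred subjects never score positive: rank them below every real score
  pooled <- dplyr::mutate(pooled,
                          eval_score = ifelse(.data$deferred, -Inf, .data$score))
  lab <- .label_lookup(labels)
  results <- pooled |>
    dplyr::group_by(.data$k, .data$t) |>
    dplyr::summarise(
      tpr = .tpr_at_fpr_scores(.data$eval_score, lab(.data$subject_id), target_fpr),
      auc = .auc_scores(.data$eval_score, lab(.data$subject_id)),
      deferral_rate = mean(.data$deferred),
      .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$tpr), dplyr::desc(.data$auc), .data$k, .data$t)
  best <- results[1, ]
  out <- knc_config(k = best$k, t = best$t, prune_radius = prune_radius)
  attr(out, "results") <- results
  attr(out, "criterion") <- sprintf("TPR @ FPR <= %g (pooled inner CV)", target_fpr)
  out
}

#' Default (k, t) tuning grid
#' @return A tibble crossing `k in {1,3,5,7,9,15}` and `t in {0, 0.05, ..., 0.45}`.
#' @export
knc_default_grid <- function() {
  tidyr::expand_grid(k = c(1L, 3L, 5L, 7L, 9L, 15L), t = seq(0, 0.45, by = 0.05))
}
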