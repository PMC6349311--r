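#' Nested cross-validated CAE pipeline
#'
#' Reproduces the full study design on a cohort: fit CAA per subject
#' (unsupervised, so models can be fitted once), then for every outer fold
#' build the training embedding from training subjects only, tune `(k, t)`
#' by inner cross-validation inside the training fold, and score the held-out
#' subjects. No tuned parameter or embedding ever sees a test subject.
#'
#' @param cohort A [generate_cohort()] / [read_cohort()] result.
#' @param caa_cfg A [caa_config()] used for every subject fit.
#' @param grid `(k, t)` tuning grid, see [knc_default_grid()].
#' @param folds Optional precomputed [make_folds()] plan (for paired
#'   comparison with baselines); built from `seed` when `NULL`.
#' @param n_folds,inner_folds Outer/inner fold counts.
#' @param target_fpr Tuning criterion bound.
#' @param r2_min,prune_radius Embedding admission threshold and radius.
#' @param seed Integer seed (folds and tuning substreams derive from it).
#' @param models Optional named list of prefitted [caa()] models keyed by
#'   subject id (e.g. to reuse fits across label permutations).
#' @return A `cae_cv` object: `scores` (tibble with `subject_id`, `label`,
#'   `fold`, `score`, `m_p`, `n_discriminative`, `deferred`, `roc_score` —
#'   the score with deferred subjects at `-Inf`), `tuned` (per-fold selected
#'   `k`, `t`), `folds`, and `models`.
#' @export
run_cae_pipeline <- function(cohort, caa_cfg = caa_config(),
                             grid = knc_default_grid(), folds = NULL,
                             n_folds = 10L, inner_folds = 10L,
                             target_fpr = 0.025, r2_min = 0.25,
                             prune_radius = 2, seed = 1L, models = NULL) {
  labels <- cohort$labels
  if (is.null(models)) {
    models <- purrr::imap(cohort$data, function(x, id)
      caa(x, caa_cfg, subject_id = id))
  }
  if (is.null(folds)) folds <- make_folds(labels, n_folds = n_folds, seed = seed)
  scores <- list()
  tuned_tbl <- list()
  for (f in sort(unique(folds$fold))) {
    test_subj <- folds$subject_id[folds$fold == f]
    train_subj <- setdiff(labels$subject_id, test_subj)
    train_labels <- dplyr::filter(labels, .data$subject_id %in% train_subj)
    tuned <- tune_k_t(models[train_subj], train_labels, grid = grid,
                      inner_folds = inner_folds, target_fpr = target_fpr,
                      r2_min = r2_min, prune_radius = prune_radius,
                      seed = seed + f)
    emb <- build_embedding(models[train_subj], labels = train_labels,
                           r2_min = r2_min, prune_radius = prune_radius)
    sc <- knc_score(models[test_subj], emb, tuned, r2_min = r2_min)
    sc$fold <- f
    scores[[f]] <- sc
    tuned_tbl[[f]] <- tibble::tibble(fold = f, k = tuned$k, t = tuned$t)
  }
  scores <- dplyr::bind_rows(scores) |>
    dplyr::left_join(labels, by = "subject_id") |>
    dplyr::mutate(roc_score = ifelse(.data$deferred, -Inf, .data$score)) |>
    dplyr::arrange(.data$subject_id)
  structure(list(scores = scores, tuned = dplyr::bind_rows(tuned_tbl),
                 folds = folds, models = models),
            class = "cae_cv")
}

#' @export
print.cae_cv <- function(x, ...) {
  cat(sprintf("<cae_cv: %d subjects, %d folds, %.0f%% deferred>\n",
              nrow(x$scores), length(unique(x$scores$fold)),
              100 * mean(x$scores$deferred)))
  invisible(x)
}

#' @export
glance.cae_cv <- function(x, ...) {
  roc <- roc_with_ci(x$scores$roc_score, x$scores$label, n_boot = 0L)
  tibble::tibble(auc = roc$auc,
                 tpr_at_fpr_05 = tpr_at_fpr(roc, 0.05)$tpr,
                 deferral_rate = mean(x$scores$deferred),
                 n_subjects = nrow(x$scores))
}

# Euclidean k-nn positive-vote fraction via class::knn
.knn_frac_pos <- function(train_x, train_y, test_x, k) {
  pred <- class::knn(train_x, test_x, factor(train_y, levels = c(0, 1)),
                     k = k, prob = TRUE, use.all = TRUE)
  p <- attr(pred, "prob")
  ifelse(pred == "1", p, 1 - p)
}

.scale_by_train <- function(train_x, test_x) {
  mu <- colMeans(train_x)
  sdv <- apply(train_x, 2, sd)
  sdv[sdv == 0] <- 1
  list(train = sweep(sweep(train_x, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(test_x, 2, mu), 2, sdv, "/"))
}

#' Quartile- and last-point-featurized baselines
#'
#' The standard featurize-then-classify comparison: per subject either the
#' three quartiles of every feature over the window ("sets") or the final
#' recorded row ("points"), fed to L1-regularized logistic regression
#' (glmnet) and to Euclidean k-nn. Evaluated on the *same* fold plan as the
#' CAE pipeline for a paired comparison; hyperparameters (lasso penalty,
#' neighbor count) are tuned inside each training fold.
#'
#' @param cohort A cohort object; baselines consume the raw, unstandardized
#'   matrices (marginal information is part of their signal).
#' @param folds A [make_folds()] plan.
#' @param methods Subset of `"logit_sets"`, `"logit_points"`, `"knn_sets"`,
#'   `"knn_points"`.
#' @param knn_grid Candidate neighbor counts for the k-nn baselines.
#' @param target_fpr Tuning criterion bound for k-nn (same
#'   deployment-aligned criterion as the CAE tuner).
#' @param inner_folds Inner folds for hyperparameter tuning.
#' @param seed Integer seed.
#' @return A tibble: `method`, `subject_id`, `label`, `fold`, `score`,
#'   `deferred` (always `FALSE`: baselines never defer), `roc_score`.
#' @export
run_baselines <- function(cohort, folds,
                          methods = c("logit_sets", "logit_points",
                                      "knn_sets", "knn_points"),
                          knn_grid = c(1L, 3L, 5L, 7L, 9L, 15L),
                          target_fpr = 0.025, inner_folds = 10L, seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  labels <- cohort$labels
  feats <- list(
    sets = t(vapply(cohort$data, quartile_featurize,
                    quartile_featurize(cohort$data[[1]]))),
    points = t(vapply(cohort$data, last_point_featurize,
                      last_point_featurize(cohort$data[[1]])))
  )
  y <- stats::setNames(labels$label, labels$subject_id)
  out <- list()
  for (method in methods) {
    kind <- sub("^.*_", "", method)
    learner <- sub("_.*$", "", method)
    X <- feats[[kind]][labels$subject_id, , drop = FALSE]
    for (f in sort(unique(folds$fold))) {
      test_subj <- folds$subject_id[folds$fold == f]
      tr <- !(labels$subject_id %in% test_subj)
      Xtr <- X[tr, , drop = FALSE]
      ytr <- y[labels$subject_id[tr]]
      Xte <- X[!tr, , drop = FALSE]
      inner <- make_folds(labels[tr, ], n_folds = inner_folds, seed = seed + f)
      foldid <- inner$fold[match(labels$subject_id[tr], inner$subject_id)]
      if (learner == "logit") {
        cvfit <- withr::with_seed(seed + f, glmnet::cv.glmnet(
          Xtr, ytr, family = "binomial", alpha = 1, foldid = foldid))
        sc <- as.vector(predict(cvfit, Xte, s = "lambda.min",
                                type = "response"))
      } else {
        sx <- .scale_by_train(Xtr, Xte)
        # tune k on pooled inner out-of-fold vote fractions
        tune <- vapply(knn_grid, function(k) {
          pooled_s <- numeric(0)
          pooled_y <- numeric(0)
          for (g in sort(unique(foldid))) {
            if (length(unique(ytr[foldid != g])) < 2) next
            s <- .knn_frac_pos(sx$train[foldid != g, , drop = FALSE],
                               ytr[foldid != g],
                               sx$train[foldid == g, , drop = FALSE],
                               min(k, sum(foldid != g)))
            pooled_s <- c(pooled_s, s)
            pooled_y <- c(pooled_y, ytr[foldid == g])
          }
          c(.tpr_at_fpr_scores(pooled_s, pooled_y, target_fpr),
            .auc_scores(pooled_s, pooled_y))
        }, numeric(2))
        best_k <- knn_grid[order(-tune[1, ], -tune[2, ], knn_grid)][1]
        sc <- .knn_frac_pos(sx$train, ytr, sx$test,
                            min(best_k, nrow(sx$train)))
      }
      out[[length(out) + 1]] <- tibble::tibble(
        method = method, subject_id = rownames(Xte) %||% labels$subject_id[!tr],
        label = y[labels$subject_id[!tr]], fold = f, score = sc,
        deferred = FALSE, roc_score = sc)
    }
  }
  dplyr::bind_rows(out) |> dplyr::arrange(.data$method, .data$subject_id)
}

#' Summarize cross-validated scores
#'
#' One row per method: AUC with bootstrap CI, TPR at the requested FPR
#' bounds, and deferral rate.
#'
#' @param scores A tibble with columns `method` (optional), `subject_id`,
#'   `label`, `roc_score`, `deferred`.
#' @param fpr_targets FPR bounds to report TPR at.
#' @param n_boot Bootstrap replicates for CIs.
#' @param seed Integer seed.
#' @return A tibble.
#' @export
cv_summary <- function(scores, fpr_targets = c(0.025, 0.05), n_boot = 1000L,
                       seed = 1L) {
  if (!"method" %in% names(scores)) scores$method <- "cae"
  scores |>
    dplyr::group_by(.data$method) |>
    dplyr::group_modify(function(df, key) {
      roc <- roc_with_ci(df$roc_score, df$label, n_boot = n_boot, seed = seed)
      row <- tibble::tibble(auc = roc$auc, auc_lo = roc$auc_ci[1],
                            auc_hi = roc$auc_ci[2],
                            deferral_rate = mean(df$deferred))
      for (ft in fpr_targets) {
        tt <- tpr_at_fpr(roc, ft)
        row[[sprintf("tpr_at_fpr_%g", ft)]] <- tt$tpr
        row[[sprintf("tpr_lo_%g", ft)]] <- tt$ci_lo
        row[[sprintf("tpr_hi_%g", ft)]] <- tt$ci_hi
      }
      row
    }) |>
    dplyr::ungroup()
}
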