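# build a labeled embedding from explicit pairs
embed_pairs <- function(pairs, labels) {
  m <- length(pairs[[1]]$u)
  ids <- vapply(pairs, function(p) p$subject_id, "")
  models <- purrr::imap(split(pairs, ids), function(ps, id) {
    structure(list(pairs = ps, config = caa_config(),
                   forbidden = forbidden_sets(m), objective_trace = list(),
                   feature_names = sprintf("f%d", 1:m), subject_id = id,
                   n_obs = 100L), class = "caa_fit")
  })
  build_embedding(models, labels = labels)
}

test_that("a correlation's vote is the mean label of its nearest neighbors", {
  m <- 6
  base <- random_pair(m, seed = 1)
  # five close neighbors (labels 1,1,1,1,0) and two far points
  mk <- function(id, eps_seed, idx) {
    delta <- withr::with_seed(eps_seed, rnorm(m, sd = 0.01))
    u <- base$u + delta
    p <- canonical_pair(u / sqrt(sum(u^2)), base$v, 0.5, r_squared = 0.6,
                        subject_id = id, pair_index = idx)
    p
  }
  far <- function(id) {
    p <- random_pair(m, seed = 999)
    p$u <- c(0, 1, 0, 0, 0, 0)[1:m] # supports disjoint from the base pair,
    p$v <- c(0, 0, 0, 0, 1, 0)[1:m] # so every group element is ~2.83 away
    p$subject_id <- id
    p$r_squared <- 0.6
    p
  }
  pairs <- c(lapply(1:5, function(i) mk(paste0("n", i), i, 0)),
             list(far("f1"), far("f2")))
  labels <- c(n1 = 1, n2 = 1, n3 = 1, n4 = 1, n5 = 0, f1 = 0, f2 = 0)
  emb <- embed_pairs(pairs, labels)
  q <- base
  q$subject_id <- "query"
  v <- correlation_vote(q, emb, knc_config(k = 5))
  expect_equal(v$q, 0.8)
  expect_identical(v$n_neighbors_used, 5L)
  expect_true(v$discriminative)

  # fewer neighbors than k: uses what exists
  v2 <- correlation_vote(q, emb, knc_config(k = 20, prune_radius = 0.5))
  expect_identical(v2$n_neighbors_used, 5L)

  # zero neighbors in radius: non-discriminative whatever t says
  v3 <- correlation_vote(q, emb, knc_config(k = 5, t = 0, prune_radius = 1e-9))
  expect_false(v3$discriminative)
  expect_identical(v3$n_neighbors_used, 0L)

  # structures never vote on their own subject
  q_own <- pairs[[1]]
  v4 <- correlation_vote(q_own, emb, knc_config(k = 5))
  nb <- neighbors_within(emb, q_own, 5)
  expect_true("n1" %in% nb$subject_id) # present in the raw neighbor list
  expect_identical(v4$n_neighbors_used, 4L) # n2..n5; far points are pruned
  expect_equal(v4$q, mean(c(1, 1, 1, 0)))

  # unlabeled training points are an error
  emb_na <- embed_pairs(pairs, labels = c(n1 = 1, n2 = 1, n3 = 1, n4 = 1,
                                          n5 = 0, f1 = 0)[names(labels)])
  expect_error(correlation_vote(q, emb_na, knc_config()),
               class = "cae_data_error")
})

test_that("vote aggregation reproduces the log-odds worked examples", {
  cfg <- knc_config(k = 5, t = 0)
  votes <- tibble::tibble(q = c(0.8, 0.8), n_neighbors_used = 5L,
                          discriminative = TRUE)
  expect_equal(subject_score(votes, cfg)$score, log(16), tolerance = 1e-10)

  votes2 <- tibble::tibble(q = c(0.9, 0.1), n_neighbors_used = 5L,
                           discriminative = TRUE)
  expect_equal(subject_score(votes2, cfg)$score, 0, tolerance = 1e-12)

  cfg3 <- knc_config(k = 5, t = 0.25)
  votes3 <- tibble::tibble(q = 0.6, n_neighbors_used = 5L,
                           discriminative = abs(0.6 - 0.5) > 0.25)
  s3 <- subject_score(votes3, cfg3)
  expect_true(s3$deferred)
  expect_identical(s3$n_discriminative, 0L)

  # empty vote set defers
  s4 <- subject_score(tibble::tibble(q = numeric(), n_neighbors_used = integer(),
                                     discriminative = logical()), cfg)
  expect_true(s4$deferred)
})

test_that("with t = 0 and tiny epsilon the unthresholded aggregation returns", {
  qs <- c(0.2, 0.4, 0.6, 0.8)
  votes <- tibble::tibble(q = qs, n_neighbors_used = 5L, discriminative = TRUE)
  cfg <- knc_config(k = 5, t = 0, epsilon = 1e-12)
  expect_equal(subject_score(votes, cfg)$score, sum(log(qs / (1 - qs))),
               tolerance = 1e-8)
})

test_that("scores are monotone in added positive votes and antisymmetric in labels", {
  cfg <- knc_config(k = 5, t = 0.05)
  for (s in 1:20) {
    qs <- withr::with_seed(s, round(runif(4), 2))
    votes <- tibble::tibble(q = qs, n_neighbors_used = 5L,
                            discriminative = abs(qs - 0.5) > cfg$t)
    base <- subject_score(votes, cfg)$score
    plus <- dplyr::bind_rows(votes, tibble::tibble(q = 0.9, n_neighbors_used = 5L,
                                                   discriminative = TRUE))
    expect_gte(subject_score(plus, cfg)$score, base)
    # label swap: q -> 1 - q negates the score exactly (clip is symmetric)
    flipped <- dplyr::mutate(votes, q = 1 - q)
    expect_equal(subject_score(flipped, cfg)$score, -base, tolerance = 1e-10)
  }
})

test_that("deferral dominates every operating threshold", {
  scores <- tibble::tibble(subject_id = c("a", "b", "c"),
                           score = c(3, 1.5, 99), m_p = c(3L, 2L, 0L),
                           n_discriminative = c(2L, 1L, 0L),
                           deferred = c(FALSE, FALSE, TRUE))
  dec <- predict_with_deferral(scores, threshold = 2)
  expect_identical(dec$decision, c("recommend_positive", "defer", "defer"))
})

test_that("tuning returns a singleton grid unchanged and separates a clean cohort", {
  co <- tiny_cohort(n_per_class = 8, seed = 13)
  models <- fit_cohort_models(co)

  single <- tune_k_t(models, co$labels, grid = tibble::tibble(k = 3L, t = 0.1),
                     inner_folds = 4)
  expect_identical(single$k, 3L)
  expect_identical(single$t, 0.1)

  tuned <- tune_k_t(models, co$labels,
                    grid = tidyr::expand_grid(k = c(1L, 3L, 5L),
                                              t = c(0, 0.1, 0.2, 0.3)),
                    inner_folds = 4, seed = 5)
  res <- attr(tuned, "results")
  expect_s3_class(res, "tbl_df")
  # a planted discriminative structure is recoverable: perfect inner TPR at
  # zero false positives for the winning configuration
  expect_gte(res$tpr[1], 0.9)

  # label permutation drives the tuning statistic to chance level
  perm_labels <- co$labels
  perm_labels$label <- withr::with_seed(99, sample(perm_labels$label))
  tuned_perm <- tune_k_t(models, perm_labels,
                         grid = tidyr::expand_grid(k = c(1L, 3L, 5L),
                                                   t = c(0, 0.1, 0.2, 0.3)),
                         inner_folds = 4, seed = 5)
  res_perm <- attr(tuned_perm, "results")
  expect_lt(max(res_perm$auc), 0.85)

  expect_error(tune_k_t(models, dplyr::mutate(co$labels, label = 1),
                        inner_folds = 4), class = "cae_data_error")
})
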