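# shared fixture builders; everything is generated in code at test time

# raw matrix with one planted two-block structure (single latent factor)
planted_matrix <- function(n, m, block_a = 1:3, block_b = 4:6, r2 = 0.8,
                           seed = 1) {
  cfg <- cohort_config(n_subjects_per_class = 1, n_features = m,
                       n_timesteps = n,
                       shared_structures = list(structure_spec(block_a, block_b, r2)),
                       class1_structures = list(), seed = seed)
  generate_subject(cfg, 0, seed = seed)$x
}

noise_matrix <- function(n, m, seed = 1) {
  cfg <- cohort_config(n_subjects_per_class = 1, n_features = m,
                       n_timesteps = n, shared_structures = list(),
                       class1_structures = list(), seed = seed)
  generate_subject(cfg, 0, seed = seed)$x
}

random_psd <- function(m, seed = 1) {
  withr::with_seed(seed, {
    A <- matrix(rnorm(m * m), m, m)
    crossprod(A) / m
  })
}

# random sparse unit vector on a given support
unit_on <- function(m, support, seed = 1) {
  withr::with_seed(seed, {
    v <- numeric(m)
    v[support] <- rnorm(length(support))
    v / sqrt(sum(v^2))
  })
}

# random canonicalized pair with disjoint supports
random_pair <- function(m, seed = 1, k_u = 2, k_v = 2) {
  withr::with_seed(seed, {
    idx <- sample.int(m, k_u + k_v)
    u <- numeric(m); u[idx[1:k_u]] <- rnorm(k_u)
    v <- numeric(m); v[idx[(k_u + 1):(k_u + k_v)]] <- rnorm(k_v)
    u <- u / sqrt(sum(u^2))
    v <- v / sqrt(sum(v^2))
    if (u[which.max(abs(u))] < 0) { u <- -u; v <- -v }
    canonical_pair(u, v, d = runif(1), r_squared = runif(1, 0.3, 1),
                   subject_id = paste0("r", seed), pair_index = 0L)
  })
}

# tiny, fast cohort with one shared and one class-1 structure
tiny_cohort <- function(n_per_class = 8, m = 12, n_t = 600, seed = 7,
                        r2 = 0.85) {
  cfg <- cohort_config(
    n_subjects_per_class = n_per_class, n_features = m, n_timesteps = n_t,
    shared_structures = list(structure_spec(1:2, 3:4, r2)),
    class1_structures = list(structure_spec(5:6, 7:8, r2)),
    seed = seed)
  generate_cohort(cfg)
}

fast_caa_cfg <- function(...) caa_config(max_pairs = 3, n_restarts = 4, ...)

fit_cohort_models <- function(cohort, cfg = fast_caa_cfg()) {
  purrr::imap(cohort$data, function(x, id) caa(x, cfg, subject_id = id))
}

# scipy SLSQP oracle for the convex half-step (see inst/oracle)
oracle_l1lp <- function(instances) {
  script <- system.file("oracle", "solve_subproblem.py", package = "cae")
  stopifnot(nzchar(script))
  inp <- tempfile(fileext = ".json")
  jsonlite::write_json(instances, inp, auto_unbox = FALSE, digits = NA)
  out <- system2("python", script, stdout = TRUE, stdin = inp)
  unlist(jsonlite::fromJSON(paste(out, collapse = "")))
}

# exhaustive-threshold oracle for TPR at bounded FPR
brute_tpr_at_fpr <- function(scores, labels, fpr_target) {
  ths <- c(-Inf, sort(unique(scores)), Inf)
  best <- 0
  for (th in ths) {
    fpr <- mean(scores[labels == 0] > th)
    tpr <- mean(scores[labels == 1] > th)
    if (fpr <= fpr_target) best <- max(best, tpr)
  }
  best
}
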