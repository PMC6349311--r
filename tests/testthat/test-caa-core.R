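test_that("weighted soft-thresholding matches its definition", {
  expect_equal(soft_threshold_weighted(3, 1), 2)
  expect_equal(soft_threshold_weighted(-0.5, 1), 0)
  g <- c(1, -2, 3)
  expect_equal(soft_threshold_weighted(g, 0), g)
  expect_equal(soft_threshold_weighted(g, c(0.5, 0.5, 10)), c(0.5, -1.5, 0))
  expect_error(soft_threshold_weighted(g, -1), class = "cae_data_error")
})

test_that("lambda1 is the smallest multiplier zeroing the forbidden support", {
  expect_equal(compute_lambda1(c(2, 3), c(1, 0.5)), 6)
  expect_equal(compute_lambda1(c(2, 3), c(1, 0)), 2)
  expect_error(compute_lambda1(c(1, 1), c(0, 0)), class = "cae_degenerate_step")

  for (s in 1:20) {
    m <- 6
    g <- withr::with_seed(100 + s, rnorm(m))
    v <- unit_on(m, sample_support <- withr::with_seed(s, sample.int(m, 3)),
                 seed = s)
    fb <- forbidden_sets(m)
    lam1 <- compute_lambda1(g, v, fb)
    w <- vapply(fb, function(sj) sum(abs(v[sj])), numeric(1))
    thr <- soft_threshold_weighted(g, lam1 * w)
    # forbidden support exactly zeroed, free coordinates untouched
    expect_true(all(abs(thr[v != 0]) < 1e-12))
    expect_equal(thr[v == 0], g[v == 0])
    # smallest such multiplier: shrinking it lets a forbidden coord survive
    if (any(abs(g[v != 0]) > 1e-8)) {
      thr2 <- soft_threshold_weighted(g, 0.99 * lam1 * w)
      expect_true(any(thr2[v != 0] != 0))
    }
  }
})

test_that("the KKT half-step reproduces hand-computed solutions", {
  G <- matrix(c(1, .9, .1, .9, 1, .2, .1, .2, 1), 3, 3)
  st <- kkt_solve_step(G, c(1, 0, 0), c = 1.2)
  expected <- c(0, .9, .1) / sqrt(.9^2 + .1^2)
  expect_equal(st$u, expected, tolerance = 1e-10)
  expect_equal(st$params$lambda2, 0)
  expect_equal(sqrt(sum(st$u^2)), 1, tolerance = 1e-10)

  # m = 2: the only unit vector with support disjoint from e1 is +/- e2
  G2 <- matrix(c(1, .3, .3, 1), 2, 2)
  st2 <- kkt_solve_step(G2, c(1, 0), c = sqrt(2))
  expect_equal(abs(st2$u), c(0, 1), tolerance = 1e-12)

  # degenerate: nothing correlates with v's support
  expect_error(kkt_solve_step(diag(3), c(1, 0, 0), c = 1.5),
               class = "cae_degenerate_step")
})

test_that("an active L1 constraint is met to tolerance by the bisection", {
  for (s in 1:10) {
    G <- random_psd(6, seed = s)
    v <- unit_on(6, 1:2, seed = s)
    cc <- 1.3
    st <- kkt_solve_step(G, v, c = cc)
    l1 <- sum(abs(st$u))
    expect_lte(l1, cc * (1 + 1e-8))
    if (st$params$lambda2 > 0) expect_equal(l1, cc, tolerance = 1e-6)
    expect_equal(sqrt(sum(st$u^2)), 1, tolerance = 1e-10)
    # disjointness against v is exact
    expect_identical(sum(abs(st$u[v != 0])), 0)
  }
})

test_that("alternating search ascends and returns a feasible canonical pair", {
  x <- planted_matrix(1500, 10, seed = 3)
  fm <- standardize_columns(x)
  G <- crossprod(unclass(fm)) / (nrow(fm) - 1)
  pair <- alternate_convex_search(G, caa_config(n_restarts = 4))
  trace <- attr(pair, "trace")
  expect_true(all(diff(trace) >= -1e-10))
  expect_equal(sqrt(sum(pair$u^2)), 1, tolerance = 1e-8)
  expect_equal(sqrt(sum(pair$v^2)), 1, tolerance = 1e-8)
  expect_lte(sum(abs(pair$u)), 1.5 * (1 + 1e-8))
  expect_identical(sum(abs(pair$u * pair$v)), 0)
  expect_gte(pair$d, 0)
  # sign canonicalization: dominant coordinate of u positive
  expect_gt(pair$u[which.max(abs(pair$u))], 0)
  # recovered structure lies in the planted clique
  supp <- union(which(pair$u != 0), which(pair$v != 0))
  expect_true(all(supp %in% 1:6))
})

test_that("initializing from either block yields the same structure", {
  # one planted 1-1 relation, so the optimum is unique up to the u/v swap
  x <- planted_matrix(2000, 8, block_a = 1, block_b = 2, r2 = 0.9, seed = 5)
  fm <- standardize_columns(x)
  G <- crossprod(unclass(fm)) / (nrow(fm) - 1)
  # c = 1 forces one coordinate per axis, so the fixed point is unique up to
  # the swap and the two runs must coincide under the canonical metric
  cfg <- caa_config(c1 = 1, c2 = 1)
  p1 <- alternate_convex_search(G, cfg, v_init = c(1, 0, 0, 0, 0, 0, 0, 0))
  p2 <- alternate_convex_search(G, cfg, v_init = c(0, 1, 0, 0, 0, 0, 0, 0))
  expect_lt(canonical_distance(p1, p2), 1e-4)
  expect_equal(p1$d, p2$d, tolerance = 1e-5)
})

test_that("pair R^2 matches the projection correlation", {
  # exact linear relation, no noise
  z <- withr::with_seed(1, rnorm(300))
  x <- cbind(z, 2 * z, withr::with_seed(2, rnorm(300)), withr::with_seed(3, rnorm(300)))
  p <- canonical_pair(c(1, 0, 0, 0), c(0, 1, 0, 0), 1)
  expect_equal(compute_r_squared(x, p), 1, tolerance = 1e-10)
  # independent blocks: near-zero
  xn <- noise_matrix(7200, 6, seed = 9)
  pn <- canonical_pair(unit_on(6, 1:2, 1), unit_on(6, 4:5, 2), 0.1)
  expect_lt(compute_r_squared(xn, pn), 0.01)
  # zero-variance projection warns and returns 0
  p0 <- canonical_pair(c(0, 0, 0, 0), c(0, 1, 0, 0), 0)
  expect_warning(r0 <- compute_r_squared(x, p0), "zero-variance")
  expect_identical(r0, 0)
})

test_that("deflation removes exactly the discovered correlation", {
  G <- diag(4)
  G[1, 2] <- G[2, 1] <- 0.9
  p <- canonical_pair(c(1, 0, 0, 0), c(0, 1, 0, 0), d = 0.9)
  Gd <- deflate_gram(G, p)
  expect_equal(Gd[1, 2], 0)
  expect_equal(Gd, t(Gd))
  for (s in 1:20) {
    Gs <- random_psd(8, seed = s)
    pr <- random_pair(8, seed = s)
    pr$d <- as.numeric(pr$u %*% Gs %*% pr$v)
    Gd <- deflate_gram(Gs, pr)
    expect_lt(abs(as.numeric(pr$u %*% Gd %*% pr$v)), 1e-8)
  }
})

test_that("multi-pair extraction orders structures by strength", {
  cfg2 <- cohort_config(
    n_subjects_per_class = 1, n_features = 14, n_timesteps = 2500,
    shared_structures = list(structure_spec(1:3, 4:6, 0.9),
                             structure_spec(7:9, 10:12, 0.6)),
    class1_structures = list(), seed = 2)
  x <- generate_subject(cfg2, 0, seed = 21)$x
  fit <- caa(x, caa_config(max_pairs = 4, n_restarts = 6))
  expect_gte(length(fit$pairs), 2)
  supp1 <- union(which(fit$pairs[[1]]$u != 0), which(fit$pairs[[1]]$v != 0))
  expect_true(all(supp1 %in% 1:6)) # stronger clique first
  # no retained pair mixes the two planted structures
  for (p in fit$pairs) {
    supp <- union(which(p$u != 0), which(p$v != 0))
    expect_false(any(supp %in% 1:6) && any(supp %in% 7:12))
  }
  # max_pairs = 1 returns only the stronger structure
  fit1 <- caa(x, caa_config(max_pairs = 1, n_restarts = 6))
  expect_length(fit1$pairs, 1)
  expect_equal(fit1$pairs[[1]]$d, fit$pairs[[1]]$d)
  # all retained pairs clear the R^2 filter strictly
  expect_true(all(vapply(fit$pairs, function(p) p$r_squared, 1) > 0.25))
})

test_that("fit accessors tidy/glance expose the pair table", {
  x <- planted_matrix(800, 8, block_a = 1:2, block_b = 3:4, seed = 4)
  fit <- caa(x, fast_caa_cfg(), subject_id = "subjA")
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("pair_index", "d", "r_squared") %in% names(td)))
  gl <- glance(fit)
  expect_identical(gl$n_pairs, nrow(td))
  expect_identical(gl$n_features, 8L)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("budgets outside [1, sqrt(m)] are rejected", {
  x <- planted_matrix(400, 6, block_a = 1:2, block_b = 3:4, seed = 1)
  expect_error(caa(x, caa_config(c1 = 3)), class = "cae_data_error")
  expect_error(caa_config(c1 = 0.5))
})

test_that("polynomial expansion finds quadratic relations between features", {
  ex <- expand_polynomial_features(withr::with_seed(1, matrix(rnorm(60), 30, 2)),
                                   degree = 2)
  expect_identical(ncol(ex$x), 4L)
  expect_identical(ex$forbidden[[1]], c(1L, 3L))
  expect_identical(ex$forbidden[[2]], c(2L, 4L))
  expect_identical(ex$forbidden[[3]], c(1L, 3L))

  # y = x^2 across two distinct features becomes linear after expansion
  tt <- withr::with_seed(8, rnorm(3000))
  x <- cbind(a = tt, b = tt^2 + withr::with_seed(9, rnorm(3000, sd = 0.1)),
             c = withr::with_seed(10, rnorm(3000)))
  ex <- expand_polynomial_features(x, degree = 2)
  fit <- caa(ex$x, caa_config(max_pairs = 1, n_restarts = 6),
             forbidden = ex$forbidden)
  expect_length(fit$pairs, 1)
  p <- fit$pairs[[1]]
  expect_gt(p$r_squared, 0.9)
  supp_u <- which(p$u != 0)
  supp_v <- which(p$v != 0)
  # the a^2 column (index 4) pairs with b (index 2)
  expect_true(4 %in% c(supp_u, supp_v) && 2 %in% c(supp_u, supp_v))
  # supports never co-activate a feature with its own power
  for (i in supp_u) expect_false(any(ex$forbidden[[i]] %in% supp_v))
})

test_that("expansion on random data never violates the power groups", {
  for (s in 1:5) {
    x <- withr::with_seed(s, matrix(rnorm(200 * 4), 200, 4))
    ex <- expand_polynomial_features(x, degree = 2)
    fit <- caa(ex$x, caa_config(r2_min = 0, max_pairs = 2, n_restarts = 3),
               forbidden = ex$forbidden)
    for (p in fit$pairs) {
      for (i in which(p$u != 0)) {
        expect_false(any(ex$forbidden[[i]] %in% which(p$v != 0)))
      }
    }
  }
})
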