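#' Weighted soft-thresholding operator
#'
#' Applies `sign(g) * max(|g| - theta, 0)` coordinate-wise. This is the
#' proximal operator behind the KKT solution of each CAA half-step: the
#' per-coordinate threshold is `lambda1 * w_i + lambda2`, where the first
#' term enforces the disjoint-support constraint and the second the L1
#' budget.
#'
#' @param g Numeric vector (typically a gradient `G %*% v`).
#' @param theta Non-negative thresholds, scalar or one per coordinate.
#' @return Numeric vector of the same length as `g`.
#' @examples
#' soft_threshold_weighted(c(1, -2, 3), c(0.5, 0.5, 10))
#' @export
soft_threshold_weighted <- function(g, theta) {
  if (any(theta < 0)) abort("thresholds must be non-negative", class = "cae_data_error")
  sign(g) * pmax(abs(g) - theta, 0)
}

# disjointness weights: w_i = sum_{j in S_i} |v_j|
.support_weights <- function(v, forbidden) {
  vapply(forbidden, function(s) sum(abs(v[s])), numeric(1))
}

#' Smallest disjointness multiplier
#'
#' Returns the smallest lambda1 such that soft-thresholding the gradient `g`
#' at per-coordinate level `lambda1 * w_i`, with `w_i = sum_{j in S_i} |v_j|`,
#' zeroes every coordinate whose activation is forbidden by the support of
#' `v`. Coordinates with `w_i = 0` (no forbidden partner active in `v`) are
#' unaffected by the disjointness term.
#'
#' @param g Gradient vector, `G %*% v`.
#' @param v Current value of the opposite canonical vector; must be non-zero.
#' @param forbidden A [forbidden_sets()] object (`NULL` for the default
#'   self-correlation sets).
#' @return A single non-negative number.
#' @examples
#' compute_lambda1(c(2, 3), c(1, 0.5), forbidden_sets(2))
#' @export
compute_lambda1 <- function(g, v, forbidden = NULL) {
  forbidden <- .check_forbidden(forbidden, length(v))
  if (all(v == 0)) abort("`v` is identically zero; re-initialize", class = "cae_degenerate_step")
  w <- .support_weights(v, forbidden)
  idx <- which(w > 0)
  max(abs(g[idx]) / w[idx])
}

# canonical sign: flip (u, v) jointly so the largest-|.| coordinate of u is
# positive; ties resolved to the lowest index by which.max.
.sign_canonicalize <- function(u, v) {
  i <- which.max(abs(u))
  if (u[i] < 0) list(u = -u, v = -v) else list(u = u, v = v)
}

#' One KKT-derived half-step of the CAA search
#'
#' Solves the convex subproblem `max_u u' G v` subject to `||u||_2 <= 1`,
#' `||u||_1 <= c` and support disjointness against `v` under the forbidden
#' sets. The solution is a soft-thresholded, renormalized gradient: the
#' disjointness multiplier `lambda1` is computed in closed form and, when the
#' L1 constraint is active, `lambda2` is found by bisection so that
#' `||u||_1 = c` (the L1 norm of the normalized thresholded gradient is
#' continuous and non-increasing in `lambda2`).
#'
#' @param G Symmetric positive semi-definite gram matrix (here, a sample
#'   correlation matrix).
#' @param v Current opposite canonical vector (unit L2 norm or less).
#' @param c L1 budget in `[1, sqrt(m)]`.
#' @param forbidden A [forbidden_sets()] object or `NULL` for the default.
#' @return A list with elements `u` (unit L2 norm) and `params`
#'   (`lambda1`, `lambda2`). Signals a condition of class
#'   `cae_degenerate_step` when the thresholded gradient is identically zero
#'   (every admissible correlate of `v`'s support is forbidden or
#'   uncorrelated).
#' @export
kkt_solve_step <- function(G, v, c, forbidden = NULL) {
  m <- length(v)
  forbidden <- .check_forbidden(forbidden, m)
  g <- as.vector(G %*% v)
  lam1 <- compute_lambda1(g, v, forbidden)
  w <- .support_weights(v, forbidden)
  forb <- which(w > 0)
  thr <- function(lam2) {
    u <- soft_threshold_weighted(g, lam1 * w + lam2)
    u[forb] <- 0 # guard floating-point residue at the boundary
    u
  }
  nrm2 <- function(x) sqrt(sum(x^2))
  u0 <- thr(0)
  # a free gradient at floating-point-residue level (e.g. an exactly deflated
  # column) carries no structure: treat as degenerate, not as signal
  if (all(u0 == 0) || max(abs(u0)) <= 1e-12 * max(1, max(abs(g)))) {
    abort("degenerate step: thresholded gradient is identically zero",
          class = "cae_degenerate_step")
  }
  if (sum(abs(u0 / nrm2(u0))) <= c) {
    return(list(u = u0 / nrm2(u0), params = list(lambda1 = lam1, lambda2 = 0)))
  }
  # bisection on lambda2; ||.||_1 of the normalized vector decreases from its
  # unconstrained value towards 1, so [0, max|g|] brackets the root
  lo <- 0
  hi <- max(abs(g))
  if (sum(abs(thr(hi))) != 0) {
    abort("binary search failed to bracket the L1 constraint",
          class = "cae_error")
  }
  for (it in seq_len(200)) {
    mid <- (lo + hi) / 2
    um <- thr(mid)
    if (all(um == 0)) {
      hi <- mid
    } else if (sum(abs(um / nrm2(um))) > c) {
      lo <- mid
    } else {
      hi <- mid
    }
    if ((hi - lo) <= 1e-15 * max(1, hi)) break
  }
  u <- thr(hi) # feasible side of the bracket
  if (all(u == 0)) u <- thr(lo)
  if (all(u == 0)) {
    abort("degenerate step: thresholded gradient is identically zero",
          class = "cae_degenerate_step")
  }
  u <- u / nrm2(u)
  if (abs(sum(abs(u)) - c) > 1e-6) {
    # Tied gradient maxima make ||.||_1 of the normalized thresholded vector
    # jump over c (it plateaus at sqrt(#ties)); the optimum then sits at a
    # corner of the constraint set: mass c with unit energy spread over the
    # tied coordinates. Deterministic split: one coordinate (lowest index
    # among the tied) gets the larger weight.
    u <- .tie_corner_solution(g, w, c)
    if (is.null(u)) {
      abort(sprintf("L1 bisection did not converge: ||u||_1 = %.8f, c = %.8f",
                    sum(abs(thr(lo) / nrm2(thr(lo)))), c), class = "cae_error")
    }
    return(list(u = u, params = list(lambda1 = lam1, lambda2 = hi)))
  }
  list(u = u, params = list(lambda1 = lam1, lambda2 = hi))
}

# Corner solution of max g'u s.t. ||u||_2 = 1, ||u||_1 = c on the tied
# maximal free coordinates. With k tied coordinates and 1 <= c <= sqrt(k),
# weights (a, b, ..., b) with a + (k-1) b = c and a^2 + (k-1) b^2 = 1 attain
# the optimum g_max * c. Returns NULL when the configuration is not a tie.
.tie_corner_solution <- function(g, w, c, tol = 1e-9) {
  free <- which(w == 0 & g != 0)
  if (!length(free)) return(NULL)
  gmax <- max(abs(g[free]))
  tied <- free[abs(g[free]) >= (1 - tol) * gmax]
  k <- length(tied)
  if (k < 2) return(NULL)
  u <- numeric(length(g))
  if (sqrt(k) <= c) { # equal mass already satisfies the budget
    u[tied] <- sign(g[tied]) / sqrt(k)
    return(u)
  }
  r <- k - 1
  disc <- c^2 * r^2 - r * (r + 1) * (c^2 - 1)
  if (disc < 0) return(NULL)
  b <- (c * r - sqrt(disc)) / (r * (r + 1))
  a <- c - r * b
  if (b < -1e-12 || a < b) return(NULL)
  tied <- tied[order(tied)]
  u[tied[1]] <- sign(g[tied[1]]) * a
  u[tied[-1]] <- sign(g[tied[-1]]) * max(b, 0)
  u / sqrt(sum(u^2))
}

#' Canonical pairs
#'
#' One discovered correlation structure: unit vectors `u`, `v` with disjoint
#' (forbidden-set-respecting) supports, the canonical correlation value
#' `d = u' G v` on correlation scale, and the fit R^2 between the projection
#' scores.
#'
#' @param u,v Numeric vectors of unit L2 norm.
#' @param d Canonical correlation value.
#' @param r_squared Squared Pearson correlation of the projection scores.
#' @param subject_id Identifier of the subject the pair belongs to.
#' @param pair_index Zero-based extraction order.
#' @return A `canonical_pair` object.
#' @export
canonical_pair <- function(u, v, d, r_squared = NA_real_,
                           subject_id = NA_character_, pair_index = 0L) {
  structure(list(u = as.numeric(u), v = as.numeric(v), d = d,
                 r_squared = r_squared, subject_id = subject_id,
                 pair_index = as.integer(pair_index)),
            class = "canonical_pair")
}

#' @export
print.canonical_pair <- function(x, ...) {
  cat(sprintf("<canonical_pair: |supp u| = %d, |supp v| = %d, d = %.3f, R^2 = %.3f>\n",
              sum(x$u != 0), sum(x$v != 0), x$d,
              if (is.na(x$r_squared)) NA else x$r_squared))
  invisible(x)
}

#' CAA sparsity and search configuration
#'
#' @param c1,c2 L1 budgets for the two canonical vectors, in `[1, sqrt(m)]`.
#'   Small budgets give small, readable supports; the default 1.5 targets
#'   structures of two to three features per axis.
#' @param max_pairs Maximum number of pairs to extract.
#' @param r2_min Retention threshold on the pair R^2 (strict inequality);
#'   extraction stops at the first sub-threshold pair, which is discarded.
#' @param tol Convergence tolerance on the max coordinate change of the
#'   sign-canonicalized pair between iterations.
#' @param max_iter Iteration cap for the alternating search.
#' @param n_restarts Number of initializations per pair (eigenvector-guided
#'   plus random single-coordinate starts).
#' @param seed Integer seed controlling the random restarts.
#' @return A `caa_config` object (a validated list).
#' @export
caa_config <- function(c1 = 1.5, c2 = 1.5, max_pairs = 5L, r2_min = 0.25,
                       tol = 1e-6, max_iter = 500L, n_restarts = 8L,
                       seed = 1L) {
  stopifnot(c1 >= 1, c2 >= 1, max_pairs >= 1, r2_min >= 0, r2_min < 1,
            tol > 0, max_iter >= 1, n_restarts >= 1)
  structure(list(c1 = c1, c2 = c2, max_pairs = as.integer(max_pairs),
                 r2_min = r2_min, tol = tol, max_iter = as.integer(max_iter),
                 n_restarts = as.integer(n_restarts), seed = as.integer(seed)),
            class = "caa_config")
}

# single alternating run from a given unit initialization
.acs_single <- function(G, config, forbidden, v_init) {
  v <- v_init
  u <- NULL
  trace <- numeric(0)
  iters <- 0L
  for (it in seq_len(config$max_iter)) {
    iters <- it
    su <- kkt_solve_step(G, v, config$c1, forbidden)
    u_new <- su$u
    trace <- c(trace, sum(u_new * (G %*% v)))
    sv <- kkt_solve_step(G, u_new, config$c2, forbidden)
    v_new <- sv$u
    trace <- c(trace, sum(u_new * (G %*% v_new)))
    cn <- .sign_canonicalize(u_new, v_new)
    if (!is.null(u)) {
      co <- .sign_canonicalize(u, v)
      if (max(abs(cn$u - co$u), abs(cn$v - co$v)) < config$tol) {
        u <- u_new
        v <- v_new
        break
      }
    }
    u <- u_new
    v <- v_new
  }
  cn <- .sign_canonicalize(u, v)
  d <- sum(cn$u * (G %*% cn$v))
  if (d < 0) { # cannot occur for an exact half-step (the feasible set is
    cn <- .sign_canonicalize(cn$u, -cn$v) # sign-symmetric); guard anyway
    d <- -d
  }
  list(u = cn$u, v = cn$v, d = d, trace = trace, iters = iters)
}

# initial coordinates: argmax |.| of the leading eigenvectors (deduplicated),
# topped up with seeded random coordinates
.acs_inits <- function(G, n_restarts, seed) {
  m <- ncol(G)
  n_eig <- min(3L, n_restarts, m)
  ev <- eigen(G, symmetric = TRUE)$vectors
  inits <- unique(vapply(seq_len(n_eig), function(j) which.max(abs(ev[, j])), integer(1)))
  if (length(inits) < n_restarts) {
    extra <- withr::with_seed(seed, sample.int(m, min(m, n_restarts * 2L), replace = FALSE))
    inits <- unique(c(inits, extra))
  }
  inits[seq_len(min(n_restarts, length(inits)))]
}

#' Alternate convex search for one canonical pair
#'
#' Alternates the KKT half-step for `u` and for `v` until the
#' sign-canonicalized pair moves less than `tol` in any coordinate, or
#' `max_iter` is reached. Each half-step solves its convex subproblem
#' exactly, so the objective `u' G v` is non-decreasing along the search.
#' When `v_init` is `NULL`, the best pair (largest `d`) over `n_restarts`
#' single-coordinate initializations is returned: the first starts at the
#' dominant coordinate of the leading eigenvector of `G`, the rest at random
#' coordinates drawn under `config$seed`. Dense initializations are useless
#' here — the disjointness threshold zeroes the entire support of a fully
#' dense vector — hence the sparse starts.
#'
#' @inheritParams kkt_solve_step
#' @param config A [caa_config()].
#' @param v_init Optional unit-norm starting vector; `NULL` for the restart
#'   schedule.
#' @return A [canonical_pair()] with attributes `trace` (objective values
#'   across half-steps), `iters` and `restart`. Signals
#'   `cae_degenerate_step` if every restart degenerates.
#' @export
alternate_convex_search <- function(G, config = caa_config(), forbidden = NULL,
                                    v_init = NULL) {
  m <- ncol(G)
  forbidden <- .check_forbidden(forbidden, m)
  runs <- list()
  if (!is.null(v_init)) {
    runs[[1]] <- .acs_single(G, config, forbidden, v_init)
    restarts <- 0L
  } else {
    inits <- .acs_inits(G, config$n_restarts, config$seed)
    for (r in seq_along(inits)) {
      v0 <- numeric(m)
      v0[inits[r]] <- 1
      res <- tryCatch(.acs_single(G, config, forbidden, v0),
                      cae_degenerate_step = function(e) NULL)
      if (!is.null(res)) {
        res$restart <- r - 1L
        runs[[length(runs) + 1]] <- res
      }
    }
    if (!length(runs)) {
      abort("no structure found: every restart degenerated",
            class = "cae_degenerate_step")
    }
  }
  best <- runs[[which.max(vapply(runs, function(r) r$d, numeric(1)))]]
  out <- canonical_pair(best$u, best$v, best$d)
  attr(out, "trace") <- best$trace
  attr(out, "iters") <- best$iters
  attr(out, "restart") <- best$restart %||% 0L
  out
}

#' Pair R^2
#'
#' Squared Pearson correlation between the two projection scores `X u` and
#' `X v`. Pairs are retained only when this exceeds the `r2_min` filter.
#'
#' @param X A standardized [feature_matrix][as_feature_matrix] (or anything
#'   coercible; standardized on the way in).
#' @param pair A [canonical_pair()].
#' @return A number in `[0, 1]`; zero (with a warning) when either projection
#'   has zero variance.
#' @export
compute_r_squared <- function(X, pair) {
  fm <- .as_standardized(X)
  s1 <- as.vector(unclass(fm) %*% pair$u)
  s2 <- as.vector(unclass(fm) %*% pair$v)
  if (sd(s1) == 0 || sd(s2) == 0) {
    warn("zero-variance projection; R^2 set to 0")
    return(0)
  }
  cor(s1, s2)^2
}

#' Gram-matrix deflation
#'
#' Removes an already-found correlation structure from the gram matrix:
#' `G' = G - d (u v' + v u')`. With unit-norm, disjoint-support `u` and `v`
#' this makes `u' G' v = 0`, so the next alternating search cannot rediscover
#' the same pair.
#'
#' @param G Symmetric gram (correlation) matrix.
#' @param pair A [canonical_pair()].
#' @return The deflated symmetric matrix.
#' @export
deflate_gram <- function(G, pair) {
  G - pair$d * (outer(pair$u, pair$v) + outer(pair$v, pair$u))
}
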