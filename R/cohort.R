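#' Planted correlation structure
#'
#' Specifies one latent structure of the synthetic cohort generator: two
#' disjoint feature blocks whose weighted sums share a common latent factor.
#' The per-feature model is `x_j = w_j z + sigma e_j` on both blocks; the
#' noise variance `sigma^2` is solved in closed form so the *population* R^2
#' between the weighted block sums equals `target_r2`:
#' with `alpha = sum(weights_a^2)`, `beta = sum(weights_b^2)`,
#' `sigma^2` is the positive root of
#' `(alpha + s)(beta + s) = alpha beta / target_r2`.
#'
#' @param support_a,support_b Disjoint feature index sets (1-based).
#' @param target_r2 Population R^2 of the planted relation, in (0, 1).
#' @param weights_a,weights_b Loadings on the supports (default all 1).
#' @return A `structure_spec` object.
#' @export
structure_spec <- function(support_a, support_b, target_r2,
                           weights_a = NULL, weights_b = NULL) {
  support_a <- as.integer(support_a)
  support_b <- as.integer(support_b)
  if (length(intersect(support_a, support_b))) {
    abort("structure supports must be disjoint", class = "cae_data_error")
  }
  stopifnot(target_r2 > 0, target_r2 < 1,
            length(support_a) >= 1, length(support_b) >= 1)
  weights_a <- weights_a %||% rep(1, length(support_a))
  weights_b <- weights_b %||% rep(1, length(support_b))
  stopifnot(length(weights_a) == length(support_a),
            length(weights_b) == length(support_b))
  structure(list(support_a = support_a, support_b = support_b,
                 target_r2 = target_r2, weights_a = weights_a,
                 weights_b = weights_b),
            class = "structure_spec")
}

# closed-form structural noise variance for a structure_spec
.structure_sigma2 <- function(st) {
  a <- sum(st$weights_a^2)
  b <- sum(st$weights_b^2)
  (-(a + b) + sqrt((a + b)^2 - 4 * a * b * (1 - 1 / st$target_r2))) / 2
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the qEEG setting the methodology was designed for: 80
#' subjects in two balanced outcome classes, 66 features sampled at 1 Hz
#' over a two-hour epoch (7200 timestamps). One structure is shared by both
#' classes and one is specific to class 1, both with a planted R^2 of 0.8.
#'
#' @param n_subjects_per_class Subjects per class.
#' @param n_features,n_timesteps Matrix dimensions per subject.
#' @param shared_structures,class0_structures,class1_structures Lists of
#'   [structure_spec()]; every subject receives the shared structures plus
#'   its class's own.
#' @param noise_sd Standard deviation of unstructured features.
#' @param class1_shift Optional mean shift for class 1: a list
#'   `list(features = <indices>, delta = <scalar>)`.
#' @param equalize_variance If `TRUE`, every feature's marginal variance is
#'   topped up with independent noise to the maximum over classes, so the
#'   classes differ only in correlation structure (used to isolate
#'   correlation signal from marginal signal).
#' @param ar1 AR(1) coefficient of the latent series (0 = i.i.d. rows, the
#'   default; the method treats rows as exchangeable).
#' @param seed Master seed; the manifest regenerates the cohort exactly.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_subjects_per_class = 40L, n_features = 66L,
                          n_timesteps = 7200L,
                          shared_structures = list(structure_spec(1:3, 4:6, 0.8)),
                          class0_structures = list(),
                          class1_structures = list(structure_spec(7:9, 10:12, 0.8)),
                          noise_sd = 1, class1_shift = NULL,
                          equalize_variance = FALSE, ar1 = 0, seed = 1L) {
  stopifnot(n_subjects_per_class >= 1, n_features >= 2, n_timesteps >= 2,
            noise_sd > 0, ar1 >= 0, ar1 < 1)
  all_structs <- c(shared_structures, class0_structures, class1_structures)
  for (st in all_structs) {
    if (max(st$support_a, st$support_b) > n_features) {
      abort("structure support outside [1, n_features]", class = "cae_data_error")
    }
  }
  structure(list(n_subjects_per_class = as.integer(n_subjects_per_class),
                 n_features = as.integer(n_features),
                 n_timesteps = as.integer(n_timesteps),
                 shared_structures = shared_structures,
                 class0_structures = class0_structures,
                 class1_structures = class1_structures,
                 noise_sd = noise_sd, class1_shift = class1_shift,
                 equalize_variance = equalize_variance, ar1 = ar1,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

.active_structures <- function(cfg, class_label) {
  c(cfg$shared_structures,
    if (class_label == 0) cfg$class0_structures else cfg$class1_structures)
}

# per-feature structural variance for a class (before equalization/shift)
.class_variances <- function(cfg, class_label) {
  v <- rep(cfg$noise_sd^2, cfg$n_features)
  for (st in .active_structures(cfg, class_label)) {
    s2 <- .structure_sigma2(st)
    v[st$support_a] <- st$weights_a^2 + s2
    v[st$support_b] <- st$weights_b^2 + s2
  }
  v
}

#' Generate one synthetic subject
#'
#' @param cfg A [cohort_config()].
#' @param class_label 0 or 1.
#' @param seed Integer seed for this subject.
#' @return A list: `x` (raw, unstandardized numeric matrix with feature
#'   names `f000...`), and `realized_r2` (empirical R^2 of each active
#'   planted structure's weighted block sums).
#' @export
generate_subject <- function(cfg, class_label, seed) {
  structs <- .active_structures(cfg, class_label)
  supports <- unlist(lapply(structs, function(s) c(s$support_a, s$support_b)))
  if (anyDuplicated(supports)) {
    abort("simultaneously active structures overlap in support",
          class = "cae_data_error")
  }
  n <- cfg$n_timesteps
  m <- cfg$n_features
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * m, sd = cfg$noise_sd), n, m)
    realized <- numeric(length(structs))
    for (si in seq_along(structs)) {
      st <- structs[[si]]
      s2 <- .structure_sigma2(st)
      z <- if (cfg$ar1 > 0) {
        as.vector(stats::arima.sim(list(ar = cfg$ar1), n,
                                   sd = sqrt(1 - cfg$ar1^2)))
      } else {
        rnorm(n)
      }
      for (j in seq_along(st$support_a)) {
        x[, st$support_a[j]] <- st$weights_a[j] * z + sqrt(s2) * rnorm(n)
      }
      for (j in seq_along(st$support_b)) {
        x[, st$support_b[j]] <- st$weights_b[j] * z + sqrt(s2) * rnorm(n)
      }
      sa <- x[, st$support_a, drop = FALSE] %*% st$weights_a
      sb <- x[, st$support_b, drop = FALSE] %*% st$weights_b
      realized[si] <- cor(sa, sb)[1]^2
    }
    if (cfg$equalize_variance) {
      v_here <- .class_variances(cfg, class_label)
      v_target <- pmax(.class_variances(cfg, 0), .class_variances(cfg, 1))
      topup <- v_target - v_here
      for (j in which(topup > 1e-12)) {
        x[, j] <- x[, j] + rnorm(n, sd = sqrt(topup[j]))
      }
    }
    if (class_label == 1 && !is.null(cfg$class1_shift)) {
      x[, cfg$class1_shift$features] <-
        x[, cfg$class1_shift$features] + cfg$class1_shift$delta
    }
  })
  colnames(x) <- sprintf("f%03d", seq_len(m) - 1L)
  list(x = x, realized_r2 = realized)
}

#' Generate a full synthetic cohort
#'
#' Balanced classes; each subject receives the shared structures plus its
#' class's structures. Per-subject seeds are drawn once from the master
#' seed, so the manifest regenerates the cohort exactly.
#'
#' @param cfg A [cohort_config()].
#' @return A `cae_cohort`: `data` (named list of raw matrices), `labels`
#'   (tibble `subject_id`, `label`) and `manifest` (per-subject tibble with
#'   seeds and realized structure R^2 as a list-column, plus the config as
#'   an attribute).
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  n_tot <- 2L * cfg$n_subjects_per_class
  ids <- sprintf("s%03d", seq_len(n_tot))
  labels <- rep(c(0, 1), each = cfg$n_subjects_per_class)
  seeds <- withr::with_seed(cfg$seed,
                            sample.int(.Machine$integer.max - 1L, n_tot))
  data <- vector("list", n_tot)
  names(data) <- ids
  realized <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    sub <- generate_subject(cfg, labels[i], seeds[i])
    data[[i]] <- sub$x
    realized[[i]] <- sub$realized_r2
  }
  manifest <- tibble::tibble(subject_id = ids, label = labels, seed = seeds,
                             n_structures = lengths(realized),
                             realized_r2 = realized)
  attr(manifest, "config") <- cfg
  structure(list(data = data,
                 labels = tibble::tibble(subject_id = ids, label = labels),
                 manifest = manifest),
            class = "cae_cohort")
}

#' @export
print.cae_cohort <- function(x, ...) {
  d <- dim(x$data[[1]])
  cat(sprintf("<cae_cohort: %d subjects (%d x %d each), %d positive>\n",
              length(x$data), d[1], d[2], sum(x$labels$label)))
  invisible(x)
}

# strip classes so configs serialize as plain JSON
.cohort_cfg_as_list <- function(cfg) {
  out <- unclass(cfg)
  for (blk in c("shared_structures", "class0_structures", "class1_structures")) {
    out[[blk]] <- lapply(out[[blk]], unclass)
  }
  out
}

#' Write a cohort to plain-text fixtures
#'
#' One CSV per subject, a labels CSV and a manifest JSON, matching what the
#' command-line workflow reads back.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_fixtures <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (id in names(cohort$data)) {
    f <- file.path(dir, paste0(id, ".csv"))
    write.csv(as.data.frame(cohort$data[[id]]), f, row.names = FALSE)
    files <- c(files, f)
  }
  lf <- file.path(dir, "labels.csv")
  write.csv(cohort$labels, lf, row.names = FALSE)
  mf <- file.path(dir, "manifest.json")
  man <- cohort$manifest
  jsonlite::write_json(
    list(config = .cohort_cfg_as_list(attr(man, "config")),
         subjects = dplyr::mutate(man, realized_r2 = purrr::map(man$realized_r2, identity))),
    mf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, lf, mf))
}

#' Read a fixture directory back into a cohort
#'
#' @param dir Directory produced by [write_fixtures()] (or any directory of
#'   per-subject CSVs plus a `labels.csv`).
#' @return A `cae_cohort` (manifest present only if `manifest.json` exists).
#' @export
read_cohort <- function(dir) {
  lf <- file.path(dir, "labels.csv")
  if (!file.exists(lf)) abort(paste0("no labels.csv in ", dir), class = "cae_data_error")
  labels <- tibble::as_tibble(read.csv(lf, colClasses = c(subject_id = "character")))
  data <- list()
  for (id in labels$subject_id) {
    f <- file.path(dir, paste0(id, ".csv"))
    if (!file.exists(f)) abort(paste0("missing data file for subject ", id),
                               class = "cae_data_error")
    data[[id]] <- as.matrix(read.csv(f))
  }
  mf <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(mf)) jsonlite::read_json(mf) else NULL
  structure(list(data = data, labels = labels, manifest = manifest),
            class = "cae_cohort")
}
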