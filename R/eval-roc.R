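## Empirical ROC machinery with subject-level stratified bootstrap.
## A subject is called positive at threshold th iff score > th (strict), so
## the reported operating points are conservative: the empirical FPR at the
## realizing threshold never exceeds the target.

# full step curve: thresholds Inf, then the unique scores in decreasing order
.roc_points <- function(scores, labels) {
  pos <- labels == 1
  neg <- !pos
  ths <- c(Inf, sort(unique(scores[is.finite(scores)]), decreasing = TRUE))
  fpr <- vapply(ths, function(th) mean(scores[neg] > th), numeric(1))
  tpr <- vapply(ths, function(th) mean(scores[pos] > th), numeric(1))
  tibble::tibble(threshold = ths, fpr = fpr, tpr = tpr,
                 tnr = 1 - fpr, fnr = 1 - tpr)
}

# trapezoidal AUC of the step curve == Mann-Whitney statistic with tie split
.auc_scores <- function(scores, labels) {
  pts <- .roc_points(scores, labels)
  # append the (1,1) endpoint (threshold below every score, incl. -Inf)
  fpr <- c(pts$fpr, 1)
  tpr <- c(pts$tpr, 1)
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

.tpr_at_fpr_scores <- function(scores, labels, fpr_target) {
  pts <- .roc_points(scores, labels)
  ok <- pts$fpr <= fpr_target
  if (!any(ok)) return(0)
  max(pts$tpr[ok])
}

#' Empirical ROC with stratified bootstrap confidence intervals
#'
#' Computes the full empirical ROC over all score thresholds (positive iff
#' `score > threshold`) together with 95% percentile confidence bands from a
#' subject-level bootstrap stratified by class. Scores of `-Inf` encode
#' deferred subjects: they sit below every threshold and can never be called
#' positive.
#'
#' @param scores Numeric subject scores (may contain `-Inf`).
#' @param labels Binary labels, same order as `scores`.
#' @param n_boot Number of bootstrap replicates (0 to skip).
#' @param seed Integer seed for the bootstrap.
#' @return A `roc_result`: `curve` (tibble with `threshold`, `fpr`, `tpr`,
#'   `tnr`, `fnr`, `tpr_lo`, `tpr_hi`), `auc`, `auc_ci`, `n_boot`,
#'   `n_pos`, `n_neg`, plus the bootstrap curves for downstream
#'   [tpr_at_fpr()] intervals. `tidy()` returns the curve, `glance()` the
#'   AUC row, `autoplot()` draws the low-FPR-emphasizing log-x curve.
#' @export
roc_with_ci <- function(scores, labels, n_boot = 1000L, seed = 1L) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2) {
    abort("both classes must be present", class = "cae_data_error")
  }
  if (length(unique(scores[is.finite(scores)])) <= 1) {
    warn("degenerate scores: ROC is a flat curve")
  }
  curve <- .roc_points(scores, labels)
  auc <- .auc_scores(scores, labels)
  boot <- NULL
  auc_ci <- c(NA_real_, NA_real_)
  tpr_lo <- tpr_hi <- rep(NA_real_, nrow(curve))
  if (n_boot > 0) {
    ipos <- which(labels == 1)
    ineg <- which(labels == 0)
    boot <- withr::with_seed(seed, lapply(seq_len(n_boot), function(b) {
      idx <- c(sample(ipos, replace = TRUE), sample(ineg, replace = TRUE))
      list(scores = scores[idx], labels = labels[idx])
    }))
    aucs <- vapply(boot, function(b) .auc_scores(b$scores, b$labels), numeric(1))
    auc_ci <- unname(quantile(aucs, c(0.025, 0.975)))
    # pointwise band: bootstrap TPR at each base-curve FPR (conservative rule)
    tpr_mat <- vapply(boot, function(b) {
      vapply(curve$fpr, function(f) .tpr_at_fpr_scores(b$scores, b$labels, f),
             numeric(1))
    }, numeric(nrow(curve)))
    tpr_mat <- matrix(tpr_mat, nrow = nrow(curve))
    tpr_lo <- apply(tpr_mat, 1, quantile, 0.025)
    tpr_hi <- apply(tpr_mat, 1, quantile, 0.975)
  }
  curve$tpr_lo <- tpr_lo
  curve$tpr_hi <- tpr_hi
  structure(list(curve = curve, auc = auc, auc_ci = auc_ci,
                 n_boot = as.integer(n_boot), n_pos = sum(labels == 1),
                 n_neg = sum(labels == 0), boot = boot),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result: AUC = %.3f [%.3f, %.3f], %d+/%d-, %d bootstrap reps>\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$n_pos, x$n_neg, x$n_boot))
  invisible(x)
}

#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, auc_lo = x$auc_ci[1], auc_hi = x$auc_ci[2],
                 n_pos = x$n_pos, n_neg = x$n_neg, n_boot = x$n_boot)
}

#' TPR at a bounded FPR
#'
#' The largest achievable true-positive rate whose empirical false-positive
#' rate does not exceed `fpr_target`, the (largest, hence most conservative)
#' threshold realizing it, and a bootstrap confidence interval when the
#' `roc_result` carries bootstrap replicates. The bound convention reflects
#' deployment: the false-positive tolerance is a ceiling, never a target to
#' average around.
#'
#' @param roc A [roc_with_ci()] result.
#' @param fpr_target FPR bound in (0, 1).
#' @return A one-row tibble: `fpr_target`, `tpr`, `threshold`, `ci_lo`,
#'   `ci_hi`.
#' @export
tpr_at_fpr <- function(roc, fpr_target = 0.025) {
  stopifnot(fpr_target > 0, fpr_target < 1)
  ok <- roc$curve$fpr <= fpr_target
  if (!any(ok)) {
    res <- tibble::tibble(fpr_target = fpr_target, tpr = 0,
                          threshold = max(roc$curve$threshold))
  } else {
    best <- max(roc$curve$tpr[ok])
    th <- max(roc$curve$threshold[ok & roc$curve$tpr == best])
    res <- tibble::tibble(fpr_target = fpr_target, tpr = best, threshold = th)
  }
  if (!is.null(roc$boot)) {
    bs <- vapply(roc$boot, function(b)
      .tpr_at_fpr_scores(b$scores, b$labels, fpr_target), numeric(1))
    res$ci_lo <- unname(quantile(bs, 0.025))
    res$ci_hi <- unname(quantile(bs, 0.975))
  } else {
    res$ci_lo <- NA_real_
    res$ci_hi <- NA_real_
  }
  res
}

#' Plot a ROC curve with the low-FPR region emphasized
#'
#' @param object A `roc_result`.
#' @param fnr_view Plot TNR vs FNR instead of TPR vs FPR.
#' @param ... Unused.
#' @return A ggplot with a log-scale x axis (zero rates floored at half the
#'   smallest resolvable rate).
#' @export
autoplot.roc_result <- function(object, fnr_view = FALSE, ...) {
  df <- object$curve
  if (fnr_view) {
    df <- dplyr::transmute(df, x = .data$fnr, y = .data$tnr)
    labs <- c("FNR", "TNR")
    floor_x <- 0.5 / object$n_pos
  } else {
    df <- dplyr::transmute(df, x = .data$fpr, y = .data$tpr,
                           lo = object$curve$tpr_lo, hi = object$curve$tpr_hi)
    labs <- c("FPR", "TPR")
    floor_x <- 0.5 / object$n_neg
  }
  df$x <- pmax(df$x, floor_x)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = paste0(labs[1], " (log scale)"), y = labs[2]) +
    ggplot2::theme_minimal()
  if (!fnr_view && !all(is.na(object$curve$tpr_lo))) {
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                                  alpha = 0.2)
  }
  p
}
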