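#' ROC analysis of bipolar voltage against unipolar non-viability
#'
#' Labels every mapping point as non-viable when its unipolar voltage is
#' below `upv_cutoff` (default 5 mV) and evaluates the bipolar voltage as a
#' diagnostic score for that label, a lower bipolar voltage meaning more
#' likely non-viable. A point is called positive at candidate cut-off `c`
#' when `bipv < c`. The area under the ROC curve is computed by the
#' trapezoidal rule; its confidence interval by a seeded nonparametric
#' bootstrap over points (percentile method, 2000 resamples by default).
#'
#' @param points A `mapping_points` data frame.
#' @param upv_cutoff Unipolar viability/non-viability cut-off in mV
#'   (default 5).
#' @param n_boot Bootstrap resamples for the AUC confidence interval
#'   (default 2000; 0 skips the interval).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `roc_result`: list with `curve` (data frame of
#'   `cutoff_mV`, `sensitivity`, `specificity`), `auc`, `auc_ci`, `n_pos`,
#'   `n_neg`.
#' @export
roc_bipv_cutoff <- function(points, upv_cutoff = 5, n_boot = 2000L,
                            conf = 0.95, seed = 1L) {
  pts <- points[points$stable, , drop = FALSE]
  labels <- pts$upv_mV < upv_cutoff
  scores <- pts$bipv_mV
  if (!any(labels) || all(labels)) {
    stop("both viable and non-viable points are required: ROC undefined",
         call. = FALSE)
  }
  curve <- roc_points(labels, scores)
  auc <- auc_trapezoid(curve)
  ci <- NULL
  if (n_boot > 0) {
    n <- length(labels)
    boots <- withr::with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        lb <- labels[idx]
        if (!any(lb) || all(lb)) return(NA_real_)
        auc_rank(lb, scores[idx])
      }, numeric(1))
    })
    ci <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          na.rm = TRUE, names = FALSE)
  }
  structure(list(curve = curve, auc = auc, auc_ci = ci,
                 n_pos = sum(labels), n_neg = sum(!labels),
                 labels = labels, scores = scores),
            class = "roc_result")
}

#' Sensitivity and specificity at an arbitrary bipolar cut-off
#'
#' @param x A `roc_result` from [roc_bipv_cutoff()].
#' @param cutoff Bipolar cut-off in mV; points with `bipv < cutoff` are
#'   called non-viable.
#' @return Named numeric vector `c(sensitivity, specificity)`.
#' @export
sens_spec_at <- function(x, cutoff) {
  stopifnot(inherits(x, "roc_result"))
  c(sensitivity = mean(x$scores[x$labels] < cutoff),
    specificity = mean(x$scores[!x$labels] >= cutoff))
}

# sensitivity/specificity at every distinguishing cut-off (positive: score < c)
roc_points <- function(labels, scores) {
  cuts <- c(sort(unique(scores)), max(scores) + 1)
  sens <- vapply(cuts, function(cc) mean(scores[labels] < cc), numeric(1))
  spec <- vapply(cuts, function(cc) mean(scores[!labels] >= cc), numeric(1))
  data.frame(cutoff_mV = cuts, sensitivity = sens, specificity = spec)
}

# rank (Mann-Whitney) AUC, identical to the trapezoidal value but O(n log n);
# a lower score marks the positive class, ties counted half
auc_rank <- function(labels, scores) {
  r <- rank(scores)
  n_neg <- sum(!labels)
  w <- sum(r[!labels]) - n_neg * (n_neg + 1) / 2
  w / (n_neg * (length(labels) - n_neg))
}

# trapezoidal area under the (FPR, TPR) curve incl. the (0,0) anchor
auc_trapezoid <- function(curve) {
  fpr <- c(0, 1 - curve$specificity)
  tpr <- c(0, curve$sensitivity)
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %d non-viable vs %d viable points\n",
              x$n_pos, x$n_neg))
  if (is.null(x$auc_ci)) {
    cat(sprintf("  AUC %.3f\n", x$auc))
  } else {
    cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f)\n",
                x$auc, x$auc_ci[1], x$auc_ci[2]))
  }
  invisible(x)
}
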