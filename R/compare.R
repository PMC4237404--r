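#' Overlap ratio between MRI and NOGA infarct regions
#'
#' Computes the (c+d)/(a+b) overlap statistic between matching regions of a
#' classified MRI transmurality map and a classified NOGA bipolar map that
#' share one grid: `a` is the MRI region area, `b` the NOGA region area,
#' `c` the NOGA shape overlaid on the MRI map and `d` the MRI shape overlaid
#' on the NOGA map (on a shared grid both equal the intersection area, so
#' the ratio equals the Dice coefficient `2|A n B| / (|A| + |B|)`). Areas
#' are percentages of the shared valid surface.
#'
#' Region pairs: `transmural` compares the bipolar `< 0.8` mV class against
#' MRI transmurality `> 75%`; `non_transmural` compares bipolar `0.8-1.9` mV
#' against MRI `25-75%`; `combined` compares bipolar `< 1.9` mV against MRI
#' `> 25%`.
#'
#' @param mri_class A class-label [polar_map()] from
#'   [classify_transmurality()] (scheme `"25-50-75"`).
#' @param noga_class A class-label [polar_map()] from [classify_voltage()]
#'   on a bipolar map.
#' @param region `"transmural"`, `"non_transmural"` or `"combined"`.
#' @return An object of class `overlap_result`: list with `a`, `b`, `c`,
#'   `d`, `ratio` (in `[0, 1]`, `NA` when both regions are empty) and
#'   `grade` (`good` > 0.60, `moderate` 0.50-0.60, else `poor`;
#'   `undefined` for the empty case).
#' @export
overlap_ratio <- function(mri_class, noga_class,
                          region = c("transmural", "non_transmural",
                                     "combined")) {
  region <- match.arg(region)
  stopifnot(inherits(mri_class, "polar_map"), inherits(noga_class, "polar_map"))
  if (!identical(dim(mri_class$values), dim(noga_class$values))) {
    stop("maps must share grid and orientation", call. = FALSE)
  }
  mri_labels <- switch(region,
                       transmural = "transmural",
                       non_transmural = c("non_transmural", "border"),
                       combined = c("non_transmural", "border", "transmural"))
  noga_labels <- switch(region,
                        transmural = "transmural",
                        non_transmural = "non_transmural",
                        combined = c("transmural", "non_transmural"))
  mri_labels <- intersect(mri_labels, attr(mri_class, "levels"))
  valid <- mri_class$valid & noga_class$valid
  overlap_masks(class_mask(mri_class, mri_labels) & valid,
                class_mask(noga_class, noga_labels) & valid,
                valid, region = region)
}

#' Overlap ratio of two logical masks on a shared grid
#'
#' The mask-level primitive behind [overlap_ratio()]; exposed for direct use
#' on arbitrary region masks.
#'
#' @param mask_a,mask_b Logical matrices (region A = MRI, region B = NOGA).
#' @param valid Logical matrix of analysable cells (default: all).
#' @param region Optional label stored in the result.
#' @return An `overlap_result` (see [overlap_ratio()]).
#' @export
overlap_masks <- function(mask_a, mask_b, valid = NULL, region = NULL) {
  stopifnot(identical(dim(mask_a), dim(mask_b)))
  if (is.null(valid)) valid <- matrix(TRUE, nrow(mask_a), ncol(mask_a))
  n_valid <- sum(valid)
  if (n_valid == 0) stop("no valid cells", call. = FALSE)
  A <- mask_a & valid
  B <- mask_b & valid
  a <- 100 * sum(A) / n_valid
  b <- 100 * sum(B) / n_valid
  inter <- 100 * sum(A & B) / n_valid
  if (a + b == 0) {
    ratio <- NA_real_
    grade <- "undefined"
    warning("both regions are empty: overlap ratio undefined", call. = FALSE)
  } else {
    ratio <- (inter + inter) / (a + b)
    grade <- if (ratio > 0.60) "good" else if (ratio >= 0.50) "moderate" else "poor"
  }
  structure(list(a = a, b = b, c = inter, d = inter, ratio = ratio,
                 grade = grade, region = region),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result%s> a=%.1f%% b=%.1f%% c=d=%.1f%% ratio=%s (%s)\n",
              if (is.null(x$region)) "" else paste0(": ", x$region),
              x$a, x$b, x$c,
              ifelse(is.na(x$ratio), "NA", sprintf("%.3f", x$ratio)),
              x$grade))
  invisible(x)
}

#' Pearson correlation with qualitative grade
#'
#' Standard Pearson product-moment correlation with a two-sided p-value
#' (t-distribution transform) and the conventional qualitative grading of
#' the coefficient magnitude: large above 0.5, moderate 0.3-0.5, small
#' 0.1-0.3, negligible below 0.1.
#'
#' @param x,y Paired numeric vectors (e.g. per-subject area measurements),
#'   `n >= 3`, each with non-zero variance.
#' @return List with `r`, `p`, `n`, `grade`.
#' @export
pearson_with_grade <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must be paired", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  list(r = r, p = ct$p.value, n = length(x), grade = grade_correlation(r))
}

#' Least-absolute-residual (L1) robust line fit
#'
#' Fits `y = intercept + slope * x` minimising the sum of absolute residuals
#' by iteratively reweighted least squares: starting from the ordinary
#' least-squares line, each iteration solves a weighted least-squares
#' problem with weights `1 / max(|residual|, 1e-8)`, stopping when the
#' coefficients change by less than `tol` (default 1e-10) or after
#' `max_iter` iterations (default 200). With two points the result is the
#' exact interpolating line; a minority of gross outliers does not move the
#' fit off an otherwise exact line (L1 breakdown behaviour).
#'
#' @param x,y Numeric vectors, `n >= 2`.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance.
#' @return List with `slope`, `intercept`, `converged`, `iterations`,
#'   `sum_abs_residuals`. Non-convergence is signalled with a warning and
#'   `converged = FALSE`.
#' @export
robust_linear_fit <- function(x, y, max_iter = 200L, tol = 1e-10) {
  if (length(x) != length(y)) stop("`x` and `y` must be paired", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 points", call. = FALSE)
  if (stats::var(x) == 0) stop("`x` is constant: slope undefined", call. = FALSE)
  X <- cbind(1, x)
  beta <- stats::lm.fit(X, y)$coefficients
  converged <- FALSE
  it <- 0L
  step <- Inf
  while (it < max_iter) {
    it <- it + 1L
    res <- y - X %*% beta
    w <- 1 / pmax(abs(res), 1e-8)
    beta_new <- stats::lm.wfit(X, y, as.vector(w))$coefficients
    step <- max(abs(beta_new - beta))
    beta <- beta_new
    if (step < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("IRLS did not converge within %d iterations (last step %.3g)",
                    max_iter, step), call. = FALSE)
  }
  list(slope = unname(beta[2]), intercept = unname(beta[1]),
       converged = converged, iterations = it,
       sum_abs_residuals = sum(abs(y - X %*% beta)))
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken as `x - y`; by package convention `x` is the
#' NOGA-derived and `y` the MRI-derived measurement, so a positive mean
#' difference means the voltage map overestimates relative to MRI. Limits
#' of agreement are exactly `mean +/- 2 * SD` of the differences (sample
#' SD). Both the SD of the differences and the limit half-width (`2 * SD`)
#' are reported explicitly.
#'
#' @param x,y Paired numeric vectors of equal length, `n >= 2`.
#' @return An object of class `bland_altman`: list with `mean_diff`,
#'   `sd_diff`, `limits` (length-2 vector), `half_width`, `n`, and the
#'   per-pair `means` and `differences` for plotting.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must be paired", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  m <- mean(d)
  s <- stats::sd(d)
  structure(list(mean_diff = m, sd_diff = s,
                 limits = c(lower = m - 2 * s, upper = m + 2 * s),
                 half_width = 2 * s, n = length(d),
                 means = (x + y) / 2, differences = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n=%d  mean diff %.3f  SD %.3f  limits [%.3f, %.3f]\n",
              x$n, x$mean_diff, x$sd_diff, x$limits[1], x$limits[2]))
  invisible(x)
}

#' Bland-Altman plot
#'
#' @param x A [bland_altman()] result.
#' @param xlab,ylab,main Plot annotation.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.bland_altman <- function(x, xlab = "Mean of methods",
                              ylab = "Difference (NOGA - cMRI)",
                              main = "Bland-Altman", ...) {
  graphics::plot(x$means, x$differences, xlab = xlab, ylab = ylab,
                 main = main, pch = 19, ...)
  graphics::abline(h = x$mean_diff, lwd = 2)
  graphics::abline(h = x$limits, col = "blue", lty = 2)
  invisible(x)
}
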