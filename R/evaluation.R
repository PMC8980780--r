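#' Pixel-level segmentation accuracy metrics
#'
#' AUC (Mann-Whitney rank statistic with ties averaged), accuracy,
#' sensitivity, specificity and F1 from the thresholded confusion matrix,
#' all evaluated inside the field of view only (the dark background outside
#' the fundus circle would otherwise inflate specificity).
#'
#' @param scores Real-valued prediction grid (probabilities or a binary
#'   mask; binary scores make the AUC degenerate to `(sens + spec) / 2`,
#'   which is warned about).
#' @param truth Binary reference grid of the same shape.
#' @param fov Optional binary field-of-view mask; default: everywhere.
#' @param threshold Score threshold for the confusion matrix, default 0.5.
#' @return One-row tibble: `auc`, `accuracy`, `sensitivity`, `specificity`,
#'   `f1`, and the confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
#' @examples
#' t <- matrix(c(1, 1, 0, 0), 2); s <- matrix(c(.9, .4, .6, .2), 2)
#' pixel_metrics(s, t)$auc  # 0.75
pixel_metrics <- function(scores, truth, fov = NULL, threshold = 0.5) {
  if (!identical(dim(scores), dim(truth))) {
    rlang::abort("scores and truth differ in shape",
                 class = "vesselmetrics_shape_error")
  }
  truth <- as_binary_matrix(truth, "truth")
  sel <- if (is.null(fov)) rep(TRUE, length(truth)) else fov == 1L
  y <- as.numeric(truth)[sel]
  p <- as.numeric(scores)[sel]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  auc <- if (n1 == 0 || n0 == 0) {
    rlang::warn("truth is all one class inside the FOV: AUC undefined",
                class = "vesselmetrics_undefined_measure")
    NA_real_
  } else {
    if (all(p %in% c(0, 1))) {
      rlang::warn("binary scores: AUC degenerates to (sensitivity + specificity)/2",
                  class = "vesselmetrics_degenerate_auc")
    }
    r <- rank(p)
    n1 <- as.numeric(n1); n0 <- as.numeric(n0)
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  pred <- p >= threshold
  tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
  fn <- sum(!pred & y == 1); tn <- sum(!pred & y == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else NA_real_
  tibble::tibble(auc = auc, accuracy = (tp + tn) / length(y),
                 sensitivity = sens, specificity = spec, f1 = f1,
                 tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Reliability band for an intraclass correlation
#'
#' Cutpoints: below 0.5 poor, 0.5-0.75 moderate, 0.75-0.9 good, 0.9 and
#' above excellent.
#'
#' @param icc ICC value(s).
#' @return Character vector of bands.
#' @export
icc_band <- function(icc) {
  cut(icc, breaks = c(-Inf, 0.5, 0.75, 0.9, Inf), right = FALSE,
      labels = c("poor", "moderate", "good", "excellent")) |> as.character()
}

#' Test-retest agreement: intraclass correlation
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC
#' (ICC(A,1) in the McGraw-Wong taxonomy — the standard test-retest choice)
#' with its 95% confidence interval, plus the reliability band.
#'
#' @param pairs An `n x k` matrix or data frame: one row per subject, one
#'   column per measurement occasion/rater (commonly k = 2).
#' @param conf_level Confidence level, default 0.95.
#' @return Object of class `icc_agreement` with `icc`, `ci_low`, `ci_high`,
#'   `band` and the ANOVA mean squares; see [tidy.icc_agreement()].
#' @export
#' @examples
#' x <- cbind(a = c(10, 12, 14, 16, 20), b = c(11, 12, 13, 17, 19))
#' icc_agreement(x)$band
icc_agreement <- function(pairs, conf_level = 0.95) {
  x <- as.matrix(pairs)
  storage.mode(x) <- "double"
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x); k <- ncol(x)
  if (n < 3L || k < 2L) {
    rlang::abort("need at least 3 subjects and 2 measurements each",
                 class = "vesselmetrics_contract_error")
  }
  grand <- mean(x)
  rowm <- rowMeans(x); colm <- colMeans(x)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom <= 0 || (msr <= mse && msc <= mse && abs(denom) < 1e-12)) {
    rlang::warn("no between-subject variance: ICC undefined",
                class = "vesselmetrics_undefined_measure")
    icc <- NA_real_
  } else icc <- (msr - mse) / denom
  # McGraw & Wong confidence bounds for ICC(A,1)
  alpha <- 1 - conf_level
  ci <- c(NA_real_, NA_real_)
  if (!is.na(icc) && mse > 0) {
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f1 <- stats::qf(1 - alpha / 2, n - 1, v)
    f2 <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f1 * mse) /
      (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f2 * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f2 * msr)
    ci <- c(max(-1, lo), min(1, hi))
  }
  structure(list(icc = icc, ci_low = ci[1], ci_high = ci[2],
                 band = if (is.na(icc)) NA_character_ else icc_band(icc),
                 n = n, k = k, msr = msr, msc = msc, mse = mse,
                 conf_level = conf_level),
            class = "icc_agreement")
}

#' @export
print.icc_agreement <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f (%d%% CI %.3f-%.3f), %s reliability, n = %d\n",
              x$icc, round(100 * x$conf_level), x$ci_low, x$ci_high, x$band, x$n))
  invisible(x)
}

#' @rdname icc_agreement
#' @param x An `icc_agreement` object.
#' @param ... Unused.
#' @export
tidy.icc_agreement <- function(x, ...) {
  tibble::tibble(icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high,
                 band = x$band, n = x$n, k = x$k)
}

#' @rdname icc_agreement
#' @export
glance.icc_agreement <- function(x, ...) tidy.icc_agreement(x)

#' Bland-Altman limits of agreement
#'
#' Mean of the paired differences and the limits
#' `mean +/- 1.96 * SD(differences)` (sample SD).
#'
#' @param pairs An `n x 2` matrix or data frame of paired measurements.
#' @return Object of class `bland_altman` with `mean_diff`, `sd_diff`,
#'   `loa_lower`, `loa_upper` and the per-subject `means`/`diffs`.
#' @export
#' @examples
#' bland_altman(cbind(c(10, 20), c(12, 18)))$loa_upper  # 1.96 * sd(c(-2, 2))
bland_altman <- function(pairs) {
  x <- as.matrix(pairs)
  if (ncol(x) != 2L) {
    rlang::abort("Bland-Altman needs exactly two measurements per subject",
                 class = "vesselmetrics_contract_error")
  }
  d <- x[, 1] - x[, 2]
  m <- rowMeans(x)
  md <- mean(d)
  sdd <- if (length(d) > 1L) stats::sd(d) else 0
  structure(list(mean_diff = md, sd_diff = sdd,
                 loa_lower = md - 1.96 * sdd, loa_upper = md + 1.96 * sdd,
                 means = m, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean diff %.3f, limits of agreement [%.3f, %.3f]\n",
              x$mean_diff, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' @rdname bland_altman
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(mean_diff = x$mean_diff, sd_diff = x$sd_diff,
                 loa_lower = x$loa_lower, loa_upper = x$loa_upper,
                 n = length(x$diffs))
}

#' @rdname bland_altman
#' @param object A `bland_altman` object.
#' @export
autoplot.bland_altman <- function(object, ...) {
  df <- tibble::tibble(mean = object$means, diff = object$diffs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$mean_diff, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = 2) +
    ggplot2::labs(x = "Mean of pair", y = "Difference",
                  title = "Bland-Altman agreement") +
    ggplot2::theme_minimal()
}
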