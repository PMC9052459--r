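as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(labels == 1)
  if (is.factor(labels) && nlevels(labels) == 2L) {
    return(labels == levels(labels)[2L])
  }
  stop("labels must be logical, 0/1, or a two-level factor", call. = FALSE)
}

# Orient scores so that larger oriented score = more likely positive.
orient_scores <- function(scores, orientation) {
  if (orientation == "higher_score_positive") scores else -scores
}

#' Empirical ROC curve over midpoint thresholds
#'
#' Builds the receiver operating characteristic curve of a score
#' against a binary anchor. Candidate thresholds sit at the midpoints
#' between adjacent distinct observed scores (so an integer change
#' scale yields half-integer cut points, the granularity at which such
#' thresholds are conventionally reported), plus two degenerate
#' endpoint thresholds outside the observed range giving the
#' (sens = 1, spec = 0) and (sens = 0, spec = 1) operating points.
#'
#' With `orientation = "higher_score_positive"` a pair is classified
#' positive when its score exceeds the threshold; with
#' `"lower_score_positive"` when it falls below (used for PASS, where a
#' lower symptom state indicates an acceptable state).
#'
#' @param labels Logical (or 0/1) vector; `TRUE` is the positive class.
#' @param scores Numeric vector, same length.
#' @param orientation `"higher_score_positive"` or
#'   `"lower_score_positive"`.
#' @param positive_label Free-text meaning of the positive class,
#'   carried into printouts.
#' @return Object of class `prom_roc`: a list with `points` (data frame
#'   of threshold, sensitivity, specificity), `auc`, `n_positive`,
#'   `n_negative`, `orientation`, `positive_label`.
#' @examples
#' r <- roc_curve(c(TRUE, TRUE, FALSE, FALSE), c(3, 4, 0, 1))
#' r$auc
#' optimal_cutpoint(r)
#' @export
roc_curve <- function(labels, scores,
                      orientation = c("higher_score_positive",
                                      "lower_score_positive"),
                      positive_label = "positive") {
  orientation <- match.arg(orientation)
  labels <- as_binary_labels(labels)
  stopifnot(length(labels) == length(scores))
  keep <- !is.na(labels) & !is.na(scores)
  labels <- labels[keep]; scores <- scores[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC undefined: both classes must be present (n_positive = ",
         n_pos, ", n_negative = ", n_neg, ")", call. = FALSE)
  }
  s <- orient_scores(scores, orientation)
  v <- sort(unique(s))
  gap <- if (length(v) > 1L) min(diff(v)) else 1
  thr_or <- c(v[1L] - gap / 2,
              if (length(v) > 1L) (v[-length(v)] + v[-1L]) / 2,
              v[length(v)] + gap / 2)
  # classify positive when oriented score > oriented threshold
  sens <- vapply(thr_or, function(t) mean(s[labels] > t), numeric(1))
  spec <- vapply(thr_or, function(t) mean(s[!labels] <= t), numeric(1))
  thr <- if (orientation == "higher_score_positive") thr_or else -thr_or
  ord <- order(thr)
  points <- data.frame(threshold = thr[ord], sensitivity = sens[ord],
                       specificity = spec[ord])
  structure(list(points = points,
                 auc = auc(labels, scores, orientation),
                 n_positive = n_pos, n_negative = n_neg,
                 orientation = orientation,
                 positive_label = positive_label),
            class = "prom_roc")
}

#' @export
print.prom_roc <- function(x, ...) {
  cat("ROC curve (", x$positive_label, "): ", x$n_positive, " positive / ",
      x$n_negative, " negative, ", nrow(x$points), " operating points\n",
      sep = "")
  cat("Orientation: ", x$orientation, "\n", sep = "")
  cat("AUC (Mann-Whitney): ", format(x$auc, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @param x A `prom_roc` object.
#' @param ... Passed to [plot()].
#' @rdname roc_curve
#' @export
plot.prom_roc <- function(x, ...) {
  fpr <- 1 - x$points$specificity
  tpr <- x$points$sensitivity
  ord <- order(fpr, tpr)
  plot(fpr[ord], tpr[ord], type = "s", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("ROC (%s), AUC = %.3f", x$positive_label, x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  cp <- optimal_cutpoint(x)
  graphics::points(1 - cp$specificity, cp$sensitivity, pch = 19)
  invisible(x)
}

#' Optimal cut point: closest point to the top-left corner
#'
#' Selects the operating point minimising the Euclidean distance
#' `sqrt((1 - sens)^2 + (1 - spec)^2)` to the corner (sens = 1,
#' spec = 1). Exact distance ties are broken toward higher sensitivity,
#' then toward the smaller absolute threshold, so the choice is
#' deterministic.
#'
#' @param curve A [roc_curve()] object.
#' @return List of class `cutpoint` with `threshold`, `sensitivity`,
#'   `specificity`, `distance_to_corner`.
#' @export
optimal_cutpoint <- function(curve) {
  stopifnot(inherits(curve, "prom_roc"))
  p <- curve$points
  d <- sqrt((1 - p$sensitivity)^2 + (1 - p$specificity)^2)
  eps <- 1e-12
  cand <- which(d <= min(d) + eps)
  if (length(cand) > 1L) {
    best_sens <- max(p$sensitivity[cand])
    cand <- cand[p$sensitivity[cand] >= best_sens - eps]
  }
  if (length(cand) > 1L) {
    cand <- cand[order(abs(p$threshold[cand]))][1L]
  }
  structure(list(threshold = p$threshold[cand],
                 sensitivity = p$sensitivity[cand],
                 specificity = p$specificity[cand],
                 distance_to_corner = d[cand]),
            class = "cutpoint")
}

#' @export
print.cutpoint <- function(x, ...) {
  cat(sprintf(
    "Optimal cut point: %.4g (sens %.3f, spec %.3f, corner distance %.4f)\n",
    x$threshold, x$sensitivity, x$specificity, x$distance_to_corner))
  invisible(x)
}

#' Area under the ROC curve (Mann--Whitney estimate)
#'
#' Computed from mid-ranks: the probability that a randomly chosen
#' positive outranks a randomly chosen negative, ties counted one half.
#' This equals the trapezoidal area under the empirical ROC curve.
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(TRUE, TRUE, FALSE, FALSE), c(2, 1, 2, 0))  # 0.625
#' @export
auc <- function(labels, scores,
                orientation = c("higher_score_positive",
                                "lower_score_positive")) {
  orientation <- match.arg(orientation)
  labels <- as_binary_labels(labels)
  keep <- !is.na(labels) & !is.na(scores)
  labels <- labels[keep]; scores <- scores[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  s <- orient_scores(scores, orientation)
  r <- rank(s)  # mid-ranks handle ties
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

discrimination_label <- function(auc) {
  if (auc > 0.8) "excellent" else if (auc >= 0.7) "acceptable" else "poor"
}

#' AUC confidence interval by DeLong's method
#'
#' Nonparametric variance of the Mann--Whitney AUC from placement
#' values (DeLong's structural components): for each positive the
#' fraction of negatives it outranks and vice versa; the variance is
#' `var(V10)/m + var(V01)/n`. The Wald interval `auc +/- z * SE` is
#' truncated to `[0, 1]`. Perfect separation gives zero variance and a
#' degenerate interval, reported with a warning.
#'
#' The discrimination label follows the usual convention: acceptable
#' for AUC in [0.7, 0.8], excellent above 0.8, poor below 0.7 (the
#' boundary 0.8 itself is classed acceptable).
#'
#' @inheritParams roc_curve
#' @param alpha Two-sided error rate (default 0.05 for a 95\% CI).
#' @return Object of class `auc_ci`: list with `auc`, `ci_low`,
#'   `ci_high`, `se`, `method = "delong"`, `discrimination_label`.
#' @export
auc_ci_delong <- function(labels, scores,
                          orientation = c("higher_score_positive",
                                          "lower_score_positive"),
                          alpha = 0.05) {
  orientation <- match.arg(orientation)
  labels <- as_binary_labels(labels)
  keep <- !is.na(labels) & !is.na(scores)
  labels <- labels[keep]; scores <- scores[keep]
  m <- sum(labels); n <- sum(!labels)
  if (m < 2L || n < 2L) {
    stop("DeLong CI requires at least 2 observations in each class (",
         m, " positive, ", n, " negative)", call. = FALSE)
  }
  s <- orient_scores(scores, orientation)
  x <- s[labels]; y <- s[!labels]
  # placement values via mid-ranks: V10_i = (rank of x_i in (x,y) - rank in x)/n
  r_all <- rank(c(x, y))
  v10 <- (r_all[seq_len(m)] - rank(x)) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(y)) / m
  a <- mean(v10)
  v <- stats::var(v10) / m + stats::var(v01) / n
  if (v <= .Machine$double.eps) {
    warning("zero DeLong variance (perfect separation): ",
            "confidence interval collapses to the point estimate",
            call. = FALSE)
    v <- 0
  }
  se <- sqrt(v)
  z <- stats::qnorm(1 - alpha / 2)
  structure(list(auc = a,
                 ci_low = max(0, a - z * se),
                 ci_high = min(1, a + z * se),
                 se = se, alpha = alpha, method = "delong",
                 discrimination_label = discrimination_label(a)),
            class = "auc_ci")
}

#' @export
print.auc_ci <- function(x, ...) {
  cat(sprintf("AUC %.3f (%d%% CI %.3f to %.3f, %s) - %s discrimination\n",
              x$auc, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high,
              x$method, x$discrimination_label))
  invisible(x)
}
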