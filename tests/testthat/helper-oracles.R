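# Independent oracles and fixture builders used across the suite.

# Exhaustive-search cut point oracle: recomputes sensitivity/specificity
# by direct counting at every midpoint threshold (plus outer endpoints),
# independent of the package's ROC construction.
brute_force_cutpoint <- function(labels, scores,
                                 orientation = "higher_score_positive") {
  s <- if (orientation == "higher_score_positive") scores else -scores
  v <- sort(unique(s))
  gap <- if (length(v) > 1) min(diff(v)) else 1
  thr <- c(v[1] - gap / 2,
           if (length(v) > 1) (v[-length(v)] + v[-1]) / 2,
           v[length(v)] + gap / 2)
  best <- NULL
  for (t in thr) {
    sens <- mean(s[labels] > t)
    spec <- mean(s[!labels] <= t)
    d <- sqrt((1 - sens)^2 + (1 - spec)^2)
    orig_t <- if (orientation == "higher_score_positive") t else -t
    cand <- list(threshold = orig_t, sensitivity = sens, specificity = spec,
                 distance = d)
    if (is.null(best) ||
        d < best$distance - 1e-12 ||
        (abs(d - best$distance) <= 1e-12 &&
         (sens > best$sensitivity + 1e-12 ||
          (abs(sens - best$sensitivity) <= 1e-12 &&
           abs(orig_t) < abs(best$threshold))))) {
      best <- cand
    }
  }
  best
}

# Trapezoidal area under an ROC curve's operating points.
trapezoid_auc <- function(curve) {
  fpr <- 1 - curve$points$specificity
  tpr <- curve$points$sensitivity
  ord <- order(fpr, tpr)
  fpr <- c(0, fpr[ord], 1)
  tpr <- c(0, tpr[ord], 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Random binary-label instance on an integer or half-integer score grid,
# with ties likely.
random_roc_instance <- function(n_max = 50) {
  n <- sample(4:n_max, 1)
  repeat {
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (any(labels) && any(!labels)) break
  }
  grid <- if (runif(1) < 0.5) 0:10 else seq(0, 10, by = 0.5)
  scores <- sample(grid, n, replace = TRUE) +
    labels * sample(0:3, n, replace = TRUE)  # mild signal
  list(labels = labels, scores = pmin(scores, 10))
}

# Minimal anchor-pairs fixture for the estimators.
make_pairs <- function(change, grc_label, state = NULL, baseline = NULL,
                       pass_satisfied = NA, instrument = "nrs",
                       timepoint = "m3") {
  n <- length(change)
  if (is.null(state)) state <- rep(0, n)
  if (is.null(baseline)) baseline <- change + state
  df <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    timepoint = rep_len(timepoint, n),
    instrument = instrument,
    baseline = baseline, state = state, change = change,
    grc = unname(grc_levels()[grc_label]),
    grc_label = grc_label,
    pass_satisfied = rep_len(pass_satisfied, n),
    stringsAsFactors = FALSE)
  structure(df, instrument = instrument, range = 10,
            class = c("anchor_pairs", "data.frame"))
}

# Direct maximum-likelihood logistic fit by optim(), as an oracle for
# the predictive-modelling coefficients.
logistic_ml_oracle <- function(y, x) {
  nll <- function(b) {
    eta <- b[1] + b[2] * x
    -sum(y * eta - log1p(exp(eta)))
  }
  stats::optim(c(0, 0.1), nll, method = "BFGS",
               control = list(reltol = 1e-14))$par
}
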