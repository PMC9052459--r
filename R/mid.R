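#' Dichotomisation of the global rating of change
#'
#' For the ROC and predictive-modelling MID estimators the five GRC
#' levels are split into an improved set, a reference set, and an
#' excluded set (deteriorated patients are dropped). The default puts
#' the cut between "unchanged" and "somewhat better", so both
#' "somewhat better" and "much better" count as improved, "unchanged"
#' is the reference, and the two "worse" levels are excluded.
#'
#' @param improved,reference,excluded Character vectors of GRC labels;
#'   together they must partition the five levels.
#' @return List of class `grc_dichotomization`.
#' @export
grc_dichotomization <- function(improved = c("much_better", "somewhat_better"),
                                reference = "unchanged",
                                excluded = c("somewhat_worse", "much_worse")) {
  all_levels <- names(grc_levels())
  sets <- list(improved = improved, reference = reference, excluded = excluded)
  flat <- unlist(sets, use.names = FALSE)
  if (length(flat) != 5L || !setequal(flat, all_levels) || anyDuplicated(flat)) {
    stop("improved/reference/excluded must partition the five GRC levels",
         call. = FALSE)
  }
  if (length(reference) == 0L) {
    stop("reference set must be non-empty", call. = FALSE)
  }
  structure(sets, class = "grc_dichotomization")
}

dichotomize_pairs <- function(pairs, dicho) {
  lab <- pairs$grc_label
  keep <- lab %in% c(dicho$improved, dicho$reference)
  p <- pairs[keep, , drop = FALSE]
  p$improved <- p$grc_label %in% dicho$improved
  p
}

mid_fit_obj <- function(...) {
  structure(list(...), class = "mid_fit")
}

boot_cluster <- function(pairs, boot_unit) {
  if (boot_unit == "patient") pairs$patient_id else NULL
}

#' Anchor-based minimal important difference (MID) estimation
#'
#' Estimates the smallest change in an instrument's score that patients
#' perceive as an important improvement, anchored to the global rating
#' of change, by one of four established methods:
#'
#' \describe{
#'   \item{`"mc"` (mean change)}{Mean change score of the pairs rating
#'     themselves "somewhat better" (only that level: the smallest
#'     perceived improvement).}
#'   \item{`"mdc"` (mean difference of change)}{Mean change among
#'     "somewhat better" minus mean change among the reference
#'     ("unchanged") pairs.}
#'   \item{`"roc"`}{Optimal cut point (closest to the top-left corner)
#'     of the ROC curve of the change score discriminating improved
#'     from unchanged pairs; reports sensitivity, specificity and the
#'     AUC with a DeLong confidence interval.}
#'   \item{`"predictive"`}{Logistic regression of improved-vs-unchanged
#'     on the change score, `logit P(improved) = C + B * change`; the
#'     MID is the change value where the likelihood ratio for
#'     improvement equals 1, `(ln(pre_odds) - C) / B` with
#'     `pre_odds = n_improved / n_reference`. The unadjusted variant
#'     `-C / B` (the 50\% posterior-probability point) is also stored.}
#' }
#'
#' Confidence intervals for the MID itself are percentile bootstrap
#' (re-running the full estimator on each resample); `n_boot = 0`
#' skips them.
#'
#' @param pairs Anchor--outcome pairs from [build_pairs()].
#' @param method `"mc"`, `"mdc"`, `"roc"` or `"predictive"`.
#' @param dichotomization A [grc_dichotomization()] (ROC/predictive).
#' @param n_boot Bootstrap replicates for the MID CI (default 1000).
#' @param conf_level Confidence level (default 0.95).
#' @param seed Optional integer seed for the bootstrap.
#' @param boot_unit Resampling unit, `"pair"` (default) or `"patient"`.
#' @return Object of class `mid_fit` with the estimate (`mid`, in
#'   change-score units, positive = improvement), `ci_low`/`ci_high`,
#'   method-specific fields (`sensitivity`, `specificity`, `auc`,
#'   logistic `C`, `B`, `pre_odds`, `mid_unadjusted`) and group sizes.
#' @examples
#' coh <- generate_cohort(synthetic_config(seed = 7))
#' p <- build_pairs(coh, "nrs")
#' fit <- mid(p, "roc", n_boot = 50, seed = 1)
#' fit
#' coef(fit)
#' @seealso [mid_all()], [pass()]
#' @export
mid <- function(pairs, method = c("roc", "mc", "mdc", "predictive"),
                dichotomization = grc_dichotomization(),
                n_boot = 1000, conf_level = 0.95, seed = NULL,
                boot_unit = c("pair", "patient")) {
  method <- match.arg(method)
  boot_unit <- match.arg(boot_unit)
  stopifnot(is.data.frame(pairs), all(c("change", "grc_label") %in% names(pairs)))
  alpha <- 1 - conf_level
  instrument <- attr(pairs, "instrument") %||% "score"

  est <- switch(method,
                mc = mid_point_mc,
                mdc = mid_point_mdc,
                roc = mid_point_roc,
                predictive = mid_point_predictive)
  point <- est(pairs, dichotomization)  # errors propagate with context

  ci <- c(NA_real_, NA_real_)
  boot_note <- NULL
  if (n_boot > 0) {
    bdata <- switch(method,
                    mc = pairs[pairs$grc_label == "somewhat_better", , drop = FALSE],
                    mdc = pairs[pairs$grc_label %in%
                                  c("somewhat_better", dichotomization$reference), ,
                                drop = FALSE],
                    dichotomize_pairs(pairs, dichotomization))
    # lean per-resample statistics: skip the DeLong CI inside the bootstrap
    stat <- switch(method,
      roc = function(d) {
        if (sum(d$improved) < 2L || sum(!d$improved) < 2L) stop("class too small")
        optimal_cutpoint(roc_curve(d$improved, d$change))$threshold
      },
      predictive = function(d) predictive_mid_quick(d),
      function(d) est(d, dichotomization)$mid)
    ci <- bootstrap_ci(stat, bdata, n_reps = n_boot, alpha = alpha,
                       seed = seed, cluster = boot_cluster(bdata, boot_unit))
    if (ci[1L] == ci[2L]) {
      warning("degenerate bootstrap CI (point-mass replicate distribution)",
              call. = FALSE)
      boot_note <- "degenerate"
    }
  }

  mid_fit_obj(instrument = instrument, method = method,
              mid = point$mid, ci_low = ci[1L], ci_high = ci[2L],
              conf_level = conf_level, n_boot = n_boot,
              sensitivity = point$sensitivity, specificity = point$specificity,
              auc = point$auc, C = point$C, B = point$B,
              pre_odds = point$pre_odds, mid_unadjusted = point$mid_unadjusted,
              n_improved = point$n_improved, n_reference = point$n_reference,
              dichotomization = dichotomization, boot_unit = boot_unit,
              boot_note = boot_note, seed = seed)
}

# Fast prevalence-adjusted predictive MID on a dichotomised resample;
# NA/error on separation or non-positive slope (bootstrap redraws those).
predictive_mid_quick <- function(d) {
  n_imp <- sum(d$improved); n_ref <- sum(!d$improved)
  if (n_imp < 2L || n_ref < 2L) stop("class too small")
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, d$change), as.numeric(d$improved),
                   family = stats::binomial()))
  if (!fit$converged) stop("no convergence")
  C <- fit$coefficients[1L]; B <- fit$coefficients[2L]
  if (!is.finite(B) || B <= 0) stop("non-positive slope")
  unname((log(n_imp / n_ref) - C) / B)
}

mid_point_mc <- function(pairs, dicho) {
  ch <- pairs$change[pairs$grc_label == "somewhat_better"]
  ch <- ch[!is.na(ch)]
  if (length(ch) == 0L) {
    stop("mean change method: no pairs with GRC 'somewhat_better'",
         call. = FALSE)
  }
  list(mid = mean(ch), n_improved = length(ch), n_reference = NA_integer_)
}

mid_point_mdc <- function(pairs, dicho) {
  sb <- pairs$change[pairs$grc_label == "somewhat_better"]
  ref <- pairs$change[pairs$grc_label %in% dicho$reference]
  sb <- sb[!is.na(sb)]; ref <- ref[!is.na(ref)]
  if (length(sb) == 0L) {
    stop("mean difference of change: 'somewhat_better' group is empty",
         call. = FALSE)
  }
  if (length(ref) == 0L) {
    stop("mean difference of change: reference ('unchanged') group is empty",
         call. = FALSE)
  }
  list(mid = mean(sb) - mean(ref), n_improved = length(sb),
       n_reference = length(ref))
}

mid_point_roc <- function(pairs, dicho) {
  p <- dichotomize_pairs(pairs, dicho)
  n_imp <- sum(p$improved); n_ref <- sum(!p$improved)
  if (n_imp < 2L || n_ref < 2L) {
    stop("ROC method needs >= 2 improved and >= 2 reference pairs (have ",
         n_imp, " and ", n_ref, ")", call. = FALSE)
  }
  curve <- roc_curve(p$improved, p$change,
                     orientation = "higher_score_positive",
                     positive_label = "improved")
  cp <- optimal_cutpoint(curve)
  auc_ci <- auc_ci_delong(p$improved, p$change,
                          orientation = "higher_score_positive")
  list(mid = cp$threshold, sensitivity = cp$sensitivity,
       specificity = cp$specificity, auc = auc_ci,
       n_improved = n_imp, n_reference = n_ref)
}

mid_point_predictive <- function(pairs, dicho) {
  p <- dichotomize_pairs(pairs, dicho)
  n_imp <- sum(p$improved); n_ref <- sum(!p$improved)
  if (n_imp < 2L || n_ref < 2L) {
    stop("predictive method needs >= 2 improved and >= 2 reference pairs",
         call. = FALSE)
  }
  sep_msg <- paste0("predictive method: logistic fit did not converge or ",
                    "separated; use the ROC method (mid_roc) instead")
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, p$change), as.numeric(p$improved),
                   family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        stop(sep_msg, call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  if (!fit$converged) stop(sep_msg, call. = FALSE)
  C <- fit$coefficients[1L]; B <- fit$coefficients[2L]
  if (!is.finite(B) || B <= 0) {
    stop("predictive method: anchor and change score are inversely related ",
         "(slope B <= 0)", call. = FALSE)
  }
  pre_odds <- n_imp / n_ref
  list(mid = unname((log(pre_odds) - C) / B),
       mid_unadjusted = unname(-C / B),
       C = unname(C), B = unname(B), pre_odds = pre_odds,
       auc = auc_ci_delong(p$improved, p$change,
                           orientation = "higher_score_positive"),
       n_improved = n_imp, n_reference = n_ref)
}

#' @rdname mid
#' @export
mid_mc <- function(pairs, n_boot = 1000, seed = NULL, ...) {
  mid(pairs, method = "mc", n_boot = n_boot, seed = seed, ...)
}

#' @rdname mid
#' @export
mid_mdc <- function(pairs, n_boot = 1000, seed = NULL, ...) {
  mid(pairs, method = "mdc", n_boot = n_boot, seed = seed, ...)
}

#' @rdname mid
#' @param ... Passed on to [mid()].
#' @export
mid_roc <- function(pairs, dichotomization = grc_dichotomization(),
                    n_boot = 1000, seed = NULL, ...) {
  mid(pairs, method = "roc", dichotomization = dichotomization,
      n_boot = n_boot, seed = seed, ...)
}

#' @rdname mid
#' @export
mid_predictive <- function(pairs, dichotomization = grc_dichotomization(),
                           n_boot = 1000, seed = NULL, ...) {
  mid(pairs, method = "predictive", dichotomization = dichotomization,
      n_boot = n_boot, seed = seed, ...)
}

#' @export
print.mid_fit <- function(x, ...) {
  lab <- c(mc = "mean change", mdc = "mean difference of change",
           roc = "ROC optimal cut point", predictive = "predictive modelling")
  cat(sprintf("MID (%s) for %s: %.4g", lab[[x$method]], x$instrument, x$mid))
  if (!is.na(x$ci_low)) {
    cat(sprintf(" (%d%% CI %.4g to %.4g)", round(100 * x$conf_level),
                x$ci_low, x$ci_high))
  }
  cat("\n")
  invisible(x)
}

#' @export
summary.mid_fit <- function(object, ...) {
  print(object)
  cat(sprintf("Groups: n_improved = %s, n_reference = %s\n",
              object$n_improved, object$n_reference))
  if (!is.null(object$sensitivity)) {
    cat(sprintf("At cut point: sensitivity %.3f, specificity %.3f\n",
                object$sensitivity, object$specificity))
  }
  if (!is.null(object$auc)) print(object$auc)
  if (!is.null(object$C)) {
    cat(sprintf(
      "Logistic fit: C (intercept) = %.4g, B (slope) = %.4g, pre-test odds = %.4g\n",
      object$C, object$B, object$pre_odds))
    cat(sprintf("Unadjusted MID (-C/B): %.4g\n", object$mid_unadjusted))
  }
  if (object$n_boot > 0) {
    cat(sprintf("CI: percentile bootstrap, %d replicates, %s resampling\n",
                object$n_boot, object$boot_unit))
  }
  invisible(object)
}

#' @export
coef.mid_fit <- function(object, ...) {
  out <- c(mid = object$mid)
  if (!is.null(object$C)) out <- c(out, C = object$C, B = object$B)
  out
}

#' @export
confint.mid_fit <- function(object, parm = "mid", level = NULL, ...) {
  if (!is.null(level) && !isTRUE(all.equal(level, object$conf_level))) {
    stop("CI was computed at level ", object$conf_level,
         "; re-fit with conf_level = ", level, call. = FALSE)
  }
  m <- matrix(c(object$ci_low, object$ci_high), nrow = 1,
              dimnames = list("mid", c("low", "high")))
  m
}

#' Predicted probability of perceived improvement
#'
#' For a predictive-modelling fit, returns the fitted logistic
#' probability of an "improved" anchor rating at given change scores;
#' for an ROC fit, returns the binary classification at the estimated
#' cut point.
#'
#' @param object A `mid_fit`.
#' @param newdata Numeric vector of change scores (or data frame with a
#'   `change` column).
#' @param ... Unused.
#' @export
predict.mid_fit <- function(object, newdata, ...) {
  change <- if (is.data.frame(newdata)) newdata$change else newdata
  if (object$method == "predictive") {
    stats::plogis(object$C + object$B * change)
  } else if (object$method == "roc") {
    change > object$mid
  } else {
    stop("predict() is defined for 'roc' and 'predictive' fits only",
         call. = FALSE)
  }
}

#' MID by all four methods for all registered instruments
#'
#' Runs the mean-change, mean-difference-of-change, ROC and
#' predictive-modelling estimators for each requested instrument and
#' assembles the results into one table (the usual
#' instrument-by-method layout). A method failing on one instrument
#' (for example an empty reference group) is recorded as an error
#' marker in that cell without aborting the rest.
#'
#' @param cohort A [prom_cohort()].
#' @param instruments Instruments to analyse (default all four).
#' @inheritParams mid
#' @return Data frame of class `mid_table`: one row per instrument and
#'   method with `mid`, `ci_low`, `ci_high`, `sensitivity`,
#'   `specificity`, `auc`, `auc_low`, `auc_high`, `n_improved`,
#'   `n_reference`, `error`.
#' @export
mid_all <- function(cohort, instruments = instrument_registry()$instrument,
                    dichotomization = grc_dichotomization(),
                    n_boot = 1000, conf_level = 0.95, seed = NULL,
                    boot_unit = c("pair", "patient")) {
  boot_unit <- match.arg(boot_unit)
  methods <- c("mdc", "mc", "roc", "predictive")
  rows <- list()
  for (ins in instruments) {
    pairs <- build_pairs(cohort, ins)
    for (i in seq_along(methods)) {
      m <- methods[i]
      cell_seed <- if (is.null(seed)) NULL
                   else seed + 100L * match(ins, instruments) + i
      fit <- tryCatch(
        suppressWarnings(mid(pairs, method = m,
                             dichotomization = dichotomization,
                             n_boot = n_boot, conf_level = conf_level,
                             seed = cell_seed, boot_unit = boot_unit)),
        error = function(e) e)
      rows[[length(rows) + 1L]] <- if (inherits(fit, "error")) {
        data.frame(instrument = ins, method = m, mid = NA_real_,
                   ci_low = NA_real_, ci_high = NA_real_,
                   sensitivity = NA_real_, specificity = NA_real_,
                   auc = NA_real_, auc_low = NA_real_, auc_high = NA_real_,
                   n_improved = NA_integer_, n_reference = NA_integer_,
                   error = conditionMessage(fit), stringsAsFactors = FALSE)
      } else {
        data.frame(instrument = ins, method = m, mid = fit$mid,
                   ci_low = fit$ci_low, ci_high = fit$ci_high,
                   sensitivity = fit$sensitivity %||% NA_real_,
                   specificity = fit$specificity %||% NA_real_,
                   auc = if (is.null(fit$auc)) NA_real_ else fit$auc$auc,
                   auc_low = if (is.null(fit$auc)) NA_real_ else fit$auc$ci_low,
                   auc_high = if (is.null(fit$auc)) NA_real_ else fit$auc$ci_high,
                   n_improved = fit$n_improved %||% NA_integer_,
                   n_reference = fit$n_reference %||% NA_integer_,
                   error = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, conf_level = conf_level,
            class = c("mid_table", "data.frame"))
}

#' @export
print.mid_table <- function(x, digits = 3, ...) {
  cat("MID estimates (change-score units, positive = improvement), ",
      round(100 * attr(x, "conf_level")), "% CIs\n", sep = "")
  fmt <- function(v, lo, hi) {
    ifelse(is.na(v), "--",
           ifelse(is.na(lo), sprintf("%.3g", v),
                  sprintf("%.3g (%.3g to %.3g)", v, lo, hi)))
  }
  wide <- do.call(rbind, lapply(split(x, x$instrument)[unique(x$instrument)],
    function(d) {
      data.frame(instrument = d$instrument[1L],
                 mdc = fmt(d$mid[d$method == "mdc"],
                           d$ci_low[d$method == "mdc"],
                           d$ci_high[d$method == "mdc"]),
                 mc = fmt(d$mid[d$method == "mc"],
                          d$ci_low[d$method == "mc"],
                          d$ci_high[d$method == "mc"]),
                 roc = fmt(d$mid[d$method == "roc"],
                           d$ci_low[d$method == "roc"],
                           d$ci_high[d$method == "roc"]),
                 predictive = fmt(d$mid[d$method == "predictive"],
                                  d$ci_low[d$method == "predictive"],
                                  d$ci_high[d$method == "predictive"]),
                 stringsAsFactors = FALSE)
    }))
  print.data.frame(wide, row.names = FALSE)
  if (any(!is.na(x$error))) {
    cat("Failed cells:\n")
    bad <- x[!is.na(x$error), c("instrument", "method", "error")]
    print.data.frame(bad, row.names = FALSE)
  }
  invisible(x)
}
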