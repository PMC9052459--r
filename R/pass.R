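#' Patient acceptable symptom state (PASS) estimation
#'
#' Estimates the symptom-state score below which patients consider
#' themselves well, anchored to the binary satisfaction question
#' ("would you be satisfied if your condition were to stay like
#' this?"). PASS is a state concept, so both methods operate on
#' follow-up state scores, never change scores:
#'
#' \describe{
#'   \item{`"percentile75"`}{The 75th percentile of the state scores of
#'     the satisfied pairs (linear-interpolation quantile, the type-7
#'     definition with index `h = (n - 1) p + 1`).}
#'   \item{`"roc"`}{The ROC optimal cut point (closest to the top-left
#'     corner) discriminating satisfied from unsatisfied pairs, with
#'     lower scores oriented positive (acceptable); reports
#'     sensitivity (satisfied at or below the threshold), specificity
#'     (unsatisfied above it), and the AUC with a DeLong interval.}
#' }
#'
#' @param pairs Anchor--outcome pairs carrying `state` and
#'   `pass_satisfied` (from [build_pairs()]; rows with a missing PASS
#'   anchor are dropped and counted).
#' @param method `"roc"` or `"percentile75"`.
#' @param prob Percentile for the percentile method (default 0.75).
#' @param n_boot Bootstrap replicates for a percentile CI of the
#'   threshold (default 1000; `0` skips it).
#' @param conf_level Confidence level (default 0.95).
#' @param seed Optional integer seed.
#' @param boot_unit `"pair"` (default) or `"patient"`.
#' @param scope `"pooled"` (default, all follow-ups) or `"final"`
#'   (only the last follow-up, m12).
#' @return Object of class `pass_fit` with `pass_threshold` (scores at
#'   or below it are "acceptable"), and for the ROC method
#'   `sensitivity`, `specificity` and `auc`.
#' @examples
#' coh <- generate_cohort(synthetic_config(seed = 7))
#' p <- build_pairs(coh, "nrs", require_anchor = "pass")
#' pass(p, "percentile75", n_boot = 0)
#' @seealso [pass_all()], [mid()]
#' @export
pass <- function(pairs, method = c("roc", "percentile75"), prob = 0.75,
                 n_boot = 1000, conf_level = 0.95, seed = NULL,
                 boot_unit = c("pair", "patient"),
                 scope = c("pooled", "final")) {
  method <- match.arg(method)
  boot_unit <- match.arg(boot_unit)
  scope <- match.arg(scope)
  stopifnot(is.data.frame(pairs),
            all(c("state", "pass_satisfied") %in% names(pairs)))
  alpha <- 1 - conf_level
  instrument <- attr(pairs, "instrument") %||% "score"
  p <- pairs[!is.na(pairs$pass_satisfied) & !is.na(pairs$state), , drop = FALSE]
  if (scope == "final") p <- p[p$timepoint == "m12", , drop = FALSE]
  n_sat <- sum(p$pass_satisfied); n_unsat <- sum(!p$pass_satisfied)

  if (method == "percentile75") {
    if (n_sat == 0L) {
      stop("PASS percentile method: no satisfied pairs", call. = FALSE)
    }
    if (n_sat < 4L) {
      warning("only ", n_sat, " satisfied pairs: the ", 100 * prob,
              "th percentile is unstable", call. = FALSE)
    }
    thr <- unname(stats::quantile(p$state[p$pass_satisfied], prob, type = 7))
    point <- list(pass_threshold = thr)
    stat <- function(d) {
      s <- d$state[d$pass_satisfied]
      if (!length(s)) stop("no satisfied pairs in resample")
      unname(stats::quantile(s, prob, type = 7))
    }
  } else {
    if (n_sat < 2L || n_unsat < 2L) {
      stop("PASS ROC method needs >= 2 satisfied and >= 2 unsatisfied pairs ",
           "(have ", n_sat, " and ", n_unsat, ")", call. = FALSE)
    }
    curve <- roc_curve(p$pass_satisfied, p$state,
                       orientation = "lower_score_positive",
                       positive_label = "acceptable state")
    cp <- optimal_cutpoint(curve)
    point <- list(pass_threshold = cp$threshold,
                  sensitivity = cp$sensitivity,
                  specificity = cp$specificity,
                  auc = auc_ci_delong(p$pass_satisfied, p$state,
                                      orientation = "lower_score_positive"))
    stat <- function(d) {
      if (sum(d$pass_satisfied) < 2L || sum(!d$pass_satisfied) < 2L) {
        stop("class too small")
      }
      optimal_cutpoint(roc_curve(d$pass_satisfied, d$state,
                                 orientation = "lower_score_positive"))$threshold
    }
  }

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    ci <- bootstrap_ci(stat, p, n_reps = n_boot, alpha = alpha, seed = seed,
                       cluster = boot_cluster(p, boot_unit))
    if (ci[1L] == ci[2L]) {
      warning("degenerate bootstrap CI (point-mass replicate distribution)",
              call. = FALSE)
    }
  }

  structure(c(point,
              list(instrument = instrument, method = method, prob = prob,
                   ci_low = ci[1L], ci_high = ci[2L],
                   conf_level = conf_level, n_boot = n_boot,
                   n_satisfied = n_sat, n_unsatisfied = n_unsat,
                   scope = scope, boot_unit = boot_unit, seed = seed)),
            class = "pass_fit")
}

#' @rdname pass
#' @param ... Passed on to [pass()].
#' @export
pass_percentile <- function(pairs, prob = 0.75, n_boot = 0, ...) {
  pass(pairs, method = "percentile75", prob = prob, n_boot = n_boot, ...)
}

#' @rdname pass
#' @export
pass_roc <- function(pairs, n_boot = 0, seed = NULL, ...) {
  pass(pairs, method = "roc", n_boot = n_boot, seed = seed, ...)
}

#' @export
print.pass_fit <- function(x, ...) {
  lab <- c(percentile75 = sprintf("%gth percentile", 100 * x$prob),
           roc = "ROC optimal cut point")
  cat(sprintf("PASS (%s) for %s: %.4g", lab[[x$method]], x$instrument,
              x$pass_threshold))
  if (!is.na(x$ci_low)) {
    cat(sprintf(" (%d%% CI %.4g to %.4g)", round(100 * x$conf_level),
                x$ci_low, x$ci_high))
  }
  cat("  [scores <= threshold are acceptable]\n")
  invisible(x)
}

#' @export
summary.pass_fit <- function(object, ...) {
  print(object)
  cat(sprintf("Anchor: %d satisfied, %d unsatisfied (%s scope)\n",
              object$n_satisfied, object$n_unsatisfied, object$scope))
  if (!is.null(object$sensitivity)) {
    cat(sprintf("At cut point: sensitivity %.3f, specificity %.3f\n",
                object$sensitivity, object$specificity))
  }
  if (!is.null(object$auc)) print(object$auc)
  invisible(object)
}

#' @export
coef.pass_fit <- function(object, ...) {
  c(pass_threshold = object$pass_threshold)
}

#' @export
confint.pass_fit <- function(object, parm = "pass_threshold", level = NULL, ...) {
  matrix(c(object$ci_low, object$ci_high), nrow = 1,
         dimnames = list("pass_threshold", c("low", "high")))
}

#' PASS by both methods for all registered instruments
#'
#' Runs the 75th-percentile and ROC PASS estimators per instrument,
#' assembling a table; per-cell failures are recorded without aborting.
#'
#' @param cohort A [prom_cohort()].
#' @param instruments Instruments to analyse (default all four).
#' @inheritParams pass
#' @return Data frame of class `pass_table`.
#' @export
pass_all <- function(cohort, instruments = instrument_registry()$instrument,
                     prob = 0.75, n_boot = 0, conf_level = 0.95, seed = NULL,
                     boot_unit = c("pair", "patient"),
                     scope = c("pooled", "final")) {
  boot_unit <- match.arg(boot_unit)
  scope <- match.arg(scope)
  methods <- c("percentile75", "roc")
  rows <- list()
  for (ins in instruments) {
    pairs <- build_pairs(cohort, ins, require_anchor = "pass")
    for (i in seq_along(methods)) {
      m <- methods[i]
      cell_seed <- if (is.null(seed)) NULL
                   else seed + 100L * match(ins, instruments) + i
      fit <- tryCatch(
        suppressWarnings(pass(pairs, method = m, prob = prob,
                              n_boot = n_boot, conf_level = conf_level,
                              seed = cell_seed, boot_unit = boot_unit,
                              scope = scope)),
        error = function(e) e)
      rows[[length(rows) + 1L]] <- if (inherits(fit, "error")) {
        data.frame(instrument = ins, method = m, pass_threshold = NA_real_,
                   ci_low = NA_real_, ci_high = NA_real_,
                   sensitivity = NA_real_, specificity = NA_real_,
                   auc = NA_real_, auc_low = NA_real_, auc_high = NA_real_,
                   n_satisfied = NA_integer_, n_unsatisfied = NA_integer_,
                   error = conditionMessage(fit), stringsAsFactors = FALSE)
      } else {
        data.frame(instrument = ins, method = m,
                   pass_threshold = fit$pass_threshold,
                   ci_low = fit$ci_low, ci_high = fit$ci_high,
                   sensitivity = fit$sensitivity %||% NA_real_,
                   specificity = fit$specificity %||% NA_real_,
                   auc = if (is.null(fit$auc)) NA_real_ else fit$auc$auc,
                   auc_low = if (is.null(fit$auc)) NA_real_ else fit$auc$ci_low,
                   auc_high = if (is.null(fit$auc)) NA_real_ else fit$auc$ci_high,
                   n_satisfied = fit$n_satisfied,
                   n_unsatisfied = fit$n_unsatisfied,
                   error = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, conf_level = conf_level,
            class = c("pass_table", "data.frame"))
}

#' @export
print.pass_table <- function(x, digits = 3, ...) {
  cat("PASS estimates (state-score units; scores <= threshold are acceptable)\n")
  wide <- do.call(rbind, lapply(split(x, x$instrument)[unique(x$instrument)],
    function(d) {
      roc <- d[d$method == "roc", ]
      p75 <- d[d$method == "percentile75", ]
      data.frame(instrument = d$instrument[1L],
                 percentile75 = ifelse(is.na(p75$pass_threshold), "--",
                                       sprintf("%.3g", p75$pass_threshold)),
                 roc = ifelse(is.na(roc$pass_threshold), "--",
                              sprintf("%.3g", roc$pass_threshold)),
                 sensitivity = ifelse(is.na(roc$sensitivity), "--",
                                      sprintf("%.2f", roc$sensitivity)),
                 specificity = ifelse(is.na(roc$specificity), "--",
                                      sprintf("%.2f", roc$specificity)),
                 auc = ifelse(is.na(roc$auc), "--",
                              sprintf("%.2f (%.2f to %.2f)", roc$auc,
                                      roc$auc_low, roc$auc_high)),
                 stringsAsFactors = FALSE)
    }))
  print.data.frame(wide, row.names = FALSE)
  if (any(!is.na(x$error))) {
    cat("Failed cells:\n")
    print.data.frame(x[!is.na(x$error), c("instrument", "method", "error")],
                     row.names = FALSE)
  }
  invisible(x)
}
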