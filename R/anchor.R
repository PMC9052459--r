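#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties), the
#' classical Spearman rho. Thin wrapper around
#' `stats::cor(method = "spearman")` with the validation this package
#' needs: equal lengths of at least 3 and at least two distinct values
#' in each vector.
#'
#' @param x,y Numeric or ordinal vectors of equal length.
#' @return Spearman's rho in `[-1, 1]`.
#' @examples
#' spearman_rho(1:5, 1:5)        #  1
#' spearman_rho(1:3, 3:1)        # -1
#' @export
spearman_rho <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) != length(y) || length(x) < 3L) {
    stop("spearman_rho needs equal-length vectors with n >= 3", call. = FALSE)
  }
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("correlation undefined: constant vector", call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}

#' Anchor credibility report
#'
#' Assesses whether the global rating of change (GRC) is a credible
#' anchor for an instrument by correlating it (Spearman) with the
#' baseline score, the follow-up score, and the change score, each with
#' a percentile bootstrap confidence interval. The anchor is judged
#' credible when the magnitude of the change-score correlation exceeds
#' 0.5; because GRC 1 means "much better" while positive change means
#' improvement, credible change correlations are negative, so the rule
#' is applied to `|rho|`. The baseline and follow-up correlations are
#' reported without a pass/fail judgement.
#'
#' @param pairs An [build_pairs()] result (needs `grc`, `baseline`,
#'   `state`, `change`).
#' @param scope `"pooled"` (default, all follow-ups together) or
#'   `"per_timepoint"`.
#' @param n_boot Bootstrap replicates for the CIs (default 1000);
#'   `0` skips the CIs.
#' @param conf_level Confidence level (default 0.95).
#' @param seed Optional integer seed for the bootstrap.
#' @param min_n Scopes with fewer pairs than this emit a low-n warning
#'   (default 10).
#' @param boot_unit Resampling unit: `"pair"` (default) or `"patient"`
#'   (cluster bootstrap).
#' @return Data frame of class `anchor_validation`: one row per scope
#'   with `rho_baseline`, `rho_followup`, `rho_change` (each with
#'   `*_low`, `*_high`), `n_pairs` and `credible`.
#' @export
validate_anchor <- function(pairs, scope = c("pooled", "per_timepoint"),
                            n_boot = 1000, conf_level = 0.95, seed = NULL,
                            min_n = 10, boot_unit = c("pair", "patient")) {
  scope <- match.arg(scope)
  boot_unit <- match.arg(boot_unit)
  stopifnot(is.data.frame(pairs))
  alpha <- 1 - conf_level
  pairs <- pairs[!is.na(pairs$grc), , drop = FALSE]
  if (nrow(pairs) == 0L) stop("no pairs with a GRC anchor", call. = FALSE)

  one_scope <- function(p, label, seed_offset) {
    if (nrow(p) < min_n) {
      warning("scope '", label, "' has only ", nrow(p),
              " pairs (< ", min_n, "): correlations are unstable",
              call. = FALSE)
    }
    comp <- c(rho_baseline = "baseline", rho_followup = "state",
              rho_change = "change")
    row <- list(instrument = attr(pairs, "instrument") %||% "unknown",
                scope = label, n_pairs = nrow(p))
    for (k in seq_along(comp)) {
      nm <- names(comp)[k]
      col <- comp[[k]]
      rho <- tryCatch(spearman_rho(p$grc, p[[col]]),
                      error = function(e) NA_real_)
      row[[nm]] <- rho
      if (n_boot > 0 && !is.na(rho) && nrow(p) >= 3L) {
        ci <- bootstrap_ci(function(d) spearman_rho(d$grc, d[[col]]),
                           p, n_reps = n_boot, alpha = alpha,
                           seed = if (is.null(seed)) NULL
                                  else seed + seed_offset + k,
                           cluster = if (boot_unit == "patient")
                                       p$patient_id else NULL)
        row[[paste0(nm, "_low")]] <- ci[1L]
        row[[paste0(nm, "_high")]] <- ci[2L]
      } else {
        row[[paste0(nm, "_low")]] <- NA_real_
        row[[paste0(nm, "_high")]] <- NA_real_
      }
    }
    row$credible <- !is.na(row$rho_change) && abs(row$rho_change) > 0.5
    as.data.frame(row, stringsAsFactors = FALSE)
  }

  out <- if (scope == "pooled") {
    one_scope(pairs, "pooled", 0L)
  } else {
    tps <- intersect(followup_levels(), unique(pairs$timepoint))
    do.call(rbind, lapply(seq_along(tps), function(i) {
      one_scope(pairs[pairs$timepoint == tps[i], , drop = FALSE],
                tps[i], 10L * i)
    }))
  }
  rownames(out) <- NULL
  structure(out, conf_level = conf_level, n_boot = n_boot,
            class = c("anchor_validation", "data.frame"))
}

#' @export
print.anchor_validation <- function(x, digits = 3, ...) {
  cat("Anchor credibility (Spearman rho vs GRC), ",
      round(100 * attr(x, "conf_level")), "% bootstrap CIs, credible if |rho_change| > 0.5\n",
      sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
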