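# Evaluate expr under a temporary RNG state; the caller's stream is untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

resample_rows <- function(data, idx) {
  if (is.data.frame(data) || is.matrix(data)) data[idx, , drop = FALSE]
  else data[idx]
}

data_size <- function(data) {
  if (is.data.frame(data) || is.matrix(data)) nrow(data) else length(data)
}

#' Nonparametric percentile bootstrap confidence interval
#'
#' Resamples the data with replacement, recomputes the statistic on
#' each resample, and returns the percentile interval of the empirical
#' distribution. The default resampling unit is the observation (for
#' this package: the anchor--outcome pair); passing `cluster` switches
#' to a cluster bootstrap that resamples whole clusters (patients),
#' which respects within-patient correlation across pooled follow-ups.
#'
#' Resamples on which the statistic is undefined (error, `NA`, or
#' non-finite) are redrawn up to `max_redraw` times each; replicates
#' that stay undefined are dropped and counted, and the call fails if
#' more than 20\% of replicates end undefined.
#'
#' @param statistic Function taking a resampled data set (same type as
#'   `data`) and returning a single number.
#' @param data Vector or data frame to resample.
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param alpha Two-sided error rate (default 0.05).
#' @param seed Optional integer; the same seed always yields the same
#'   interval, and the caller's RNG stream is left untouched.
#' @param cluster Optional vector of cluster identifiers (same length
#'   as `data`) for a cluster bootstrap.
#' @param max_redraw Redraw cap per replicate for undefined statistics.
#' @return Numeric vector `c(low, high)` with attributes `replicates`
#'   (the replicate statistics), `n_undefined` and `n_redraws`.
#' @examples
#' x <- rnorm(100)
#' bootstrap_ci(mean, x, n_reps = 200, seed = 1)
#' @export
bootstrap_ci <- function(statistic, data, n_reps = 1000, alpha = 0.05,
                         seed = NULL, cluster = NULL, max_redraw = 10L) {
  stopifnot(is.function(statistic), n_reps >= 1)
  n <- data_size(data)
  if (n < 1L) stop("cannot bootstrap empty data", call. = FALSE)
  if (!is.null(cluster)) {
    stopifnot(length(cluster) == n)
    cl_ids <- unique(cluster)
    cl_rows <- split(seq_len(n), match(cluster, cl_ids))
  }
  draw_idx <- function() {
    if (is.null(cluster)) {
      sample.int(n, n, replace = TRUE)
    } else {
      k <- length(cl_rows)
      unlist(cl_rows[sample.int(k, k, replace = TRUE)], use.names = FALSE)
    }
  }
  eval_stat <- function(idx) {
    val <- tryCatch(statistic(resample_rows(data, idx)),
                    error = function(e) NA_real_)
    if (length(val) != 1L || !is.finite(val)) NA_real_ else as.numeric(val)
  }
  n_redraws <- 0L
  reps <- with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      val <- eval_stat(draw_idx())
      tries <- 0L
      while (is.na(val) && tries < max_redraw) {
        tries <- tries + 1L
        val <- eval_stat(draw_idx())
      }
      n_redraws <<- n_redraws + tries
      val
    }, numeric(1))
  })
  n_undef <- sum(is.na(reps))
  if (n_undef / n_reps > 0.2) {
    stop(sprintf(
      "bootstrap failed: statistic undefined on %.0f%% of %d replicates",
      100 * n_undef / n_reps, n_reps), call. = FALSE)
  }
  good <- reps[!is.na(reps)]
  ci <- unname(stats::quantile(good, c(alpha / 2, 1 - alpha / 2), type = 7))
  structure(ci, replicates = reps, n_undefined = n_undef,
            n_redraws = n_redraws)
}
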