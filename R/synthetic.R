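#' Configuration of the synthetic cohort generator
#'
#' Fully parameterises the latent-improvement model behind
#' [generate_cohort()], including the seed, so a configuration
#' reproduces its cohort exactly. Defaults emulate a base-of-thumb
#' osteoarthritis cohort treated by splinting then trapeziectomy: 50
#' patients, a baseline and five follow-ups, baseline score moments
#' matching such a population (NRS pain 6.5 (SD 1.7); PRWHE pain 34.2
#' (6.8); PRWHE function 30 (7.9); total = pain + function), and
#' anchors coupled to a latent recovery process.
#'
#' The latent model: each patient carries a recovery random effect;
#' the recovered fraction of the instrument range at follow-up `t` is
#' `f = recovery_curve[t] + patient effect + occasion noise`. Observed
#' follow-up scores are `clip(baseline - f * range + measurement
#' noise)`. The GRC anchor is driven by perceived change `10 * f +
#' anchor noise` cut at `grc_thresholds` (increasing, on the 0--10
#' perceived-change scale; the third threshold is the true MID in
#' tenths of the instrument range). The PASS anchor is a logistic in
#' the scaled symptom state with 50\% satisfaction at `pass_location`
#' (0--10 scale), so the true PASS is `pass_location / 10 * range`.
#'
#' @param n_patients Number of patients (default 50).
#' @param baseline_mean,baseline_sd Named vectors (nrs, prwhe_pain,
#'   prwhe_function) of baseline score moments.
#' @param baseline_cor Shared-severity correlation between instruments'
#'   baselines (default 0.35).
#' @param recovery_curve Named vector of mean recovered fractions of
#'   the instrument range at each follow-up.
#' @param patient_sd,occasion_sd SDs of the patient random effect and
#'   the per-occasion fluctuation of the recovered fraction.
#' @param noise_sd Named vector of measurement noise SDs (instrument
#'   units) added to follow-up scores.
#' @param grc_thresholds Four strictly increasing cut points on the
#'   0--10 perceived-change scale separating much worse / somewhat
#'   worse / unchanged / somewhat better / much better.
#' @param anchor_noise_sd SD of the anchor noise on the perceived
#'   change scale; 0 makes the GRC a deterministic function of true
#'   improvement.
#' @param pass_location,pass_scale Location (state score on the 0--10
#'   scale at 50\% satisfaction) and scale of the satisfaction
#'   logistic.
#' @param pass_nrs_weight Weight of the pain NRS state (vs the scaled
#'   PRWHE total) in the overall state driving satisfaction.
#' @param missing_rate Probability that any one score or anchor field
#'   of a follow-up record is missing (completely at random).
#' @param items If `TRUE`, also synthesise 15 PRWHE item responses
#'   consistent with the subscale scores.
#' @param seed Integer RNG seed.
#' @return List of class `synthetic_config`.
#' @seealso [generate_cohort()], [true_parameters()]
#' @export
synthetic_config <- function(
    n_patients = 50,
    baseline_mean = c(nrs = 6.5, prwhe_pain = 34.2, prwhe_function = 30),
    baseline_sd = c(nrs = 1.7, prwhe_pain = 6.8, prwhe_function = 7.9),
    baseline_cor = 0.35,
    recovery_curve = c(post_splint_6wk = 0.10, m3 = 0.25, m6 = 0.35,
                       m9 = 0.40, m12 = 0.45),
    patient_sd = 0.20,
    occasion_sd = 0.10,
    noise_sd = c(nrs = 1.0, prwhe_pain = 3.0, prwhe_function = 3.0),
    grc_thresholds = c(-5.5, -1.5, 2.5, 3.5),
    anchor_noise_sd = 0.8,
    pass_location = 2.5,
    pass_scale = 0.55,
    pass_nrs_weight = 0.6,
    missing_rate = 0,
    items = FALSE,
    seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              baseline_cor = baseline_cor, recovery_curve = recovery_curve,
              patient_sd = patient_sd, occasion_sd = occasion_sd,
              noise_sd = noise_sd, grc_thresholds = grc_thresholds,
              anchor_noise_sd = anchor_noise_sd,
              pass_location = pass_location, pass_scale = pass_scale,
              pass_nrs_weight = pass_nrs_weight,
              missing_rate = missing_rate, items = isTRUE(items),
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  need <- c("nrs", "prwhe_pain", "prwhe_function")
  if (cfg$n_patients < 1L) stop("n_patients must be >= 1", call. = FALSE)
  for (f in c("baseline_mean", "baseline_sd", "noise_sd")) {
    if (!all(need %in% names(cfg[[f]]))) {
      stop(f, " must name ", paste(need, collapse = ", "), call. = FALSE)
    }
  }
  if (!setequal(names(cfg$recovery_curve), followup_levels())) {
    stop("recovery_curve must name the five follow-up timepoints",
         call. = FALSE)
  }
  if (length(cfg$grc_thresholds) != 4L ||
      any(diff(cfg$grc_thresholds) <= 0)) {
    stop("grc_thresholds must be four strictly increasing cut points",
         call. = FALSE)
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  }
  if (cfg$anchor_noise_sd < 0 || cfg$pass_scale <= 0) {
    stop("anchor_noise_sd must be >= 0 and pass_scale > 0", call. = FALSE)
  }
  if (cfg$pass_nrs_weight < 0 || cfg$pass_nrs_weight > 1) {
    stop("pass_nrs_weight must be in [0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  patients:", x$n_patients, " seed:", x$seed, "\n")
  cat("  true MID (0-10 scale):", x$grc_thresholds[3L],
      " true PASS (0-10 scale):", x$pass_location, "\n")
  cat("  anchor noise sd:", x$anchor_noise_sd,
      " missing rate:", x$missing_rate, "\n")
  invisible(x)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Distribute an integer total over k items each bounded 0..10.
split_items <- function(total, k) {
  x <- integer(k)
  left <- as.integer(round(total))
  while (left > 0L) {
    open <- which(x < 10L)
    take <- open[sample.int(length(open), 1L)]
    add <- min(left, sample.int(3L, 1L), 10L - x[take])
    x[take] <- x[take] + add
    left <- left - add
  }
  x
}

#' Generate a reproducible synthetic PROM cohort
#'
#' Draws a cohort from the latent-improvement model described in
#' [synthetic_config()]: correlated baseline scores clipped to
#' instrument ranges (NRS rounded to integers, PRWHE pain to integers,
#' PRWHE function to half points), per-patient recovery trajectories,
#' noisy follow-up scores, a GRC anchor driven by true improvement plus
#' anchor noise (so the anchor is realistically imperfect), and a PASS
#' anchor drawn from a logistic in the observed symptom state. The
#' same configuration (including seed) always yields the identical
#' cohort.
#'
#' @param config A [synthetic_config()].
#' @return A validated [prom_cohort()].
#' @examples
#' coh <- generate_cohort(synthetic_config(n_patients = 10, seed = 42))
#' table(coh$timepoint)
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_synthetic_config(config)
  cfg <- config
  reg <- instrument_registry()
  rng <- stats::setNames(reg$range, reg$instrument)

  df <- with_seed(cfg$seed, {
    n <- cfg$n_patients
    # correlated baselines through a shared severity factor
    w <- sqrt(cfg$baseline_cor)
    z0 <- stats::rnorm(n)
    draw_base <- function(instr, lo, hi) {
      z <- w * z0 + sqrt(1 - cfg$baseline_cor) * stats::rnorm(n)
      clip(cfg$baseline_mean[[instr]] + cfg$baseline_sd[[instr]] * z, lo, hi)
    }
    b_nrs <- round(draw_base("nrs", 0, 10))
    b_pain <- round(draw_base("prwhe_pain", 0, 50))
    b_fn <- round(draw_base("prwhe_function", 0, 50) * 2) / 2

    b_p <- stats::rnorm(n, 0, cfg$patient_sd)  # patient recovery effect
    pid <- sprintf("P%05d", seq_len(n))

    # follow-up rows, vectorised over n patients x 5 timepoints
    tps <- followup_levels()
    m <- n * length(tps)
    pat <- rep(seq_len(n), times = length(tps))
    tp <- rep(tps, each = n)
    f <- cfg$recovery_curve[tp] + b_p[pat] + stats::rnorm(m, 0, cfg$occasion_sd)
    s_nrs <- round(clip(b_nrs[pat] - f * rng[["nrs"]] +
                          stats::rnorm(m, 0, cfg$noise_sd[["nrs"]]), 0, 10))
    s_pain <- round(clip(b_pain[pat] - f * rng[["prwhe_pain"]] +
                           stats::rnorm(m, 0, cfg$noise_sd[["prwhe_pain"]]),
                         0, 50))
    s_fn <- round(clip(b_fn[pat] - f * rng[["prwhe_function"]] +
                         stats::rnorm(m, 0, cfg$noise_sd[["prwhe_function"]]),
                       0, 50) * 2) / 2
    perceived <- 10 * f + stats::rnorm(m, 0, cfg$anchor_noise_sd)
    # bands (low to high perceived change): much_worse .. much_better
    grc <- 5L - findInterval(perceived, cfg$grc_thresholds)
    # overall state on the common 0-10 scale: pain NRS weighted against
    # the scaled PRWHE total (satisfaction tracks residual pain most)
    state10 <- cfg$pass_nrs_weight * s_nrs +
      (1 - cfg$pass_nrs_weight) * (s_pain + s_fn) / 10
    satisfied <- stats::runif(m) <
      stats::plogis((cfg$pass_location - state10) / cfg$pass_scale)

    df <- data.frame(
      patient_id = c(pid, pid[pat]),
      timepoint = c(rep("baseline", n), tp),
      nrs = c(b_nrs, s_nrs),
      prwhe_pain = c(b_pain, s_pain),
      prwhe_function = c(b_fn, s_fn),
      grc = c(rep(NA_integer_, n), grc),
      pass_satisfied = c(rep(NA, n), satisfied),
      stringsAsFactors = FALSE)
    ord <- order(match(df$patient_id, pid), match(df$timepoint, timepoint_levels()))
    df <- df[ord, , drop = FALSE]
    df$prwhe_total <- df$prwhe_pain + df$prwhe_function

    if (cfg$items) {
      items <- t(vapply(seq_len(nrow(df)), function(r) {
        c(split_items(df$prwhe_pain[r], 5L),
          split_items(as.integer(round(df$prwhe_function[r] * 2)), 10L))
      }, integer(15)))
      colnames(items) <- sprintf("prwhe_item_%02d", 1:15)
      df <- cbind(df, as.data.frame(items))
    }

    if (cfg$missing_rate > 0) {
      fu <- df$timepoint != "baseline"
      drop_field <- function(col) {
        hit <- fu & stats::runif(nrow(df)) < cfg$missing_rate
        df[[col]][hit] <<- NA
        hit
      }
      hit_score <- fu & stats::runif(nrow(df)) < cfg$missing_rate
      df$nrs[hit_score] <- NA
      hit_prwhe <- fu & stats::runif(nrow(df)) < cfg$missing_rate
      df$prwhe_pain[hit_prwhe] <- NA
      df$prwhe_function[hit_prwhe] <- NA
      df$prwhe_total[hit_prwhe] <- NA
      if (cfg$items) {
        for (col in sprintf("prwhe_item_%02d", 1:15)) df[[col]][hit_prwhe] <- NA
      }
      drop_field("grc")
      drop_field("pass_satisfied")
    }
    df
  })
  rownames(df) <- NULL
  prom_cohort(df)
}

#' Read / write a generator configuration as a flat key-value file
#'
#' One `key: value` pair per line; vector-valued keys use
#' comma-separated entries, named entries as `name=value` (for example
#' `recovery_curve: post_splint_6wk=0.10, m3=0.25, ...`). Lines
#' starting with `#` are comments. A bundled paper-regime
#' configuration ships at
#' `system.file("extdata", "paper_regime_config.txt", package = "midpass")`.
#'
#' @param path Path to a config file.
#' @return `read_synthetic_config()` returns a [synthetic_config()];
#'   `write_synthetic_config()` invisibly returns `path`.
#' @export
read_synthetic_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  args <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexpr(":", ln), invert = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1L])
    parts <- trimws(strsplit(kv[2L], ",", fixed = TRUE)[[1L]])
    named <- grepl("=", parts, fixed = TRUE)
    if (all(named) && length(parts)) {
      sp <- strsplit(parts, "=", fixed = TRUE)
      val <- stats::setNames(as.numeric(vapply(sp, `[`, "", 2L)),
                             trimws(vapply(sp, `[`, "", 1L)))
    } else {
      val <- parts
      if (key != "items") val <- as.numeric(val)
      else val <- as.logical(toupper(val))
    }
    args[[key]] <- val
  }
  do.call(synthetic_config, args)
}

#' @rdname read_synthetic_config
#' @param config A [synthetic_config()].
#' @export
write_synthetic_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  fmt <- function(v) {
    if (is.logical(v)) return(ifelse(v, "true", "false"))
    if (!is.null(names(v)) && any(nzchar(names(v)))) {
      paste(names(v), format(v, trim = TRUE, digits = 15), sep = "=",
            collapse = ", ")
    } else paste(format(v, trim = TRUE, digits = 15), collapse = ", ")
  }
  writeLines(c("# midpass synthetic cohort configuration",
               vapply(names(config), function(k) {
                 paste0(k, ": ", fmt(config[[k]]))
               }, "")), path)
  invisible(path)
}

#' Ground-truth thresholds implied by a generator configuration
#'
#' Reads back the generator's true MID (the perceived-change threshold
#' between "unchanged" and "somewhat better", mapped to each
#' instrument's change scale) and true PASS (the satisfaction logistic
#' location mapped to each state scale), for parameter-recovery tests.
#'
#' @param config A [synthetic_config()].
#' @return Data frame with `instrument`, `true_mid`, `true_pass`.
#' @examples
#' true_parameters(synthetic_config())
#' @export
true_parameters <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  reg <- instrument_registry()
  data.frame(instrument = reg$instrument,
             true_mid = config$grc_thresholds[3L] / 10 * reg$range,
             true_pass = config$pass_location / 10 * reg$range,
             stringsAsFactors = FALSE)
}
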