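#' Construct and validate a longitudinal PROM cohort table
#'
#' A cohort table holds one row per patient and timepoint with the NRS
#' pain score, the PRWHE subscale and total scores (optionally the 15
#' raw items), and -- at follow-ups only -- the two anchor responses:
#' the five-level global rating of change (`grc`) and the binary
#' acceptable-symptom-state question (`pass_satisfied`). Any further
#' columns are carried along untouched as covariates.
#'
#' Validation enforces score ranges, PRWHE additivity
#' (`prwhe_total = prwhe_pain + prwhe_function`), integer NRS values,
#' uniqueness of (patient, timepoint), and the rule that anchors may be
#' present only at follow-ups. Patients with follow-up rows but no
#' baseline row are flagged with a warning (they contribute no
#' anchor--outcome pairs). If raw items are present, subscales are
#' checked against [score_prwhe()] and a mismatch is flagged.
#'
#' @param data A data frame with columns `patient_id`, `timepoint`,
#'   `nrs`, `prwhe_pain`, `prwhe_function`, `prwhe_total`, optional
#'   `prwhe_item_01` .. `prwhe_item_15`, optional `grc` (codes 1--5 or
#'   labels) and `pass_satisfied` (yes/no, true/false, 1/0).
#' @return An object of class `prom_cohort` (a validated data frame
#'   with an instrument-registry attribute).
#' @seealso [read_cohort()], [build_pairs()], [generate_cohort()]
#' @export
prom_cohort <- function(data) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  required <- c("patient_id", "timepoint", "nrs", "prwhe_pain",
                "prwhe_function", "prwhe_total")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("cohort is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data$patient_id <- as.character(data$patient_id)
  data$timepoint <- as.character(data$timepoint)
  bad_tp <- which(!(data$timepoint %in% timepoint_levels()))
  if (length(bad_tp)) {
    stop("row ", bad_tp[1L], ": unknown timepoint '",
         data$timepoint[bad_tp[1L]], "'; expected one of ",
         paste(timepoint_levels(), collapse = ", "), call. = FALSE)
  }

  if ("grc" %in% names(data)) data$grc <- parse_grc(data$grc)
  else data$grc <- NA_integer_
  if ("pass_satisfied" %in% names(data)) {
    data$pass_satisfied <- parse_yes_no(data$pass_satisfied)
  } else data$pass_satisfied <- NA

  check_range <- function(col, lo, hi, integer = FALSE) {
    x <- data[[col]]
    bad <- which(!is.na(x) & (x < lo | x > hi))
    if (length(bad)) {
      stop("row ", bad[1L], ": ", col, " = ", x[bad[1L]],
           " outside [", lo, ", ", hi, "]", call. = FALSE)
    }
    if (integer) {
      bad <- which(!is.na(x) & x != round(x))
      if (length(bad)) {
        stop("row ", bad[1L], ": ", col, " = ", x[bad[1L]],
             " must be an integer", call. = FALSE)
      }
    }
  }
  check_range("nrs", 0, 10, integer = TRUE)
  check_range("prwhe_pain", 0, 50)
  check_range("prwhe_function", 0, 50)
  check_range("prwhe_total", 0, 100)

  ok <- !is.na(data$prwhe_pain) & !is.na(data$prwhe_function) &
    !is.na(data$prwhe_total)
  bad <- which(ok & abs(data$prwhe_total -
                          (data$prwhe_pain + data$prwhe_function)) > 1e-8)
  if (length(bad)) {
    stop("row ", bad[1L], ": prwhe_total (", data$prwhe_total[bad[1L]],
         ") != prwhe_pain + prwhe_function (",
         data$prwhe_pain[bad[1L]] + data$prwhe_function[bad[1L]], ")",
         call. = FALSE)
  }

  key <- paste(data$patient_id, data$timepoint, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("row ", dup[1L], ": duplicate record for patient '",
         data$patient_id[dup[1L]], "' at timepoint '",
         data$timepoint[dup[1L]], "'", call. = FALSE)
  }

  at_baseline <- data$timepoint == "baseline"
  bad <- which(at_baseline & (!is.na(data$grc) | !is.na(data$pass_satisfied)))
  if (length(bad)) {
    stop("row ", bad[1L], ": anchor responses (grc/pass_satisfied) are not ",
         "allowed at baseline", call. = FALSE)
  }

  item_cols <- sprintf("prwhe_item_%02d", 1:15)
  if (all(item_cols %in% names(data))) {
    items <- as.matrix(data[item_cols])
    have <- which(rowSums(is.na(items)) == 0 & !is.na(data$prwhe_pain) &
                    !is.na(data$prwhe_function))
    for (i in have) {
      sc <- score_prwhe(items[i, ])
      if (abs(sc[["pain"]] - data$prwhe_pain[i]) > 1e-8 ||
          abs(sc[["fn"]] - data$prwhe_function[i]) > 1e-8) {
        warning("row ", i, ": PRWHE subscales disagree with scores ",
                "recomputed from the 15 items", call. = FALSE)
      }
    }
  }

  no_baseline <- setdiff(unique(data$patient_id[!at_baseline]),
                         unique(data$patient_id[at_baseline]))
  if (length(no_baseline)) {
    warning("patient(s) without a baseline record: ",
            paste(no_baseline, collapse = ", "),
            " (their follow-ups yield no change scores)", call. = FALSE)
  }

  structure(data,
            instruments = instrument_registry(),
            flagged_no_baseline = no_baseline,
            class = c("prom_cohort", "data.frame"))
}

#' @export
print.prom_cohort <- function(x, ...) {
  n_pat <- length(unique(x$patient_id))
  cat("PROM cohort: ", n_pat, " patients, ", nrow(x), " records (",
      sum(x$timepoint != "baseline"), " follow-up)\n", sep = "")
  cat("Instruments: ", paste(attr(x, "instruments")$instrument, collapse = ", "),
      "\n", sep = "")
  cat("Anchors present: grc = ", sum(!is.na(x$grc)), ", pass_satisfied = ",
      sum(!is.na(x$pass_satisfied)), "\n", sep = "")
  invisible(x)
}

#' Read / write a cohort CSV
#'
#' The on-disk format is long-format CSV, one row per patient and
#' timepoint, with the header documented in [prom_cohort()]. `grc`
#' accepts integer codes 1--5 or the five text labels ("no change" is a
#' synonym of "unchanged"); `pass_satisfied` accepts yes/no, true/false
#' or 1/0; missing values are empty cells. Unknown columns are preserved
#' as covariates, and the round trip `write_cohort()` then
#' `read_cohort()` is lossless.
#'
#' @param path Path to a CSV file.
#' @return `read_cohort()` returns a validated [prom_cohort()];
#'   `write_cohort()` invisibly returns `path`.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  prom_cohort(df)
}

#' @rdname read_cohort
#' @param cohort A `prom_cohort` object.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "prom_cohort"))
  out <- as.data.frame(cohort)
  if ("pass_satisfied" %in% names(out)) {
    out$pass_satisfied <- ifelse(is.na(out$pass_satisfied), "",
                                 ifelse(out$pass_satisfied, "yes", "no"))
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Change score between baseline and follow-up
#'
#' Change is baseline minus follow-up, so positive change means
#' improvement on these lower-is-better instruments.
#'
#' @param baseline,followup Scores on the same instrument (vectorised).
#' @return `baseline - followup`.
#' @examples
#' compute_change(6.5, 4)   # 2.5, improvement
#' compute_change(3, 8)     # -5, deterioration
#' @export
compute_change <- function(baseline, followup) {
  if (any(is.na(baseline))) {
    stop("missing baseline score", call. = FALSE)
  }
  baseline - followup
}

#' Pool anchor--outcome pairs across follow-ups
#'
#' Builds one pair per (patient, follow-up timepoint) that has both a
#' non-missing score on the requested instrument and a non-missing GRC
#' anchor; each pair carries the change score (baseline minus
#' follow-up), the follow-up state score, the GRC and (if present) the
#' PASS anchor. Pairs missing a needed value are excluded and counted
#' in the `exclusions` attribute. Pooling across the five follow-ups is
#' the default; use `timepoints` to subset.
#'
#' @param cohort A [prom_cohort()].
#' @param instrument One of `"nrs"`, `"prwhe_total"`, `"prwhe_pain"`,
#'   `"prwhe_function"`.
#' @param timepoints Follow-up labels to include (default all five).
#' @param require_anchor Which anchor a row must carry to form a pair:
#'   `"grc"` (default, the MID analyses), `"pass"`, or `"either"`.
#' @return A data frame of class `anchor_pairs` with columns
#'   `patient_id`, `timepoint`, `instrument`, `baseline`, `state`,
#'   `change`, `grc`, `grc_label`, `pass_satisfied`; attributes
#'   `instrument` and `exclusions` (named counts).
#' @examples
#' coh <- generate_cohort(synthetic_config(n_patients = 10, seed = 1))
#' p <- build_pairs(coh, "nrs")
#' nrow(p); attr(p, "exclusions")
#' @export
build_pairs <- function(cohort, instrument,
                        timepoints = followup_levels(),
                        require_anchor = c("grc", "pass", "either")) {
  stopifnot(inherits(cohort, "prom_cohort"))
  require_anchor <- match.arg(require_anchor)
  info <- instrument_info(instrument)
  score_col <- switch(instrument,
                      nrs = "nrs", prwhe_total = "prwhe_total",
                      prwhe_pain = "prwhe_pain",
                      prwhe_function = "prwhe_function")
  bad_tp <- setdiff(timepoints, followup_levels())
  if (length(bad_tp)) {
    stop("not follow-up timepoint(s): ", paste(bad_tp, collapse = ", "),
         call. = FALSE)
  }

  empty <- data.frame(patient_id = character(), timepoint = character(),
                      instrument = character(), baseline = numeric(),
                      state = numeric(), change = numeric(),
                      grc = integer(), grc_label = character(),
                      pass_satisfied = logical(), stringsAsFactors = FALSE)
  excl <- c(missing_baseline = 0L, missing_score = 0L, missing_anchor = 0L)

  if (nrow(cohort) == 0L) {
    warning("empty cohort: no anchor-outcome pairs", call. = FALSE)
    return(structure(empty, instrument = instrument, exclusions = excl,
                     class = c("anchor_pairs", "data.frame")))
  }

  base <- cohort[cohort$timepoint == "baseline", c("patient_id", score_col)]
  base_score <- stats::setNames(base[[score_col]], base$patient_id)
  fu <- cohort[cohort$timepoint %in% timepoints, , drop = FALSE]

  has_base <- fu$patient_id %in% names(base_score) &
    !is.na(base_score[fu$patient_id])
  excl[["missing_baseline"]] <- sum(!has_base)
  fu <- fu[has_base, , drop = FALSE]

  has_score <- !is.na(fu[[score_col]])
  excl[["missing_score"]] <- sum(!has_score)
  fu <- fu[has_score, , drop = FALSE]

  has_anchor <- switch(require_anchor,
                       grc = !is.na(fu$grc),
                       pass = !is.na(fu$pass_satisfied),
                       either = !is.na(fu$grc) | !is.na(fu$pass_satisfied))
  excl[["missing_anchor"]] <- sum(!has_anchor)
  fu <- fu[has_anchor, , drop = FALSE]

  if (nrow(fu) == 0L) {
    warning("no usable anchor-outcome pairs for instrument '", instrument,
            "'", call. = FALSE)
    return(structure(empty, instrument = instrument, exclusions = excl,
                     class = c("anchor_pairs", "data.frame")))
  }

  b <- unname(base_score[fu$patient_id])
  pairs <- data.frame(
    patient_id = fu$patient_id,
    timepoint = fu$timepoint,
    instrument = instrument,
    baseline = b,
    state = fu[[score_col]],
    change = compute_change(b, fu[[score_col]]),
    grc = fu$grc,
    grc_label = grc_label(fu$grc),
    pass_satisfied = fu$pass_satisfied,
    stringsAsFactors = FALSE
  )
  rownames(pairs) <- NULL
  structure(pairs, instrument = instrument, exclusions = excl,
            range = info$range,
            class = c("anchor_pairs", "data.frame"))
}

#' @export
print.anchor_pairs <- function(x, ...) {
  cat("Anchor-outcome pairs: ", nrow(x), " pairs on '",
      attr(x, "instrument"), "' from ", length(unique(x$patient_id)),
      " patients\n", sep = "")
  excl <- attr(x, "exclusions")
  if (sum(excl)) {
    cat("Excluded: ", paste(names(excl), excl, sep = " = ", collapse = ", "),
        "\n", sep = "")
  }
  if (nrow(x)) {
    cat("GRC distribution:\n")
    print(table(factor(x$grc_label, levels = names(grc_levels()))))
  }
  invisible(x)
}
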