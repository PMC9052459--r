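#' Instrument registry
#'
#' The four patient-reported outcome instruments the package analyses:
#' the numerical rating scale for pain (NRS, integer 0--10) and the
#' Patient-Rated Wrist/Hand Evaluation (PRWHE) total score (0--100) with
#' its pain (0--50) and function (0--50) subscales. All four are scored
#' so that lower is better.
#'
#' @return A data frame with one row per instrument: `instrument`,
#'   `min`, `max`, `range`, `direction`, `integer_scale`.
#' @examples
#' instrument_registry()
#' @export
instrument_registry <- function() {
  data.frame(
    instrument = c("nrs", "prwhe_total", "prwhe_pain", "prwhe_function"),
    min = c(0, 0, 0, 0),
    max = c(10, 100, 50, 50),
    range = c(10, 100, 50, 50),
    direction = "lower_better",
    integer_scale = c(TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

instrument_info <- function(instrument) {
  reg <- instrument_registry()
  i <- match(instrument, reg$instrument)
  if (is.na(i)) {
    stop("unknown instrument '", instrument, "'; registered instruments: ",
         paste(reg$instrument, collapse = ", "), call. = FALSE)
  }
  reg[i, , drop = FALSE]
}

#' Global rating of change (GRC) levels
#'
#' Canonical labels of the five-step transition anchor, coded 1 (much
#' better) to 5 (much worse). "no_change" and "no change" are accepted
#' as synonyms of "unchanged" at parse time.
#'
#' @return Named integer vector mapping label to code.
#' @export
grc_levels <- function() {
  c(much_better = 1L, somewhat_better = 2L, unchanged = 3L,
    somewhat_worse = 4L, much_worse = 5L)
}

grc_label <- function(code) {
  names(grc_levels())[match(code, grc_levels())]
}

# Accepts integer codes 1-5, canonical labels, or synonyms; NA passes through.
parse_grc <- function(x) {
  lv <- grc_levels()
  out <- rep(NA_integer_, length(x))
  chr <- trimws(tolower(as.character(x)))
  chr[chr %in% c("", "na")] <- NA_character_
  num <- suppressWarnings(as.integer(chr))
  is_num <- !is.na(num)
  if (any(is_num & !(num %in% 1:5))) {
    stop("grc codes must be integers 1-5", call. = FALSE)
  }
  out[is_num] <- num[is_num]
  syn <- c("no_change" = "unchanged", "no change" = "unchanged",
           "same" = "unchanged")
  rest <- !is_num & !is.na(chr)
  lab <- chr[rest]
  lab <- gsub(" ", "_", lab)
  lab[lab %in% names(syn)] <- syn[lab[lab %in% names(syn)]]
  bad <- !(lab %in% names(lv))
  if (any(bad)) {
    stop("unrecognised grc label(s): ", paste(unique(lab[bad]), collapse = ", "),
         call. = FALSE)
  }
  out[rest] <- lv[lab]
  out
}

parse_yes_no <- function(x) {
  chr <- trimws(tolower(as.character(x)))
  chr[chr %in% c("", "na")] <- NA_character_
  out <- rep(NA, length(x))
  out[chr %in% c("yes", "true", "1", "y", "t")] <- TRUE
  out[chr %in% c("no", "false", "0", "n", "f")] <- FALSE
  bad <- !is.na(chr) & is.na(out)
  if (any(bad)) {
    stop("unrecognised yes/no value(s): ", paste(unique(chr[bad]), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Timepoint labels of the study design
#'
#' Baseline plus five follow-ups: after six weeks of pre-operative
#' splinting, and 3, 6, 9 and 12 months after surgery.
#'
#' @return Character vector of the six canonical labels in ordinal order
#'   (baseline first, ordinal index 0).
#' @export
timepoint_levels <- function() {
  c("baseline", "post_splint_6wk", "m3", "m6", "m9", "m12")
}

followup_levels <- function() timepoint_levels()[-1]
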