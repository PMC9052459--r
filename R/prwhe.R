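#' Score the PRWHE questionnaire
#'
#' The Patient-Rated Wrist/Hand Evaluation has 15 items rated 0--10.
#' Items 1--5 form the pain subscale (sum, 0--50); items 6--15 form the
#' function subscale (sum divided by two, 0--50, so half points occur);
#' the total is their sum (0--100). Lower scores are better.
#'
#' @param items Numeric vector of exactly 15 integers in 0--10.
#' @return Named numeric vector with components `pain`, `fn` and
#'   `total`.
#' @examples
#' score_prwhe(rep(10, 15))        # worst possible: 50, 50, 100
#' score_prwhe(c(rep(4, 5), rep(3, 10)))
#' @export
score_prwhe <- function(items) {
  if (length(items) != 15L) {
    stop("PRWHE requires exactly 15 items, got ", length(items), call. = FALSE)
  }
  bad <- which(is.na(items) | items != round(items) | items < 0 | items > 10)
  if (length(bad)) {
    stop("PRWHE item ", bad[1L], " is invalid (", items[bad[1L]],
         "); items must be integers in [0, 10]", call. = FALSE)
  }
  pain <- sum(items[1:5])
  fn <- sum(items[6:15]) / 2
  c(pain = pain, fn = fn, total = pain + fn)
}
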