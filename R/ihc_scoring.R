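#' Convert a stained-cell percentage to a cellularity grade
#'
#' Banding: 0% maps to grade 0 (no stained cells), up to 33% is grade 1,
#' 34-65% grade 2, 66% and above grade 3. Fractional percentages falling
#' between the printed bands (33-34 and 65-66) are rounded half-up before
#' banding.
#'
#' @param percent stained-cell percentage(s) in \[0, 100\].
#' @return Integer grade(s) in 0:3.
#' @export
cellularity_grade <- function(percent) {
  if (any(!is.finite(percent)) || any(percent < 0) || any(percent > 100)) {
    stop("percent must lie in [0, 100]")
  }
  p <- floor(percent + 0.5)  # round half-up
  ifelse(percent == 0, 0L,
         ifelse(p <= 33, 1L,
                ifelse(p <= 65, 2L, 3L)))
}

#' Immunohistochemistry expression score
#'
#' The expression score is the product of the staining intensity grade
#' (0 none, 1 weak, 2 moderate, 3 strong) and the stained-cellularity
#' grade, giving values in \{0, 1, 2, 3, 4, 6, 9\}.
#'
#' @param intensity,cellularity integer grade(s) in 0:3 (vectors recycle
#'   as usual).
#' @return Integer score(s).
#' @export
expression_score <- function(intensity, cellularity) {
  check_grade <- function(g, what) {
    if (any(!is.finite(g)) || any(g != as.integer(g)) ||
        any(g < 0) || any(g > 3)) {
      stop(what, " grade must be an integer in 0..3")
    }
  }
  check_grade(intensity, "intensity")
  check_grade(cellularity, "cellularity")
  as.integer(intensity) * as.integer(cellularity)
}

#' Prevalence of positive staining
#'
#' Counts samples with expression score >= 1. Non-evaluable records
#' (acellular blocks, unscorable samples) are excluded from the
#' denominator by default; set `denominator = "all"` to count them in.
#'
#' @param observations data.frame with columns `score` (integer, NA
#'   allowed for non-evaluable rows) and `evaluable` (logical).
#' @param denominator `"evaluable"` (default) or `"all"`.
#' @return List with `positive`, `evaluable`, `total`, `fraction` (the
#'   positive count over the chosen denominator).
#' @export
prevalence <- function(observations, denominator = c("evaluable", "all")) {
  denominator <- match.arg(denominator)
  stopifnot(is.data.frame(observations),
            all(c("score", "evaluable") %in% names(observations)))
  if (nrow(observations) == 0L) stop("empty observation list")
  ev <- observations[observations$evaluable & !is.na(observations$score), ,
                     drop = FALSE]
  if (nrow(ev) == 0L) stop("no evaluable records")
  positive <- sum(ev$score >= 1)
  denom <- if (denominator == "evaluable") nrow(ev) else nrow(observations)
  list(positive = positive, evaluable = nrow(ev),
       total = nrow(observations), fraction = positive / denom)
}
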