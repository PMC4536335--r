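#' Fit a first-principal-component signature model
#'
#' Builds a PC1 signature over a gene set: each gene is centered and
#' scaled to unit variance across samples, and the loading vector w is
#' the first left singular vector of the standardized matrix — the unit
#' vector (sum w_i^2 = 1) maximizing the variance of the sample scores
#' sum w_i z_ij. Standardizing first (correlation-PCA) keeps loadings
#' comparable across genes measured on different intensity scales. The
#' sign of w is fixed by [fix_sign()] so that sum(w) >= 0, i.e. a high
#' score means high aggregate expression of the signature.
#'
#' @param expr numeric matrix restricted to the signature genes: genes in
#'   rows (rownames = IDs), samples in columns. Needs >= 2 genes and
#'   >= 3 samples. More genes than samples is fine (the decomposition
#'   works on the smaller dimension).
#' @return An object of class `signature_model`: list with `genes`,
#'   `weights` (unit norm), `center`, `scale`, `sign_convention`,
#'   `score_variance` (the largest eigenvalue of the gene-gene
#'   correlation matrix).
#' @export
fit_pc1 <- function(expr) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (is.null(rownames(expr))) stop("expr must have gene IDs as rownames")
  if (nrow(expr) < 2L) stop("need at least 2 genes")
  if (ncol(expr) < 3L) stop("need at least 3 samples")
  if (anyNA(expr)) stop("missing values not supported at fit time")

  ctr <- rowMeans(expr)
  scl <- apply(expr, 1L, stats::sd)
  degenerate <- scl == 0 | !is.finite(scl)
  if (any(degenerate)) {
    stop("zero-variance gene(s): ",
         paste(rownames(expr)[degenerate], collapse = ", "))
  }
  z <- (expr - ctr) / scl
  sv <- svd(z, nu = 1L, nv = 0L)
  w <- as.numeric(sv$u[, 1L])

  model <- structure(
    list(genes = rownames(expr),
         weights = w,
         center = as.numeric(ctr),
         scale = as.numeric(scl),
         sign_convention = "sum_nonneg",
         score_variance = sv$d[1L]^2 / (ncol(expr) - 1L)),
    class = "signature_model"
  )
  fix_sign(model)
}

#' Fix the arbitrary sign of a PC1 signature
#'
#' The direction of a principal component is arbitrary: negating both
#' loadings and scores (a 180-degree rotation) leaves the model
#' equivalent, and different software makes different choices. This
#' applies one fixed convention — the sum of loadings is non-negative —
#' so results are reproducible; downstream statistics (median-split
#' membership pattern, log-rank p) are invariant to the choice, only the
#' group labels swap.
#'
#' @param model a `signature_model`.
#' @return The model, with all weights negated iff their sum was negative.
#' @export
fix_sign <- function(model) {
  stopifnot(inherits(model, "signature_model"))
  if (sum(model$weights) < 0) model$weights <- -model$weights
  model
}

#' @export
print.signature_model <- function(x, ...) {
  cat("PC1 signature over", length(x$genes), "genes;",
      "score variance", signif(x$score_variance, 5), "\n")
  invisible(x)
}

#' Score samples with a signature model
#'
#' Computes the per-sample signature score sum w_i * (x_i - center_i) /
#' scale_i. Genes absent from the matrix, or missing in a given sample,
#' are dropped for that sample and the remaining weights renormalized to
#' unit Euclidean norm; a sample must retain at least 50% of the model's
#' genes.
#'
#' @param model a `signature_model`.
#' @param expr expression matrix (genes x samples) containing the model
#'   genes (at least half of them).
#' @return Named numeric vector of scores, one per column of `expr`.
#' @export
score_samples <- function(model, expr) {
  stopifnot(inherits(model, "signature_model"), is.matrix(expr))
  present <- model$genes %in% rownames(expr)
  if (sum(present) < length(model$genes) / 2) {
    stop("fewer than 50% of signature genes present; missing: ",
         paste(model$genes[!present], collapse = ", "))
  }
  idx <- which(present)
  z <- (expr[model$genes[idx], , drop = FALSE] - model$center[idx]) /
    model$scale[idx]
  w <- model$weights[idx]

  scores <- vapply(seq_len(ncol(z)), function(j) {
    ok <- is.finite(z[, j])
    if (sum(ok) < length(model$genes) / 2) {
      stop("sample ", colnames(z)[j], " has fewer than 50% of signature ",
           "genes observed")
    }
    wj <- w[ok]
    wj <- wj / sqrt(sum(wj^2))
    sum(wj * z[ok, j])
  }, numeric(1))
  stats::setNames(scores, colnames(expr))
}

#' Split samples at the median score
#'
#' Dichotomizes samples into low/high groups at the median score; samples
#' scoring exactly at the median go to the low group (a deterministic tie
#' rule). With distinct scores the group sizes differ by at most one.
#'
#' @param scores named numeric vector of at least 2 sample scores.
#' @return Named factor with levels `low`, `high`.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2L) stop("need at least 2 samples to split")
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (max(scores) == min(scores)) stop("degenerate split: all scores identical")
  med <- stats::median(scores)
  factor(ifelse(scores <= med, "low", "high"), levels = c("low", "high"))
}

#' Kaplan-Meier product-limit estimator
#'
#' Estimates the survival function S(t) = prod over event times t_j <= t
#' of (1 - d_j / n_j), where d_j deaths occur among n_j subjects at risk.
#' Censored subjects leave the risk set immediately after their censoring
#' time (so a censoring tied with an event is still at risk for it).
#'
#' @param records data.frame with columns `time` (>= 0) and `event`
#'   (1 = death observed, 0 = censored).
#' @return An object of class `km_curve`: data.frame with one row per
#'   distinct event time (`time`, `n_risk`, `n_event`, `surv`); S(0) = 1
#'   implicitly precedes the first row.
#' @export
km_estimate <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("time", "event") %in% names(records)))
  if (nrow(records) == 0L) stop("no survival records")
  if (any(!is.finite(records$time)) || any(records$time < 0)) {
    stop("times must be finite and non-negative")
  }
  if (!all(records$event %in% c(0, 1))) stop("event must be 0 or 1")

  ev_times <- sort(unique(records$time[records$event == 1]))
  n_risk <- vapply(ev_times, function(t) sum(records$time >= t), numeric(1))
  n_event <- vapply(ev_times, function(t) {
    sum(records$time == t & records$event == 1)
  }, numeric(1))
  surv <- cumprod(1 - n_event / n_risk)

  out <- data.frame(time = ev_times, n_risk = n_risk, n_event = n_event,
                    surv = surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' At each distinct event time the observed deaths in group A are compared
#' with their hypergeometric expectation given the pooled risk sets; the
#' standardized sum is referred to a chi-square distribution with one
#' degree of freedom. Tied event times are handled through the summed
#' hypergeometric mean and variance at each distinct time (no further tie
#' correction). The statistic is symmetric in group order.
#'
#' @param group_a,group_b data.frames with columns `time`, `event`.
#' @return List with `chisq`, `p`, `n` (per-group sizes), `events`
#'   (per-group observed events), `expected` (per-group expected events).
#' @export
logrank_test <- function(group_a, group_b) {
  for (g in list(group_a, group_b)) {
    stopifnot(is.data.frame(g), all(c("time", "event") %in% names(g)))
    if (nrow(g) == 0L) stop("both groups must be non-empty")
    if (any(!is.finite(g$time)) || any(g$time < 0)) {
      stop("times must be finite and non-negative")
    }
    if (!all(g$event %in% c(0, 1))) stop("event must be 0 or 1")
  }
  time <- c(group_a$time, group_b$time)
  event <- c(group_a$event, group_b$event)
  in_a <- rep(c(TRUE, FALSE), c(nrow(group_a), nrow(group_b)))
  if (sum(event) == 0) stop("no events in either group")

  ev_times <- sort(unique(time[event == 1]))
  o_a <- e_a <- v <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n_a <- sum(at_risk & in_a)
    d_t <- sum(time == t & event == 1)
    d_a <- sum(time == t & event == 1 & in_a)
    o_a <- o_a + d_a
    e_a <- e_a + d_t * n_a / n_t
    if (n_t > 1) {
      v <- v + d_t * (n_a / n_t) * (1 - n_a / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  chisq <- if (v > 0) (o_a - e_a)^2 / v else 0
  list(chisq = chisq,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       n = c(a = nrow(group_a), b = nrow(group_b)),
       events = c(a = sum(group_a$event), b = sum(group_b$event)),
       expected = c(a = e_a, b = sum(event) - e_a))
}
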