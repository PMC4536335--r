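#' Normalize raw plate signals to viability fractions
#'
#' Converts raw fluorescence (or absorbance) readings to viability expressed
#' as a fraction of the mean untreated-control signal on the same plate.
#' Replicates are retained as separate rows; values above 1 are kept
#' (affected-fraction clipping happens later, at fit time).
#'
#' @param raw_signals data.frame of treated wells with columns `sample`,
#'   `drug`, `dose`, `replicate`, `signal`, and optionally `plate`
#'   (defaults to a single plate `"plate1"`).
#' @param controls untreated-control signals: either a numeric vector
#'   (applied to every plate) or a data.frame with columns `plate`,
#'   `signal`.
#' @return A data.frame (the viability table) with columns `sample`,
#'   `drug`, `dose`, `replicate`, `viability`, `plate`.
#' @examples
#' wells <- data.frame(sample = "s1", drug = "drugA", dose = 1,
#'                     replicate = 1, signal = 5000)
#' normalize_viability(wells, controls = c(9000, 10000, 11000))
#' @export
normalize_viability <- function(raw_signals, controls) {
  stopifnot(is.data.frame(raw_signals))
  need <- c("sample", "drug", "dose", "replicate", "signal")
  miss <- setdiff(need, names(raw_signals))
  if (length(miss) > 0L) {
    stop("raw_signals missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(is.finite(raw_signals$dose)) || any(raw_signals$dose < 0)) {
    stop("doses must be finite and non-negative")
  }
  if (is.null(raw_signals$plate)) raw_signals$plate <- "plate1"

  if (is.numeric(controls)) {
    if (length(controls) == 0L) stop("invalid control: control group is empty")
    ctrl_means <- stats::setNames(
      rep(mean(controls), length(unique(raw_signals$plate))),
      unique(raw_signals$plate)
    )
  } else if (is.data.frame(controls)) {
    if (!all(c("plate", "signal") %in% names(controls))) {
      stop("controls data.frame needs columns plate, signal")
    }
    if (nrow(controls) == 0L) stop("invalid control: control group is empty")
    ctrl_means <- tapply(controls$signal, controls$plate, mean)
  } else {
    stop("controls must be a numeric vector or a data.frame")
  }

  absent <- setdiff(unique(raw_signals$plate), names(ctrl_means))
  if (length(absent) > 0L) {
    stop("missing untreated controls for plate(s): ",
         paste(absent, collapse = ", "))
  }
  bad <- names(ctrl_means)[!is.finite(ctrl_means) | ctrl_means <= 0]
  if (length(bad) > 0L) {
    stop("invalid control: non-positive control mean on plate(s): ",
         paste(bad, collapse = ", "))
  }

  out <- raw_signals[c("sample", "drug", "dose", "replicate", "plate")]
  out$viability <- raw_signals$signal / as.numeric(ctrl_means[raw_signals$plate])
  out[c("sample", "drug", "dose", "replicate", "viability", "plate")]
}

#' Fit the median-effect dose-effect model
#'
#' Fits the two-parameter median-effect law fa/fu = (D/Dm)^m by ordinary
#' least squares on the median-effect plot, i.e. the line through
#' (log10 D, log10(fa/fu)) where fa = 1 - viability and fu = 1 - fa.
#' The slope of that line is the sigmoidicity exponent m and the dose
#' intercept gives Dm = 10^(-intercept/m), the dose producing a 50%
#' effect (the model's IC50).
#'
#' Replicates are averaged per dose before clipping (set
#' `average_replicates = FALSE` for per-well fitting). Points whose
#' affected fraction falls outside `fa_clip` are excluded: log(fa/fu) is
#' undefined at fa = 0 or 1 and numerically unstable near the boundaries.
#'
#' @param points data.frame with columns `dose` (> 0) and `viability`
#'   (fraction of untreated control); an optional `replicate` column is
#'   ignored beyond averaging.
#' @param fa_clip length-2 numeric, points kept when
#'   `fa_clip[1] <= fa <= fa_clip[2]`. Default `c(0.01, 0.99)`.
#' @param average_replicates average viability per dose before fitting?
#' @return An object of class `medfit`: list with `Dm`, `m`, `n_used`,
#'   `r_squared`, `fa_clip`.
#' @examples
#' d <- c(0.5, 1, 2, 4, 8)
#' fa <- (d / 2)^1.5 / (1 + (d / 2)^1.5)
#' fit <- fit_median_effect(data.frame(dose = d, viability = 1 - fa))
#' fit$Dm   # 2
#' fit$m    # 1.5
#' @export
fit_median_effect <- function(points, fa_clip = c(0.01, 0.99),
                              average_replicates = TRUE) {
  stopifnot(is.data.frame(points),
            all(c("dose", "viability") %in% names(points)))
  if (any(!is.finite(points$dose)) || any(points$dose <= 0)) {
    stop("all doses must be finite and strictly positive")
  }
  if (any(!is.finite(points$viability)) || any(points$viability < 0)) {
    stop("viability must be finite and non-negative")
  }
  stopifnot(length(fa_clip) == 2L, fa_clip[1] > 0, fa_clip[2] < 1,
            fa_clip[1] < fa_clip[2])

  if (average_replicates) {
    v <- tapply(points$viability, points$dose, mean)
    dose <- as.numeric(names(v))
    viability <- as.numeric(v)
  } else {
    dose <- points$dose
    viability <- points$viability
  }

  fa <- 1 - viability
  keep <- fa >= fa_clip[1] & fa <= fa_clip[2]
  n_used <- sum(keep)
  if (n_used < 3L) {
    stop("insufficient points: ", n_used,
         " usable after clipping fa to [", fa_clip[1], ", ", fa_clip[2],
         "], need >= 3")
  }

  x <- log10(dose[keep])
  y <- log10(fa[keep] / (1 - fa[keep]))
  ls <- stats::lm.fit(cbind(1, x), y)
  intercept <- ls$coefficients[1]
  m <- as.numeric(ls$coefficients[2])
  if (!is.finite(m) || m <= 0) {
    stop("non-monotone dose-effect: median-effect slope m = ",
         format(m), " is not positive")
  }
  ss_res <- sum(ls$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot

  structure(
    list(Dm = as.numeric(10^(-intercept / m)), m = m, n_used = n_used,
         r_squared = min(max(r2, 0), 1), fa_clip = fa_clip),
    class = "medfit"
  )
}

#' @export
print.medfit <- function(x, ...) {
  cat("Median-effect fit: Dm =", signif(x$Dm, 6), " m =", signif(x$m, 6),
      " (n =", x$n_used, ", R^2 =", signif(x$r_squared, 4), ")\n")
  invisible(x)
}

#' Predict the affected fraction at a dose
#'
#' Inverts the median-effect law to fa = (D/Dm)^m / (1 + (D/Dm)^m).
#' At D = Dm this is exactly 0.5; at D = 0 it is 0.
#'
#' @param fit a `medfit` object (or any list with `Dm` and `m`).
#' @param dose non-negative dose(s).
#' @return Affected fraction(s) in \[0, 1).
#' @export
predict_fa <- function(fit, dose) {
  stopifnot(is.list(fit), is.numeric(fit$Dm), is.numeric(fit$m))
  if (any(!is.finite(dose)) || any(dose < 0)) {
    stop("dose must be finite and non-negative")
  }
  ratio <- (dose / fit$Dm)^fit$m
  ratio / (1 + ratio)
}

#' Dose producing a target affected fraction
#'
#' Solves the median-effect law for dose: Dx = Dm * (fa/(1-fa))^(1/m).
#' `predict_fa(fit, dose_for_effect(fit, fa))` round-trips to `fa`.
#'
#' @param fit a `medfit` object.
#' @param fa target affected fraction(s), strictly inside (0, 1).
#' @return Dose(s) Dx.
#' @export
dose_for_effect <- function(fit, fa) {
  stopifnot(is.list(fit), is.numeric(fit$Dm), is.numeric(fit$m))
  if (any(!is.finite(fa)) || any(fa <= 0) || any(fa >= 1)) {
    stop("effect level out of open interval (0, 1)")
  }
  fit$Dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Construct a median-effect fit from known parameters
#'
#' Convenience constructor for simulation and analytic work where Dm and m
#' are specified directly rather than estimated from data.
#'
#' @param Dm dose for 50% effect (> 0).
#' @param m sigmoidicity exponent (> 0).
#' @param n_used,r_squared bookkeeping fields, defaulting to exact-fit
#'   values.
#' @return A `medfit` object.
#' @export
median_effect_fit <- function(Dm, m, n_used = 3L, r_squared = 1) {
  stopifnot(is.numeric(Dm), length(Dm) == 1L, is.finite(Dm), Dm > 0,
            is.numeric(m), length(m) == 1L, is.finite(m), m > 0)
  structure(list(Dm = Dm, m = m, n_used = as.integer(n_used),
                 r_squared = r_squared, fa_clip = c(0.01, 0.99)),
            class = "medfit")
}
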