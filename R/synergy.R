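#' Bundle single-agent and mixture fits into a combination experiment
#'
#' A constant-ratio combination experiment consists of median-effect fits
#' for drug 1 alone, drug 2 alone, and their fixed-ratio mixture (mixture
#' dose expressed as total concentration), plus drug 1's fraction of the
#' total mixture dose.
#'
#' @param fit_a,fit_b,fit_combo `medfit` objects for drug 1, drug 2 and
#'   the mixture.
#' @param fraction_a drug 1's fraction of the total mixture dose, in (0, 1).
#' @return An object of class `combo_experiment`.
#' @export
combination_experiment <- function(fit_a, fit_b, fit_combo, fraction_a) {
  for (f in list(fit_a, fit_b, fit_combo)) {
    stopifnot(is.list(f), is.numeric(f$Dm), f$Dm > 0,
              is.numeric(f$m), f$m > 0)
  }
  stopifnot(is.numeric(fraction_a), length(fraction_a) == 1L,
            fraction_a > 0, fraction_a < 1)
  structure(list(fit_a = fit_a, fit_b = fit_b, fit_combo = fit_combo,
                 fraction_a = fraction_a),
            class = "combo_experiment")
}

#' Chou-Talalay combination index at an effect level
#'
#' Computes the combination index (CI) for mutually nonexclusive agents:
#' CI = (D)1/(Dx)1 + (D)2/(Dx)2 + (D)1(D)2/\[(Dx)1(Dx)2\], where (Dx)1
#' and (Dx)2 are the single-agent doses producing the effect level `fa`
#' alone, and (D)1, (D)2 are the component doses inside the iso-effective
#' mixture. CI below 1 indicates synergism, 1 additivity, above 1
#' antagonism.
#'
#' @param exp a `combo_experiment`.
#' @param fa effect level in (0, 1); default 0.5 (the IC50 level).
#' @param additive_band half-width of the additive classification band
#'   passed to [classify_ci()].
#' @return A one-row data.frame with `effect_level`, `ci`,
#'   `classification`.
#' @export
combination_index <- function(exp, fa = 0.5, additive_band = 0) {
  stopifnot(inherits(exp, "combo_experiment"))
  if (length(fa) != 1L || !is.finite(fa) || fa <= 0 || fa >= 1) {
    stop("effect level out of open interval (0, 1)")
  }
  dc <- dose_for_effect(exp$fit_combo, fa)
  d1 <- exp$fraction_a * dc
  d2 <- (1 - exp$fraction_a) * dc
  dx1 <- dose_for_effect(exp$fit_a, fa)
  dx2 <- dose_for_effect(exp$fit_b, fa)
  ci <- d1 / dx1 + d2 / dx2 + (d1 * d2) / (dx1 * dx2)
  data.frame(effect_level = fa, ci = ci,
             classification = classify_ci(ci, additive_band),
             stringsAsFactors = FALSE)
}

#' Classify a combination index value
#'
#' CI < 1 - band is synergism, |CI - 1| <= band is additive, CI > 1 + band
#' is antagonism. The default band of 0 applies the strict thresholds;
#' a positive band absorbs estimation noise around additivity.
#'
#' @param ci combination index value(s), > 0.
#' @param additive_band non-negative half-width of the additive band.
#' @return Character vector in `c("synergism", "additive", "antagonism")`.
#' @export
classify_ci <- function(ci, additive_band = 0) {
  if (any(!is.finite(ci)) || any(ci <= 0)) {
    stop("combination index must be finite and > 0")
  }
  stopifnot(is.numeric(additive_band), additive_band >= 0)
  ifelse(ci < 1 - additive_band, "synergism",
         ifelse(ci > 1 + additive_band, "antagonism", "additive"))
}

#' Combination index across a grid of effect levels
#'
#' Evaluates [combination_index()] at each requested effect level, in grid
#' order. Useful because a single summary CI (conventionally at fa = 0.5)
#' hides how the interaction varies with effect level unless the three
#' slopes coincide, in which case CI is constant in fa.
#'
#' @param exp a `combo_experiment`.
#' @param fa_grid non-empty numeric vector of effect levels in (0, 1).
#' @param additive_band passed through to [classify_ci()].
#' @return data.frame with one row per grid value.
#' @export
ci_curve <- function(exp, fa_grid, additive_band = 0) {
  if (length(fa_grid) == 0L) stop("effect-level grid is empty")
  out <- do.call(rbind, lapply(fa_grid, function(f) {
    combination_index(exp, f, additive_band)
  }))
  rownames(out) <- NULL
  out
}
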