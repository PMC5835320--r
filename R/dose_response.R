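# IC50 estimation from viability curves and degree-of-resistance ratios.
#
# The primary estimator is a four-parameter logistic (4PL) least-squares fit
# on log10 concentration, with the IC50 defined as the concentration at which
# fitted viability crosses 50% of the untreated control (an absolute
# crossing, not the curve midpoint, because viability is normalized to
# untreated controls). If the fit fails, a log-linear interpolation between
# the concentrations bracketing 50% is used; if viability never reaches 50%,
# the estimate is censored at the highest tested concentration.

#' Construct a dose-response curve
#'
#' @param concentrations Ascending positive concentrations in uM; at least 4
#'   distinct values.
#' @param viability Mean viability (fraction of untreated control, >= 0) per
#'   concentration.
#' @param replicate_sd Optional per-concentration replicate sd.
#' @return A list of class `"dose_response_curve"`.
#' @export
dose_response_curve <- function(concentrations, viability,
                                replicate_sd = NULL) {
  if (length(unique(concentrations)) < 4)
    stop("need at least 4 distinct concentrations")
  if (length(concentrations) != length(viability))
    stop("concentrations and viability lengths differ")
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (any(viability < 0)) stop("viability must be >= 0")
  ord <- order(concentrations)
  structure(list(concentrations = concentrations[ord],
                 viability = viability[ord],
                 replicate_sd = if (!is.null(replicate_sd)) replicate_sd[ord]),
            class = "dose_response_curve")
}

#' Aggregate a replicated viability table into a dose-response curve
#'
#' @param df Data frame with columns `concentration_uM` and `viability`
#'   (replicates are averaged per concentration).
#' @return A [dose_response_curve()].
#' @export
as_dose_response_curve <- function(df) {
  if (!all(c("concentration_uM", "viability") %in% names(df)))
    stop("need columns concentration_uM and viability")
  agg <- stats::aggregate(viability ~ concentration_uM, df,
                          function(x) c(m = mean(x), s = stats::sd(x)))
  dose_response_curve(agg$concentration_uM, agg$viability[, "m"],
                      agg$viability[, "s"])
}

#' Estimate the IC50 from a dose-response curve
#'
#' Fits `v = bottom + (top - bottom) / (1 + 10^(hill * (log10(c) - e)))` by
#' least squares (bottom constrained >= 0, top free near 1) and solves for
#' the 50%-of-control crossing. Falls back to log-linear interpolation
#' between the bracketing concentrations when the fit does not converge, and
#' returns a censored estimate (`"> max tested"`) when observed viability
#' never drops below 0.5.
#'
#' @param curve A [dose_response_curve()] (or a replicated viability data
#'   frame, which is aggregated first).
#' @return A list of class `"ic50_estimate"` with fields `ic50` (uM; `NA`
#'   when censored), `censored`, `censor_bound`, `method`
#'   (`"4PL"`, `"interpolation"` or `"censored"`), and `fit` (the nls object
#'   when available).
#' @export
fit_dose_response <- function(curve) {
  if (is.data.frame(curve)) curve <- as_dose_response_curve(curve)
  if (!inherits(curve, "dose_response_curve"))
    stop("curve must be a dose_response_curve")
  conc <- curve$concentrations
  v <- curve$viability
  rises <- diff(v) > 0.2
  if (any(rises))
    warning("viability rises by more than 0.2 between consecutive ",
            "concentrations; noisy or non-monotone curve")
  if (all(v > 0.5)) {
    return(structure(list(ic50 = NA_real_, censored = TRUE,
                          censor_bound = max(conc), method = "censored",
                          fit = NULL),
                     class = "ic50_estimate"))
  }
  lc <- log10(conc)
  e_interp <- tryCatch(log10(interpolate_ic50(conc, v)),
                       error = function(e) NA_real_)
  e_starts <- unique(c(if (is.finite(e_interp)) e_interp,
                       stats::median(lc)))
  fit <- NULL
  for (e0 in e_starts) {
    for (h0 in c(1, 2)) {
      fit <- tryCatch(minpack.lm::nlsLM(
        v ~ bottom + (top - bottom) / (1 + 10^(hill * (lc - e))),
        start = list(top = min(max(max(v), 0.5), 1.5),
                     bottom = min(max(0, min(v)), 0.49),
                     e = e0, hill = h0),
        lower = c(top = 0.5, bottom = 0, e = min(lc) - 3, hill = 0.1),
        upper = c(top = 1.5, bottom = 0.49, e = max(lc) + 3, hill = 10),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (!is.null(fit)) break
  }
  if (!is.null(fit)) {
    p <- as.list(stats::coef(fit))
    # absolute 50%-of-control crossing of the fitted curve
    if (p$top > 0.5 && p$bottom < 0.5) {
      ic50 <- 10^(p$e + log10((p$top - 0.5) / (0.5 - p$bottom)) / p$hill)
      if (is.finite(ic50) && ic50 > 0) {
        return(structure(list(ic50 = ic50, censored = FALSE,
                              censor_bound = NA_real_, method = "4PL",
                              fit = fit),
                         class = "ic50_estimate"))
      }
    }
  }
  structure(list(ic50 = interpolate_ic50(conc, v), censored = FALSE,
                 censor_bound = NA_real_, method = "interpolation",
                 fit = NULL),
            class = "ic50_estimate")
}

#' Log-linear interpolation of the 50% crossing
#'
#' The fallback estimator behind [fit_dose_response()]: linear
#' interpolation of viability against log10 concentration between the pair
#' of points bracketing 50% of control. Exposed so the closed form can be
#' used (and checked) directly on bracketing pairs.
#'
#' @param concentrations Positive concentrations in uM, ascending.
#' @param viability Viability fractions per concentration; must cross 0.5.
#' @return The interpolated IC50 in uM.
#' @export
interpolate_ic50 <- function(concentrations, viability) {
  ord <- order(concentrations)
  conc <- concentrations[ord]
  v <- viability[ord]
  lc <- log10(conc)
  below <- which(v < 0.5)
  above <- which(v >= 0.5)
  if (!length(below)) stop("viability never drops below 0.5; censored")
  if (!length(above) || !any(above < min(below))) return(min(conc))
  i <- max(above[above < min(below)])
  j <- min(below)
  frac <- (0.5 - v[i]) / (v[j] - v[i])
  10^(lc[i] + frac * (lc[j] - lc[i]))
}

#' @export
print.ic50_estimate <- function(x, ...) {
  if (x$censored) {
    cat("IC50 > ", format(x$censor_bound), " uM (censored)\n", sep = "")
  } else {
    cat("IC50 = ", format(signif(x$ic50, 4)), " uM (", x$method, ")\n",
        sep = "")
  }
  invisible(x)
}

# round half away from zero, the convention used for printed ratios
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Degree of resistance between a resistant line and its parental line
#'
#' The ratio IC50(resistant) / IC50(parental), rounded half-up to two
#' decimals. A ratio below 1 flags collateral sensitivity: the resistant
#' line is hypersensitive to the drug relative to its parent.
#'
#' @param ic50_resistant,ic50_parental Positive, non-censored IC50 values
#'   (uM), or [fit_dose_response()] estimates.
#' @param resistant_id,parental_id Optional cell-line labels.
#' @return A list of class `"resistance_ratio"` with fields `ratio`,
#'   `collateral_sensitive`, `resistant_id`, `parental_id`.
#' @export
resistance_ratio <- function(ic50_resistant, ic50_parental,
                             resistant_id = "resistant",
                             parental_id = "parental") {
  get_val <- function(x) {
    if (inherits(x, "ic50_estimate")) {
      if (x$censored)
        stop("censored IC50 estimate: report the ratio as a bound ",
             "(> censor limit / parental IC50) instead")
      x$ic50
    } else as.numeric(x)
  }
  a <- get_val(ic50_resistant)
  b <- get_val(ic50_parental)
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0)
    stop("IC50 values must be positive and finite")
  ratio <- round_half_up(a / b, 2)
  structure(list(ratio = ratio, collateral_sensitive = ratio < 1,
                 resistant_id = resistant_id, parental_id = parental_id),
            class = "resistance_ratio")
}

#' @export
print.resistance_ratio <- function(x, ...) {
  cat(sprintf("Degree of resistance %s vs %s: %.2f%s\n", x$resistant_id,
              x$parental_id, x$ratio,
              if (x$collateral_sensitive) " (collateral sensitive)" else ""))
  invisible(x)
}
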