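#' Normalize raw plate signal to percent viability and fraction affected
#'
#' Blank-corrected normalization against the vehicle (untreated)
#' control: `percent_viability = 100 * (raw - mean blank) /
#' (mean vehicle - mean blank)` and `fa = 1 - percent_viability / 100`,
#' clipped to `[0, 1]`. Signals above the vehicle mean (apparent
#' stimulation) clip to `fa = 0`; clip events are counted in the
#' `n_clipped` attribute.
#'
#' @param plate data.frame with columns `drug1_dose`, `drug2_dose`,
#'   `replicate`, `raw_signal` (doses in uM; zero allowed).
#' @param vehicle numeric vector of vehicle-well raw signals; by
#'   default the plate rows with both doses zero.
#' @param blank numeric vector of blank-well raw signals (default 0).
#' @return `plate` with `percent_viability` and `fa` columns added.
#' @export
normalize_viability <- function(plate, vehicle = NULL, blank = 0) {
  if (is.null(vehicle)) {
    vehicle <- plate$raw_signal[
      plate$drug1_dose == 0 & plate$drug2_dose == 0
    ]
  }
  if (length(vehicle) < 1L) stop("at least one vehicle well is required")
  mb <- mean(blank)
  mv <- mean(vehicle)
  if (mv <= mb) {
    stop("mean vehicle signal (", signif(mv, 4),
         ") does not exceed mean blank (", signif(mb, 4),
         "): uninterpretable plate")
  }
  plate$percent_viability <-
    100 * (plate$raw_signal - mb) / (mv - mb)
  fa <- 1 - plate$percent_viability / 100
  n_clipped <- sum(fa < 0 | fa > 1)
  plate$fa <- pmin(pmax(fa, 0), 1)
  attr(plate, "n_clipped") <- n_clipped
  plate
}

#' Fit the median-effect model to single-drug dose-effect data
#'
#' Chou-Talalay median-effect fit: ordinary least squares of
#' `y = log10(fa / (1 - fa))` on `x = log10(dose)`. The slope is the
#' sigmoidicity `m`; the median-effect dose is `Dm = 10^(-intercept/m)`
#' (the dose giving 50% effect, the model's IC50); `r` is the
#' correlation coefficient of the linearized fit. Points with `fa`
#' outside the open window `(fa_min, fa_max)` are excluded before
#' fitting — the logit transform diverges at 0 and 1 — and counted in
#' `n_excluded`. A non-positive slope is flagged as an invalid fit.
#'
#' @param dose vector of doses in uM (all > 0), or a data.frame with
#'   columns `dose` and `fa`.
#' @param fa fractions affected, same length as `dose`.
#' @param fa_min,fa_max usable-effect window (defaults 0.005, 0.995).
#' @return object of class `median_effect_fit`: list with `m`, `Dm`,
#'   `r`, `n_points`, `n_excluded`, `valid`.
#' @export
fit_median_effect <- function(dose, fa = NULL,
                              fa_min = 0.005, fa_max = 0.995) {
  if (is.data.frame(dose)) {
    fa <- dose$fa
    dose <- dose$dose
  }
  if (length(dose) != length(fa)) {
    stop("`dose` and `fa` must have equal length")
  }
  if (any(dose <= 0)) stop("all doses must be positive")
  usable <- fa > fa_min & fa < fa_max
  n_excluded <- sum(!usable)
  dose <- dose[usable]
  fa <- fa[usable]
  if (length(dose) < 2L) {
    stop("fewer than 2 usable points after the (fa_min, fa_max) ",
         "exclusion rule")
  }
  x <- log10(dose)
  y <- log10(fa / (1 - fa))
  fit <- lm(y ~ x)
  m <- unname(coef(fit)[2])
  b <- unname(coef(fit)[1])
  valid <- is.finite(m) && m > 0
  Dm <- if (valid) 10^(-b / m) else NA_real_
  if (!valid) {
    warning("invalid median-effect fit: slope = ", signif(m, 4),
            " (expected > 0)")
  }
  structure(
    list(
      m = m, Dm = Dm, r = cor(x, y),
      n_points = length(dose), n_excluded = n_excluded, valid = valid
    ),
    class = "median_effect_fit"
  )
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat("Median-effect fit: m =", signif(x$m, 4),
      " Dm =", signif(x$Dm, 4), "uM  r =", signif(x$r, 4),
      " (", x$n_points, "points,", x$n_excluded, "excluded)\n")
  if (!x$valid) cat("  ** invalid fit (non-positive slope) **\n")
  invisible(x)
}

#' Single-drug dose required for a given effect
#'
#' Inverts the median-effect equation:
#' `Dx = Dm * (fa / (1 - fa))^(1/m)`. At `fa = 0.5` this is `Dm`.
#'
#' @param fit a [fit_median_effect()] result (or any list with `m`,
#'   `Dm`).
#' @param fa fraction affected, strictly inside (0, 1); vectorized.
#' @return dose(s) in uM.
#' @export
dose_for_effect <- function(fit, fa) {
  if (any(fa <= 0 | fa >= 1)) {
    stop("`fa` must be strictly between 0 and 1 (dose is unbounded ",
         "at the endpoints)")
  }
  if (isFALSE(fit$valid)) stop("invalid median-effect fit")
  fit$Dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Combination index at measured combination points
#'
#' Chou-Talalay combination index in the mutually exclusive (two-term)
#' form: for a combination `(d1, d2)` producing effect `fa`,
#' `CI = d1/Dx1 + d2/Dx2`, where `Dx_i` is the single-drug dose of
#' drug i required for the same effect under its median-effect fit.
#' Interpretation is strict: `CI < 1` synergy, `CI = 1` additive,
#' `CI > 1` antagonism.
#'
#' @param fit1,fit2 single-drug [fit_median_effect()] results.
#' @param d1,d2 administered doses in uM (non-negative, `d1 + d2 > 0`);
#'   vectorized over points.
#' @param fa measured fraction affected per point, strictly in (0, 1).
#' @return data.frame with `d1`, `d2`, `fa`, `dx1`, `dx2`, `ci`,
#'   `interpretation`.
#' @export
combination_index <- function(fit1, fit2, d1, d2, fa) {
  if (any(d1 < 0 | d2 < 0) || any(d1 + d2 <= 0)) {
    stop("doses must be non-negative with d1 + d2 > 0")
  }
  dx1 <- dose_for_effect(fit1, fa)
  dx2 <- dose_for_effect(fit2, fa)
  ci <- d1 / dx1 + d2 / dx2
  data.frame(
    d1 = d1, d2 = d2, fa = fa, dx1 = dx1, dx2 = dx2, ci = ci,
    interpretation = ifelse(
      ci < 1, "synergy", ifelse(ci > 1, "antagonism", "additive")
    ),
    stringsAsFactors = FALSE
  )
}

#' Normalized isobologram coordinates
#'
#' Expresses each combination point as `(x, y) = (d1/Dx1, d2/Dx2)`, so
#' `x + y` equals the combination index and points below the additivity
#' diagonal `x + y = 1` are synergistic regardless of the effect level
#' at which they were measured.
#'
#' @param ci_results data.frame from [combination_index()].
#' @return data.frame with `x`, `y`, `fa`.
#' @export
normalized_isobologram <- function(ci_results) {
  data.frame(
    x = ci_results$d1 / ci_results$dx1,
    y = ci_results$d2 / ci_results$dx2,
    fa = ci_results$fa
  )
}

#' Paired Student's t-test with significance labels
#'
#' Classical paired t-test on the within-pair differences, with the
#' conventional star labels: `*` for p < 0.05, `**` for p < 0.01,
#' `***` for p < 0.001. Degenerate zero-variance differences are
#' handled by convention: all-zero differences give `t = 0, p = 1`;
#' constant nonzero differences give `p = 0` with an infinite t.
#'
#' @param a,b paired numeric vectors of equal length >= 2.
#' @return list with `t`, `p`, `label`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length")
  if (length(a) < 2L) stop("at least 2 pairs are required")
  d <- a - b
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      t <- 0
      p <- 1
    } else {
      t <- sign(mean(d)) * Inf
      p <- 0
    }
  } else {
    ht <- t.test(a, b, paired = TRUE)
    t <- unname(ht$statistic)
    p <- ht$p.value
  }
  label <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else ""
  list(t = t, p = p, label = label)
}

#' Mean and standard error per condition
#'
#' Replicate summary in the means +/- SE convention: per condition,
#' the mean and `SE = sd / sqrt(n)`; a single replicate yields `SE =
#' NA`.
#'
#' @param records data.frame of replicate measurements.
#' @param value name of the value column.
#' @param by character vector of condition-defining columns.
#' @return data.frame with the condition columns plus `n`, `mean`,
#'   `se`.
#' @export
summarize_replicates <- function(records, value, by) {
  key <- interaction(records[by], drop = TRUE, lex.order = TRUE)
  groups <- split(records, key)
  rows <- lapply(groups, function(g) {
    v <- g[[value]]
    cbind(
      g[1, by, drop = FALSE],
      data.frame(
        n = length(v),
        mean = mean(v),
        se = if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_
      )
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
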