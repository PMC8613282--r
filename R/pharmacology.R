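# Pharmacodynamics: caliper tumour volume, tumour growth inhibition (TGI),
# four-parameter logistic (4PL) dose-response fitting for IC50s, and
# Chou-Talalay median-effect / combination-index analysis.

#' Caliper tumour volume
#'
#' `V = (pi / 6) * L * W^2` with length `L` and width `W` in mm. If
#' `W > L` the dimensions are swapped with a warning (the formula assumes
#' the longer axis is the length).
#'
#' @param length_mm,width_mm caliper measurements in mm (vectors recycle).
#' @return volume(s) in mm^3.
#' @export
caliper_volume <- function(length_mm, width_mm) {
  if (any(length_mm <= 0) || any(width_mm <= 0)) {
    .fail("caliper_volume", "dimensions must be positive")
  }
  swap <- width_mm > length_mm
  if (any(swap)) {
    warning("caliper_volume: width > length; dimensions swapped", call. = FALSE)
    tmp <- length_mm[swap]
    length_mm[swap] <- width_mm[swap]
    width_mm[swap] <- tmp
  }
  (pi / 6) * length_mm * width_mm^2
}

#' Tumour growth inhibition (percent)
#'
#' Two-branch TGI: when the treated tumour grew (`TVt > TV0`),
#' `TGI = 100 * (1 - (TVt - TV0) / (CVt - CV0))`; when it regressed
#' (`TVt < TV0`), `TGI = 100 * (2 - TVt / TV0)`. At `TVt = TV0` both
#' formulas give 100 (stasis); complete regression (`TVt = 0`) gives 200.
#' The growth branch requires the control group to have grown
#' (`CVt > CV0`).
#'
#' @param tv0,tvt treated-group volume (mm^3) at study start / end.
#' @param cv0,cvt control-group volume (mm^3) at study start / end (only
#'   used on the growth branch).
#' @return TGI in percent.
#' @export
tgi <- function(tv0, tvt, cv0, cvt) {
  if (tv0 <= 0) .fail("tgi", "TV0 must be > 0")
  if (tvt < 0 || cv0 < 0 || cvt < 0) .fail("tgi", "volumes must be >= 0")
  if (tvt > tv0) {
    if (cvt <= cv0) {
      .fail("tgi", "growth branch undefined: control did not grow (CVt <= CV0)")
    }
    100 * (1 - (tvt - tv0) / (cvt - cv0))
  } else if (tvt < tv0) {
    100 * (2 - tvt / tv0)
  } else {
    100
  }
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `response = bottom + (top - bottom) / (1 + (dose / ic50)^hill)` by
#' Levenberg-Marquardt with multi-start initialisation over a grid of IC50
#' and hill-slope starting values; the best-converged start (lowest residual
#' sum of squares) is returned. The hill slope is unconstrained in sign.
#'
#' @param doses concentrations (> 0), >= 4 distinct values.
#' @param responses observed responses (e.g. viability), same length.
#' @return list of class `four_pl` with `bottom`, `top`, `ic50`, `hill`,
#'   `rss`, and `fitted(dose)` via [predict_4pl()].
#' @export
fit_4pl <- function(doses, responses) {
  if (length(doses) != length(responses)) .fail("fit_4pl", "doses and responses differ in length")
  if (any(doses <= 0)) .fail("fit_4pl", "doses must be positive")
  if (length(unique(doses)) < 4L) .fail("fit_4pl", "need >= 4 distinct doses")
  df <- data.frame(dose = doses, resp = responses)
  rng <- range(responses)
  span <- max(rng[2L] - rng[1L], 1e-8)
  starts <- expand.grid(
    ic50 = exp(seq(log(min(doses)), log(max(doses)), length.out = 5)),
    hill = c(-2, -1, 1, 2)
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        resp ~ bottom + (top - bottom) / (1 + (dose / ic50)^hill),
        data = df,
        start = list(bottom = rng[1L], top = rng[2L],
                     ic50 = starts$ic50[i], hill = starts$hill[i]),
        lower = c(bottom = -Inf, top = -Inf, ic50 = 1e-12, hill = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12 * span^2) {
        cf <- coef(fit)
        best <- list(bottom = unname(cf["bottom"]), top = unname(cf["top"]),
                     ic50 = unname(cf["ic50"]), hill = unname(cf["hill"]),
                     rss = rss)
      }
    }
  }
  if (is.null(best)) .fail("fit_4pl", "no start converged (%d attempted)", nrow(starts))
  # canonical orientation: report bottom < top, flipping the hill sign
  if (best$bottom > best$top) {
    best[c("bottom", "top")] <- best[c("top", "bottom")]
    best$hill <- -best$hill
  }
  structure(best, class = "four_pl")
}

#' Evaluate a 4PL curve
#'
#' @param fit a `four_pl` object (or list with `bottom`, `top`, `ic50`,
#'   `hill`).
#' @param dose concentrations at which to evaluate.
#' @return predicted responses.
#' @export
predict_4pl <- function(fit, dose) {
  fit$bottom + (fit$top - fit$bottom) / (1 + (dose / fit$ic50)^fit$hill)
}

#' Fit the median-effect (Chou-Talalay) model
#'
#' Linear regression of `log(fa / (1 - fa))` on `log(dose)` gives the
#' median-effect slope `m` and, from the intercept `-m * log(dm)`, the
#' median-effect dose `dm` (the dose producing 50% effect).
#'
#' @param doses concentrations (> 0), >= 2 distinct values.
#' @param fa affected fractions, strictly in (0, 1).
#' @return list of class `median_effect` with `dm` and `m`.
#' @export
fit_median_effect <- function(doses, fa) {
  if (length(doses) != length(fa)) .fail("fit_median_effect", "doses and fa differ in length")
  if (length(unique(doses)) < 2L) .fail("fit_median_effect", "need >= 2 distinct doses")
  if (any(doses <= 0)) .fail("fit_median_effect", "doses must be positive")
  if (any(fa <= 0 | fa >= 1)) {
    .fail("fit_median_effect", "affected fractions must be strictly inside (0, 1)")
  }
  y <- log(fa / (1 - fa))
  x <- log(doses)
  fit <- lm(y ~ x)
  m <- unname(coef(fit)[2L])
  dm <- exp(-unname(coef(fit)[1L]) / m)
  structure(list(dm = dm, m = m), class = "median_effect")
}

#' Clip affected fractions away from 0 and 1
#'
#' Viability-derived affected fractions (`fa = 1 - treated/control`) can hit
#' the boundary exactly; the logit transform is then undefined. Values are
#' clipped into `[eps, 1 - eps]` with a warning.
#'
#' @param fa numeric vector of affected fractions.
#' @param eps clip margin (default 1e-6).
#' @return clipped vector.
#' @export
clip_fa <- function(fa, eps = 1e-6) {
  if (any(fa <= 0 | fa >= 1)) {
    warning("clip_fa: affected fractions clipped away from {0, 1}", call. = FALSE)
  }
  pmin(pmax(fa, eps), 1 - eps)
}

#' Chou-Talalay combination index
#'
#' For agents with median-effect fits `fit1`, `fit2`, the dose of agent *i*
#' alone that would produce the combination's effect `fa_combo` is
#' `Dx_i = dm_i * (fa / (1 - fa))^(1 / m_i)`; the (mutually exclusive)
#' combination index is `CI = d1 / Dx1 + d2 / Dx2`. CI < 1 indicates
#' synergy, CI = 1 additivity, CI > 1 antagonism.
#'
#' @param d1,d2 doses of the two agents in the combination (>= 0, not both
#'   zero).
#' @param fit1,fit2 `median_effect` fits for the single agents.
#' @param fa_combo affected fraction observed for the combination, in (0, 1).
#' @return the combination index (numeric scalar).
#' @export
combination_index <- function(d1, d2, fit1, fit2, fa_combo) {
  if (fa_combo <= 0 || fa_combo >= 1) {
    .fail("combination_index", "fa_combo must be strictly inside (0, 1)")
  }
  if (d1 < 0 || d2 < 0 || (d1 == 0 && d2 == 0)) {
    .fail("combination_index", "doses must be >= 0 and not both zero")
  }
  dx <- function(fit) fit$dm * (fa_combo / (1 - fa_combo))^(1 / fit$m)
  d1 / dx(fit1) + d2 / dx(fit2)
}
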