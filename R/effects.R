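#' Absolute change versus counterfactual
#'
#' The contrast of the analysis' intervention terms at the evaluation
#' week: estimate \eqn{c^\top\beta} with the indicator entries of \eqn{c}
#' set to 1 and the elapsed-week entries at their evaluation-week values;
#' SE \eqn{\sqrt{c^\top\Sigma c}}; 95% CI as estimate \eqn{\pm} 1.96 SE.
#'
#' @param fit A [fit_cits()] result.
#' @param evaluation_week Week index; defaults to the spec's evaluation
#'   week. Must be at or after the first intervention term activates.
#'
#' @return One-row tibble: `estimate`, `se`, `conf.low`, `conf.high`.
#' @export
absolute_effect <- function(fit, evaluation_week = NULL) {
  stopifnot(inherits(fit, "cits_fit"))
  spec <- fit$spec
  evaluation_week <- evaluation_week %||% spec$evaluation_week
  first_active <- if (spec$analysis_id == 2) spec$implementation_week else spec$announcement_week
  if (evaluation_week < first_active) {
    abort("evaluation week precedes the first active interruption")
  }
  cvec <- effect_contrast(fit, evaluation_week)
  est <- sum(cvec * fit$coefficients)
  se <- sqrt(drop(t(cvec) %*% fit$vcov %*% cvec))
  tibble(
    estimate = est, se = se,
    conf.low = est - 1.96 * se, conf.high = est + 1.96 * se
  )
}

# contrast vector: observed design row minus counterfactual row at a week
effect_contrast <- function(fit, evaluation_week) {
  design <- fit$design
  i <- match(evaluation_week, design$week)
  if (is.na(i)) abort("evaluation week outside the fit window")
  terms <- setdiff(names(design), "week")
  a <- as.numeric(design[i, terms])
  names(a) <- terms
  b <- a
  b[intersect(attr(design, "intervention"), terms)] <- 0
  a - b
}

# observed and counterfactual prediction rows at a week
prediction_rows <- function(fit, evaluation_week) {
  design <- fit$design
  i <- match(evaluation_week, design$week)
  if (is.na(i)) abort("evaluation week outside the fit window")
  terms <- setdiff(names(design), "week")
  a <- as.numeric(design[i, terms])
  names(a) <- terms
  b <- a
  b[intersect(attr(design, "intervention"), terms)] <- 0
  list(observed = a, counterfactual = b)
}

#' Relative change versus counterfactual, delta-method CI
#'
#' The relative difference
#' \eqn{r = 100\,(\hat y_{obs} - \hat y_{cf})/\hat y_{cf}} between the
#' model prediction and the counterfactual prediction at the evaluation
#' week, both linear forms of \eqn{\beta}. Its variance uses the
#' first-order delta method with gradient
#' \eqn{\partial r/\partial\beta = 100\,(\hat y_{cf}\,a - \hat y_{obs}\,b)/\hat y_{cf}^2}
#' for prediction rows \eqn{a} (observed) and \eqn{b} (counterfactual);
#' the 95% CI is \eqn{r \pm 1.96\sqrt{g^\top\Sigma g}}.
#'
#' A counterfactual prediction at or below zero raises a condition of
#' class `levyeval_degenerate_counterfactual`; evaluate instead at
#' [last_positive_counterfactual_week()].
#'
#' @inheritParams absolute_effect
#' @return One-row tibble: `estimate` (percent), `se`, `conf.low`,
#'   `conf.high`, `counterfactual` (the prediction the change is relative
#'   to).
#' @export
relative_effect <- function(fit, evaluation_week = NULL) {
  stopifnot(inherits(fit, "cits_fit"))
  evaluation_week <- evaluation_week %||% fit$spec$evaluation_week
  rows <- prediction_rows(fit, evaluation_week)
  a <- rows$observed
  b <- rows$counterfactual
  y_obs <- sum(a * fit$coefficients)
  y_cf <- sum(b * fit$coefficients)
  if (y_cf <= 0) {
    abort(
      glue::glue(
        "counterfactual prediction at week {evaluation_week} is not positive ",
        "({round(y_cf, 2)}); use last_positive_counterfactual_week()"
      ),
      class = "levyeval_degenerate_counterfactual"
    )
  }
  r <- 100 * (y_obs - y_cf) / y_cf
  g <- 100 * (y_cf * a - y_obs * b) / y_cf^2
  se <- sqrt(drop(t(g) %*% fit$vcov %*% g))
  tibble(
    estimate = r, se = se,
    conf.low = r - 1.96 * se, conf.high = r + 1.96 * se,
    counterfactual = y_cf
  )
}

#' Last week with a positive counterfactual
#'
#' When a projected counterfactual crosses zero before the end of the
#' window (predicting negative purchasing), effects are evaluated at the
#' final week for which the counterfactual is still positive.
#'
#' @param cf A [weekly_series()] of counterfactual values.
#' @return The largest week index with value > 0.
#' @export
last_positive_counterfactual_week <- function(cf) {
  stopifnot(nrow(cf) > 0)
  pos <- cf$week[!is.na(cf$value) & cf$value > 0]
  if (length(pos) == 0) abort("counterfactual is never positive")
  max(pos)
}

#' Full effect estimate for one fitted model
#'
#' Combines [absolute_effect()] and [relative_effect()] at the spec's
#' evaluation week. If the counterfactual prediction there is not
#' positive, the evaluation week is moved back to
#' [last_positive_counterfactual_week()] and the estimate is flagged
#' degenerate.
#'
#' @param fit A [fit_cits()] result.
#' @return One-row tibble: category, measure, analysis_id,
#'   evaluation_week, absolute and relative estimates with 95% CIs, the
#'   counterfactual value, and `degenerate`.
#' @export
estimate_effect <- function(fit) {
  stopifnot(inherits(fit, "cits_fit"))
  week <- fit$spec$evaluation_week
  degenerate <- FALSE
  rel <- tryCatch(
    relative_effect(fit, week),
    levyeval_degenerate_counterfactual = function(cnd) NULL
  )
  if (is.null(rel)) {
    week <- last_positive_counterfactual_week(project_counterfactual(fit))
    degenerate <- TRUE
    rel <- relative_effect(fit, week)
  }
  abs_eff <- absolute_effect(fit, week)
  tibble(
    category = fit$outcome_label$category %||% NA_character_,
    measure = fit$outcome_label$measure %||% NA_character_,
    analysis_id = fit$spec$analysis_id,
    evaluation_week = week,
    absolute_change = abs_eff$estimate,
    absolute_se = abs_eff$se,
    absolute_conf.low = abs_eff$conf.low,
    absolute_conf.high = abs_eff$conf.high,
    relative_change_pct = rel$estimate,
    relative_conf.low = rel$conf.low,
    relative_conf.high = rel$conf.high,
    counterfactual_value = rel$counterfactual,
    degenerate = degenerate
  )
}

#' Convert a per-household value to per person
#'
#' Divides a per-household-per-week change by the mean household size
#' (2.4 people in the UK).
#'
#' @param value Per-household-per-week value(s).
#' @param household_size Mean people per household; must be positive.
#' @return `value / household_size`.
#' @examples
#' per_person(-8.0, 2.4) # -3.33 g per person per week
#' @export
per_person <- function(value, household_size = 2.4) {
  if (!is.numeric(household_size) || household_size <= 0) {
    abort("household_size must be positive")
  }
  value / household_size
}

#' Express a sugar change as an equivalent drink swap
#'
#' Translates a sugar change and a volume change (both per person per
#' week) into "replace X mL of a drink at the reference sugar
#' concentration with Y mL of a sugar-free alternative": the replaced
#' volume is `|sugar_change| / (concentration/100)` and the replacement
#' volume adds the net volume change.
#'
#' @param sugar_change Sugar change, g per person per week.
#' @param volume_change Volume change, mL per person per week.
#' @param reference_concentration Sugar concentration of the replaced
#'   drink, g/100 mL; must be positive.
#' @return Tibble with `replaced_volume` and `replacement_volume` (mL).
#' @examples
#' sugar_volume_equivalence(3.3, 79, 5) # 66 mL replaced by 145 mL
#' @export
sugar_volume_equivalence <- function(sugar_change, volume_change,
                                     reference_concentration) {
  if (!is.numeric(reference_concentration) || reference_concentration <= 0) {
    abort("reference_concentration must be positive")
  }
  replaced <- abs(sugar_change) / (reference_concentration / 100)
  tibble(
    replaced_volume = replaced,
    replacement_volume = replaced + volume_change
  )
}
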