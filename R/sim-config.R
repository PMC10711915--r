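#' Specify the weekly purchasing process of one category
#'
#' Describes the data-generating process for one category's weekly
#' per-household outcome (volume in mL, or mass in g for powders and
#' confectionery): a linear baseline trend, an annual sinusoid, additive
#' Christmas-period (week starting in December or January) and Easter-week
#' uplifts, level and slope changes switched on at the announcement and
#' implementation weeks, and noise -- a common AR(1) weekly disturbance
#' plus a between-household random intercept.
#'
#' At week \eqn{t} (1-based) with announcement week \eqn{t_A} and
#' implementation week \eqn{t_I}, the expected outcome is
#' \deqn{\mu(t) = \beta_0 + \beta_1 (t-1) + s\,\sin(2\pi (t-1)/52.18)
#'   + \gamma_X \mathbf{1}[\mathrm{Dec/Jan}] + \gamma_E \mathbf{1}[\mathrm{Easter}]
#'   + \lambda_A A_t + \delta_A (t-t_A) A_t + \lambda_I I_t + \delta_I (t-t_I) I_t}
#' with \eqn{A_t = \mathbf{1}[t \ge t_A]}, \eqn{I_t = \mathbf{1}[t \ge t_I]}.
#'
#' @param category_label One of [levy_category_labels()].
#' @param baseline_level Expected outcome per household in week 1 (>= 0).
#' @param weekly_trend Change per week in the same units.
#' @param seasonal_amplitude Peak deviation of the annual cycle.
#' @param christmas_uplift Additive effect for weeks starting in Dec/Jan.
#' @param easter_uplift Additive Easter-week effect; only confectionery may
#'   have a nonzero value.
#' @param announcement_level_change,announcement_slope_change Level/slope
#'   changes from the announcement week onwards.
#' @param implementation_level_change,implementation_slope_change Level/slope
#'   changes from the implementation week onwards.
#' @param noise_sd Marginal sd of the common AR(1) weekly disturbance (>= 0).
#' @param household_sd Sd of the per-household random intercept (>= 0).
#' @param ar1_coefficient Lag-1 autocorrelation of the weekly disturbance,
#'   in `[0, 1)`.
#' @param unit `"mL"` or `"g"`.
#'
#' @return A `category_spec` list.
#' @export
category_spec <- function(category_label,
                          baseline_level,
                          weekly_trend = 0,
                          seasonal_amplitude = 0,
                          christmas_uplift = 0,
                          easter_uplift = 0,
                          announcement_level_change = 0,
                          announcement_slope_change = 0,
                          implementation_level_change = 0,
                          implementation_slope_change = 0,
                          noise_sd = 0,
                          household_sd = 0,
                          ar1_coefficient = 0,
                          unit = c("mL", "g")) {
  unit <- arg_match(unit)
  category_label <- arg_match0(category_label, levy_category_labels())
  stopifnot(
    baseline_level >= 0, noise_sd >= 0, household_sd >= 0,
    ar1_coefficient >= 0, ar1_coefficient < 1
  )
  if (easter_uplift != 0 && category_label != "confectionery") {
    abort("easter_uplift must be 0 for categories other than confectionery")
  }
  structure(
    list(
      category_label = category_label,
      baseline_level = baseline_level,
      weekly_trend = weekly_trend,
      seasonal_amplitude = seasonal_amplitude,
      christmas_uplift = christmas_uplift,
      easter_uplift = easter_uplift,
      announcement_level_change = announcement_level_change,
      announcement_slope_change = announcement_slope_change,
      implementation_level_change = implementation_level_change,
      implementation_slope_change = implementation_slope_change,
      noise_sd = noise_sd,
      household_sd = household_sd,
      ar1_coefficient = ar1_coefficient,
      unit = unit
    ),
    class = "category_spec"
  )
}

#' Default category processes
#'
#' One [category_spec()] per analysis category, calibrated to the observed
#' scale of British household purchasing: baselines near the weighted
#' weekly means of each category over 2014--2016 (high tier ~900 mL,
#' no-levy bands ~800--1000 mL, milk-based ~3550 mL, toiletries ~120 mL,
#' confectionery ~310 g, ...), a steep pre-existing decline for high-tier
#' drinks, intervention level/slope changes of the sign and order of
#' magnitude the levy evaluation reported (high and low tiers falling after
#' implementation, no-levy bands rising), Christmas uplifts for drinks and
#' confectionery, an Easter uplift for confectionery only, and a flat,
#' season-free toiletries control. Weekly disturbances are AR(1) with
#' lag-1 correlation 0.5 and marginal sd around 3% of baseline;
#' between-household sds are around 40% of baseline.
#'
#' @return Named list of `category_spec` objects (names are the labels).
#' @export
default_category_specs <- function() {
  sp <- list(
    category_spec("high_tier", 950, -1.3, 40, 90, 0, 30, 0.2, -150, -0.4,
      noise_sd = 25, household_sd = 400, ar1_coefficient = 0.5
    ),
    category_spec("low_tier", 150, 0.10, 10, 15, 0, -10, -0.35, -15, -0.30,
      noise_sd = 8, household_sd = 60, ar1_coefficient = 0.5
    ),
    category_spec("no_levy_low_sugar", 780, -0.10, 40, 60, 0, 40, 0.8, 60, 1.0,
      noise_sd = 25, household_sd = 300, ar1_coefficient = 0.5
    ),
    category_spec("no_levy_zero_sugar", 1020, 0.30, 50, 60, 0, 30, 0.5, 60, 1.0,
      noise_sd = 30, household_sd = 400, ar1_coefficient = 0.5
    ),
    category_spec("bottled_water", 590, 0.50, 60, 0, 0, 0, 0, -60, -0.5,
      noise_sd = 20, household_sd = 250, ar1_coefficient = 0.5
    ),
    category_spec("exempt_milk_based", 3546, 0, 60, 80, 0, -50, 0, 70, 0,
      noise_sd = 40, household_sd = 800, ar1_coefficient = 0.5
    ),
    category_spec("exempt_juice", 516, -0.05, 20, 30, 0, 0, 0, 0, 0,
      noise_sd = 15, household_sd = 200, ar1_coefficient = 0.5
    ),
    category_spec("exempt_powder", 95, -0.02, 8, 10, 0, -3, 0, 5, 0,
      noise_sd = 4, household_sd = 30, ar1_coefficient = 0.5, unit = "g"
    ),
    category_spec("exempt_alcohol", 1874, 0, 100, 400, 0, 0, 0, -60, 0,
      noise_sd = 60, household_sd = 900, ar1_coefficient = 0.5
    ),
    category_spec("confectionery", 308, 0, 20, 120, 80, 0, 0, 0, 0,
      noise_sd = 12, household_sd = 150, ar1_coefficient = 0.5, unit = "g"
    ),
    category_spec("toiletries", 123, -0.01, 0, 0, 0, 0, 0, 0, 0,
      noise_sd = 5, household_sd = 40, ar1_coefficient = 0.3
    )
  )
  setNames(sp, vapply(sp, `[[`, "", "category_label"))
}

#' Simulation configuration
#'
#' Bundles everything [simulate_panel()] needs: the household count, the
#' study calendar, per-category processes (which must include the
#' `toiletries` control), the household weight distribution (lognormal with
#' mean 1), the within-category market share given to the small-manufacturer
#' product of each category, and the seed.
#'
#' @param n_households Number of panel households.
#' @param calendar A [study_calendar()].
#' @param category_specs Named list of [category_spec()]s; must include
#'   `toiletries`.
#' @param weight_sdlog Sdlog of the lognormal household weights (meanlog is
#'   set to `-weight_sdlog^2/2` so weights have mean 1). One weight is drawn
#'   per household and replicated across its panel weeks.
#' @param small_share Market share (0--1) of each category's
#'   small-manufacturer product; the remainder is split across the large
#'   manufacturers' products.
#' @param seed Integer seed; all randomness in the generator flows from it.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_households = 100L,
                       calendar = study_calendar(),
                       category_specs = default_category_specs(),
                       weight_sdlog = 0.5,
                       small_share = 0.02,
                       seed = 1L) {
  stopifnot(
    inherits(calendar, "levy_calendar"),
    n_households >= 1, weight_sdlog >= 0,
    small_share >= 0, small_share < 1
  )
  if (!all(vapply(category_specs, inherits, TRUE, "category_spec"))) {
    abort("category_specs must be a list of category_spec objects")
  }
  labels <- vapply(category_specs, `[[`, "", "category_label")
  if (anyDuplicated(labels)) abort("duplicate category labels in category_specs")
  names(category_specs) <- labels
  if (!"toiletries" %in% labels) {
    abort("category_specs must include the 'toiletries' control category")
  }
  structure(
    list(
      n_households = as.integer(n_households),
      calendar = calendar,
      category_specs = category_specs,
      weight_sdlog = weight_sdlog,
      small_share = small_share,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}
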