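#' Study configuration
#'
#' Options shared by [run_primary()], [run_secondary_combined()] and
#' [run_sensitivity()].
#'
#' @param control_category Category supplying the control series
#'   (`"toiletries"`); set `use_control = FALSE` for the uncontrolled
#'   variant instead of changing this.
#' @param use_control Include the control covariate.
#' @param analyses Which of the three analysis designs to run.
#' @param min_weekly_purchases,min_weekly_spend Household-week filters, see
#'   [filter_households()].
#' @param error_model `"hac"` or `"ar1"`, see [fit_cits()].
#' @param harmonics Annual harmonic pairs in the design.
#' @param easter_categories Categories whose design includes the
#'   Easter-week indicator.
#' @param small_thresholds Litres/year thresholds for the
#'   small-manufacturer sensitivity runs.
#' @param calendar Optional [study_calendar()]; defaults to the calendar
#'   carried by the simulated panel (or [study_calendar()] if absent).
#'
#' @return A `study_config` list.
#' @export
study_config <- function(control_category = "toiletries",
                         use_control = TRUE,
                         analyses = 1:3,
                         min_weekly_purchases = 6,
                         min_weekly_spend = 0,
                         error_model = "hac",
                         harmonics = 2,
                         easter_categories = "confectionery",
                         small_thresholds = c(1e6, 5e5),
                         calendar = NULL) {
  stopifnot(all(analyses %in% 1:3), all(small_thresholds > 0))
  structure(
    list(
      control_category = control_category,
      use_control = use_control,
      analyses = analyses,
      min_weekly_purchases = min_weekly_purchases,
      min_weekly_spend = min_weekly_spend,
      error_model = error_model,
      harmonics = harmonics,
      easter_categories = easter_categories,
      small_thresholds = small_thresholds,
      calendar = calendar
    ),
    class = "study_config"
  )
}

panel_calendar <- function(panel, config) {
  config$calendar %||% panel$truth$config$calendar %||% study_calendar()
}

# outcome grid: every analysable category x measure; sugar only where the
# category carries sugar data
outcome_grid <- function(products, control_category) {
  cats <- setdiff(
    unique(products$levy_category),
    c(control_category, "excluded")
  )
  vol <- tibble(category = cats, measure = "volume")
  sugar_cats <- setdiff(cats, .no_sugar_categories)
  bind_rows(vol, tibble(category = sugar_cats, measure = "sugar_mass")) |>
    arrange(category, measure)
}

# shared machinery: fit every series in `series_tbl` (list-column of
# weekly_series) under every requested analysis, collecting failures
fit_effect_table <- function(series_tbl, control_series, config, calendar) {
  grid <- dplyr::cross_join(series_tbl, tibble(analysis_id = config$analyses))
  results <- purrr::pmap(grid, function(category, measure, series, analysis_id, easter) {
    tryCatch(
      {
        spec <- interruption_spec(analysis_id, calendar)
        ctrl <- if (config$use_control) control_series else NULL
        design <- build_design(spec,
          control_series = ctrl,
          harmonics = config$harmonics, easter = easter
        )
        estimate_effect(fit_cits(series, design, error_model = config$error_model))
      },
      error = function(e) {
        tibble(
          category = category, measure = measure, analysis_id = analysis_id,
          error = conditionMessage(e)
        )
      }
    )
  })
  ok <- purrr::map_lgl(results, ~ !"error" %in% names(.x))
  effects <- bind_rows(results[ok])
  failures <- bind_rows(results[!ok])
  structure(effects, failures = failures)
}

#' Run the primary category-specific analysis
#'
#' For every analysable category and applicable measure (volume for all;
#' sugar except for alcohol, zero-sugar drinks, bottled water), fits the
#' controlled interrupted time series model under each requested analysis
#' design and returns one effect estimate per category x measure x
#' analysis. Per-series failures are collected, not fatal; retrieve them
#' with `attr(result, "failures")`.
#'
#' @param panel A `levy_panel` (or a list with `purchases`, `products`,
#'   `weights`).
#' @param config A [study_config()].
#' @return Tibble of [estimate_effect()] rows, with a `failures`
#'   attribute.
#' @export
run_primary <- function(panel, config = study_config()) {
  calendar <- panel_calendar(panel, config)
  products <- if ("levy_category" %in% names(panel$products)) {
    panel$products
  } else {
    assign_category(panel$products)
  }
  purchases <- filter_households(
    panel$purchases,
    min_weekly_purchases = config$min_weekly_purchases,
    min_weekly_spend = config$min_weekly_spend
  )
  control_series <- weekly_weighted_mean(
    purchases, products, panel$weights, config$control_category, "volume"
  )
  series_tbl <- outcome_grid(products, config$control_category) |>
    mutate(
      series = purrr::map2(
        category, measure,
        ~ weekly_weighted_mean(purchases, products, panel$weights, .x, .y)
      ),
      easter = category %in% config$easter_categories
    )
  fit_effect_table(series_tbl, control_series, config, calendar)
}

# combined groupings used by the secondary analysis
.combined_groups <- list(
  all_soft_drinks = c(
    "high_tier", "low_tier", "no_levy_low_sugar", "no_levy_zero_sugar",
    "bottled_water", "exempt_milk_based", "exempt_juice", "exempt_powder"
  ),
  levy_liable = c(
    "high_tier", "low_tier", "no_levy_low_sugar", "no_levy_zero_sugar"
  )
)

#' Run the combined-category secondary analysis
#'
#' Builds combined series -- all soft drinks irrespective of levy
#' eligibility, levy-liable drinks only, and sugar-band groupings of all
#' soft drinks by the levy-tier thresholds irrespective of eligibility --
#' and fits the same models as [run_primary()] to each. Combined volume
#' totals add gram-denominated powders to millilitres (mL-equivalent).
#'
#' @inheritParams run_primary
#' @return Tibble of effect estimates with a `failures` attribute.
#' @export
run_secondary_combined <- function(panel, config = study_config()) {
  calendar <- panel_calendar(panel, config)
  products <- if ("levy_category" %in% names(panel$products)) {
    panel$products
  } else {
    assign_category(panel$products)
  }
  purchases <- filter_households(
    panel$purchases,
    min_weekly_purchases = config$min_weekly_purchases,
    min_weekly_spend = config$min_weekly_spend
  )
  control_series <- weekly_weighted_mean(
    purchases, products, panel$weights, config$control_category, "volume"
  )
  present <- unique(products$levy_category)

  one_group <- function(label, members, measure) {
    members <- intersect(members, present)
    if (measure == "sugar_mass") {
      members <- setdiff(members, .no_sugar_categories)
    }
    if (length(members) == 0) {
      return(NULL)
    }
    series <- purrr::map(
      members,
      ~ weekly_weighted_mean(purchases, products, panel$weights, .x, measure)
    )
    tibble(
      category = label, measure = measure,
      series = list(combine_categories(series, label)), easter = FALSE
    )
  }

  # sugar bands over soft drinks (everything except alcohol, confectionery,
  # toiletries, excluded), irrespective of levy eligibility
  soft <- products |>
    filter(!levy_category %in% c(
      "exempt_alcohol", "confectionery", "toiletries", "excluded"
    )) |>
    mutate(band = case_when(
      !is.na(sugar_g_per_100ml) & sugar_g_per_100ml >= 8 ~ "band_high_sugar",
      !is.na(sugar_g_per_100ml) & sugar_g_per_100ml >= 5 ~ "band_mid_sugar",
      TRUE ~ "band_low_sugar"
    ))
  one_band <- function(band_label, measure) {
    sub <- filter(soft, band == band_label)
    if (nrow(sub) == 0) {
      return(NULL)
    }
    if (measure == "sugar_mass" &&
      all(tidyr::replace_na(sub$sugar_g_per_100ml, 0) == 0)) {
      return(NULL)
    }
    tibble(
      category = band_label, measure = measure,
      series = list(weekly_weighted_mean(
        purchases, soft, panel$weights, band_label, measure,
        category_col = "band"
      )),
      easter = FALSE
    )
  }

  parts <- c(
    unname(purrr::imap(.combined_groups, function(members, label) {
      bind_rows(
        one_group(label, members, "volume"),
        one_group(label, members, "sugar_mass")
      )
    })),
    purrr::map(
      unique(soft$band),
      ~ bind_rows(one_band(.x, "volume"), one_band(.x, "sugar_mass"))
    )
  )
  series_tbl <- bind_rows(parts)
  fit_effect_table(series_tbl, control_series, config, calendar)
}

#' Run the sensitivity analyses
#'
#' Re-runs the primary analysis (i) excluding all purchases from
#' manufacturers whose estimated mean annual levy-liable volume falls
#' below each threshold, and (ii) without the control covariate, then
#' reports sign-and-significance concordance of each variant against the
#' primary run.
#'
#' @inheritParams run_primary
#' @param primary Optional precomputed [run_primary()] result (recomputed
#'   otherwise).
#' @return List with one effects table per variant
#'   (`small_<threshold>`, `uncontrolled`), the `primary` table, and
#'   `concordance`, a tibble of per-variant comparisons from
#'   [concordance_report()].
#' @export
run_sensitivity <- function(panel, config = study_config(), primary = NULL) {
  primary <- primary %||% run_primary(panel, config)
  products <- if ("levy_category" %in% names(panel$products)) {
    panel$products
  } else {
    assign_category(panel$products)
  }

  variants <- list()
  for (thr in config$small_thresholds) {
    flags <- small_manufacturer_flags(panel$purchases, products, thr)
    small_ids <- flags$manufacturer_id[flags$small]
    # the exemption concerns levy-liable drinks: only those products of a
    # small manufacturer are excluded (its exempt/control products stay)
    drop_products <- products$product_id[
      products$manufacturer_id %in% small_ids &
        products$levy_category %in% levy_liable_labels()
    ]
    reduced <- panel
    reduced$purchases <- filter(panel$purchases, !product_id %in% drop_products)
    reduced$products <- filter(products, !product_id %in% drop_products)
    variants[[paste0("small_", format(thr, scientific = FALSE))]] <-
      run_primary(reduced, config)
  }
  uncontrolled_config <- config
  uncontrolled_config$use_control <- FALSE
  variants$uncontrolled <- run_primary(panel, uncontrolled_config)

  concordance <- purrr::imap(
    variants,
    ~ mutate(concordance_report(primary, .x), variant = .y, .before = 1)
  ) |> bind_rows()
  c(variants, list(primary = primary, concordance = concordance))
}

#' Concordance of two effects tables
#'
#' Joins two effects tables on category, measure and analysis and compares
#' the sign of the absolute change and its "statistical significance"
#' (95% CI excluding 0). A pure function of the two tables.
#'
#' @param primary,alternative Effects tables from [run_primary()].
#' @return Tibble with per-row `same_sign`, `same_significance`,
#'   `concordant`.
#' @export
concordance_report <- function(primary, alternative) {
  sig <- function(lo, hi) lo > 0 | hi < 0
  inner_join(
    select(primary,
      category, measure, analysis_id,
      est_primary = absolute_change,
      lo_primary = absolute_conf.low, hi_primary = absolute_conf.high
    ),
    select(alternative,
      category, measure, analysis_id,
      est_alt = absolute_change,
      lo_alt = absolute_conf.low, hi_alt = absolute_conf.high
    ),
    by = c("category", "measure", "analysis_id")
  ) |>
    mutate(
      same_sign = sign(est_primary) == sign(est_alt),
      same_significance =
        sig(lo_primary, hi_primary) == sig(lo_alt, hi_alt),
      concordant = same_sign & same_significance
    )
}
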