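#' Filter out low-activity household-weeks
#'
#' Mirrors the panel provider's exclusion rule: a household-week is dropped
#' when it records fewer than `min_weekly_purchases` purchase events or a
#' weekly spend below `min_weekly_spend`. The real spend minimum is
#' undisclosed, so it defaults to 0 (no spend filtering).
#'
#' @param purchases Purchase events with `household_id` and
#'   `week_start_date` (and `spend` if a spend threshold is used).
#' @param min_weekly_purchases Minimum events per household-week (default 6).
#' @param min_weekly_spend Minimum weekly spend (default 0).
#'
#' @return The retained events, with the dropped household-weeks attached
#'   as the `"exclusions"` attribute (see [exclusion_log()]).
#' @export
filter_households <- function(purchases, min_weekly_purchases = 6,
                              min_weekly_spend = 0) {
  stopifnot(min_weekly_purchases >= 0, min_weekly_spend >= 0)
  purchases <- as_tibble(purchases)
  hw <- purchases |>
    group_by(household_id, week_start_date) |>
    summarise(
      n_purchases = n(),
      spend = if ("spend" %in% names(purchases)) sum(spend) else NA_real_,
      .groups = "drop"
    )
  excluded <- hw |>
    filter(
      n_purchases < min_weekly_purchases |
        (!is.na(spend) & spend < min_weekly_spend)
    )
  out <- anti_join(purchases, excluded, by = c("household_id", "week_start_date"))
  attr(out, "exclusions") <- excluded
  out
}

#' @rdname filter_households
#' @param filtered A tibble returned by `filter_households()`.
#' @export
exclusion_log <- function(filtered) {
  attr(filtered, "exclusions") %||% tibble(
    household_id = character(), week_start_date = as.Date(character()),
    n_purchases = integer(), spend = double()
  )
}

#' Construct a weekly series
#'
#' Low-level constructor for the weekly per-household mean series the
#' modelling functions consume. Weeks must be strictly increasing and
#' equally spaced 7 days apart; values must be finite (or NA for weeks
#' with an empty panel).
#'
#' @param week_start_date Dates, 7 days apart.
#' @param value Weighted mean outcome per household per week.
#' @param category,measure Labels; `measure` is `"volume"` or `"sugar_mass"`.
#' @param n_households Panel size per week (defaults to NA).
#' @param week Week indices (defaults to 1..n).
#' @return A `weekly_series` tibble.
#' @export
weekly_series <- function(week_start_date, value, category = "series",
                          measure = c("volume", "sugar_mass"),
                          n_households = NA_integer_, week = NULL) {
  measure <- arg_match(measure)
  week_start_date <- as.Date(week_start_date)
  d <- diff(as.numeric(week_start_date))
  if (length(d) && !all(d == 7)) {
    abort("weeks must be strictly increasing and equally spaced (7 days)")
  }
  if (any(!is.finite(value) & !is.na(value))) abort("values must be finite or NA")
  out <- tibble(
    week = week %||% seq_along(week_start_date),
    week_start_date = week_start_date,
    category = category,
    measure = measure,
    value = as.numeric(value),
    n_households = as.integer(n_households)
  )
  class(out) <- c("weekly_series", class(out))
  out
}

# categories for which no sugar series is defined: alcohol carries no sugar
# data on labels, the rest contain no sugar at all
.no_sugar_categories <- c(
  "exempt_alcohol", "no_levy_zero_sugar", "bottled_water", "toiletries"
)

#' Weekly weighted mean purchases per household
#'
#' Reduces purchase events to one weekly value per category: each
#' household's total category quantity that week (volume, or sugar mass
#' \eqn{\sum \mathrm{quantity} \times \mathrm{sugar}/100}), averaged over
#' the panel with the household weights, \eqn{\sum_h w_h x_h / \sum_h w_h}.
#' Panel membership comes from the weights table: a household-week present
#' there contributes \eqn{x_h = 0} if it bought nothing in the category, so
#' non-consumers dilute the mean as in the source data.
#'
#' @param purchases Purchase events (`household_id`, `week`, `product_id`,
#'   `quantity`).
#' @param products Catalogue; classified on the fly if it has no category
#'   column.
#' @param weights Panel weights (`household_id`, `week`, `weight`), also
#'   defining who is in the panel each week.
#' @param category_label The category to aggregate.
#' @param measure `"volume"` (or mass, for gram-denominated categories) or
#'   `"sugar_mass"`. Sugar is unavailable for alcohol (no label data),
#'   zero-sugar drinks, bottled water and toiletries.
#' @param category_col Column of `products` holding the labels; defaults to
#'   `levy_category`. Any label column works, so ad-hoc groupings (e.g.
#'   sugar bands) can reuse this function.
#'
#' @return A [weekly_series()] tibble; weeks with an empty panel get NA.
#' @examples
#' cfg <- sim_config(n_households = 4, seed = 1)
#' p <- simulate_panel(cfg)
#' weekly_weighted_mean(p$purchases, p$products, p$weights, "high_tier")
#' @export
weekly_weighted_mean <- function(purchases, products, weights, category_label,
                                 measure = c("volume", "sugar_mass"),
                                 category_col = "levy_category") {
  measure <- arg_match(measure)
  if (!category_col %in% names(products)) {
    if (category_col != "levy_category") {
      abort(glue::glue("products has no '{category_col}' column"))
    }
    products <- assign_category(products)
  }
  labels <- unique(products[[category_col]])
  if (!category_label %in% labels) {
    abort(glue::glue("unknown category label '{category_label}'"))
  }
  if (measure == "sugar_mass" && category_col == "levy_category" &&
    category_label %in% .no_sugar_categories) {
    abort(glue::glue("no sugar series is defined for category '{category_label}'"))
  }

  prods <- products[products[[category_col]] == category_label, , drop = FALSE]
  if (measure == "sugar_mass") {
    if (all(is.na(prods$sugar_g_per_100ml))) {
      abort(glue::glue("category '{category_label}' has no sugar data"))
    }
    prods <- mutate(prods, .sugar = tidyr::replace_na(sugar_g_per_100ml, 0))
  }

  totals <- purchases |>
    semi_join(prods, by = "product_id") |>
    (\(ev) {
      if (measure == "sugar_mass") {
        ev |>
          left_join(select(prods, product_id, .sugar), by = "product_id") |>
          mutate(x = quantity * .sugar / 100)
      } else {
        mutate(ev, x = quantity)
      }
    })() |>
    group_by(household_id, week) |>
    summarise(x = sum(x), .groups = "drop")

  panel <- weights |>
    left_join(totals, by = c("household_id", "week")) |>
    mutate(x = tidyr::replace_na(x, 0)) |>
    group_by(week, week_start_date) |>
    summarise(
      value = if (n() == 0) NA_real_ else sum(weight * x) / sum(weight),
      n_households = dplyr::n_distinct(household_id),
      .groups = "drop"
    ) |>
    arrange(week)

  weekly_series(
    week_start_date = panel$week_start_date, value = panel$value,
    category = category_label, measure = measure,
    n_households = panel$n_households, week = panel$week
  )
}

#' Combine weekly series week-wise
#'
#' Adds aligned weekly series value-by-value, e.g. to form "all soft
#' drinks combined" or "levy liable" aggregates. All series must share the
#' same week grid and measure. Combined volume series add powder and
#' confectionery grams to millilitres numerically; such totals are
#' mL-equivalent, matching how the combined rows of purchasing summaries
#' are built.
#'
#' @param series_list List of [weekly_series()] tibbles.
#' @param new_label Category label for the combined series.
#' @return A [weekly_series()] tibble.
#' @export
combine_categories <- function(series_list, new_label) {
  stopifnot(length(series_list) >= 1)
  first <- series_list[[1]]
  for (s in series_list[-1]) {
    if (!identical(s$week_start_date, first$week_start_date)) {
      abort("mismatched week grids")
    }
    if (!identical(unique(s$measure), unique(first$measure))) {
      abort("mismatched measures")
    }
  }
  total <- purrr::reduce(purrr::map(series_list, "value"), `+`)
  weekly_series(
    week_start_date = first$week_start_date, value = total,
    category = new_label, measure = unique(first$measure),
    n_households = first$n_households, week = first$week
  )
}
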