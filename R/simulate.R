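#' Simulate a product catalogue
#'
#' Builds a catalogue with (at least) three products per configured
#' category -- two from large manufacturers shared across categories and
#' one from a category-specific small manufacturer -- whose composition
#' fields are consistent with the intended levy category: sugar
#' concentrations sit on and around the 5 and 8 g/100 mL thresholds,
#' milk-based products exceed 75% milk, alcoholic products exceed 1.2% ABV
#' (plus one alcohol-replacement product), powders and confectionery carry
#' gram units, juices are 100% juice with no added sugar, and bottled water
#' is flagged as such.
#'
#' @param config A [sim_config()]; its seed drives the composition jitter.
#'
#' @return Tibble of products with the [assign_category()] input schema
#'   plus `intended_category`, `market_share` (within category) and `unit`.
#' @export
simulate_catalogue <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  specs <- config$category_specs

  base_row <- function(group, sugar = NA_real_, milk = 0, abv = 0, juice = 0,
                       form = "liquid", nas = FALSE, water = FALSE) {
    tibble(
      product_group = group, sugar_g_per_100ml = sugar,
      milk_content_pct = milk, abv_pct = abv, juice_pct = juice,
      physical_form = form, no_added_sugar = nas, is_bottled_water = water
    )
  }
  # three composition rows per category; the first pins the tier boundary
  composer <- list(
    high_tier = function() base_row("soft_drink", c(8, stats::runif(1, 8.5, 10), stats::runif(1, 10, 12))),
    low_tier = function() base_row("soft_drink", c(5, stats::runif(1, 5.5, 7.5), 7.99)),
    no_levy_low_sugar = function() base_row("soft_drink", c(4.99, stats::runif(1, 1, 4.5), 0.5)),
    no_levy_zero_sugar = function() base_row("soft_drink", c(0, 0, 0)),
    bottled_water = function() base_row("water", 0, water = TRUE),
    exempt_milk_based = function() base_row(
      "dairy_drink", c(stats::runif(1, 8.5, 12), stats::runif(1, 3, 4.9), stats::runif(1, 5, 7.9)),
      milk = stats::runif(3, 80, 95)
    ),
    exempt_alcohol = function() {
      out <- base_row(c("beer", "wine", "alcohol_replacement"))
      out$abv_pct <- c(4.5, 13, 0)
      out
    },
    exempt_juice = function() base_row("juice", stats::runif(3, 8, 11), juice = 100, nas = TRUE),
    exempt_powder = function() base_row("hot_beverage", stats::runif(3, 30, 70), form = "powder"),
    confectionery = function() {
      base_row(
        c("sugar_confectionery", "chocolate_confectionery", "chocolate_confectionery"),
        stats::runif(3, 45, 65),
        form = "solid"
      )
    },
    toiletries = function() base_row(c("shampoo", "hair_conditioner", "liquid_soap"))
  )

  cat_tbl <- function(label) {
    rows <- composer[[label]]()
    k <- nrow(rows)
    share <- c(rep((1 - config$small_share) / (k - 1), k - 1), config$small_share)
    rows |>
      mutate(
        intended_category = label,
        product_id = sprintf("%s_p%d", label, row_number()),
        description = sprintf("synthetic %s product %d", label, row_number()),
        manufacturer_id = c(
          sprintf("M%02d", seq_len(k - 1)),
          sprintf("S_%s", label)
        ),
        market_share = share,
        unit = specs[[label]]$unit
      )
  }

  purrr::map(names(specs), cat_tbl) |>
    bind_rows() |>
    select(
      product_id, description, product_group, sugar_g_per_100ml,
      milk_content_pct, abv_pct, juice_pct, physical_form, no_added_sugar,
      is_bottled_water, manufacturer_id, intended_category, market_share, unit
    )
}

# expected weekly per-household outcome for one category_spec; `include`
# controls which interruption terms contribute (used for counterfactuals)
expected_path <- function(spec, calendar, weeks = seq_len(calendar$n_weeks),
                          include = c("announcement", "implementation")) {
  wk <- calendar$weeks[weeks, , drop = FALSE]
  t <- as.numeric(weeks)
  tA <- calendar$announcement_week
  tI <- calendar$implementation_week
  A <- as.numeric(t >= tA)
  I <- as.numeric(t >= tI)
  mu <- spec$baseline_level +
    spec$weekly_trend * (t - 1) +
    spec$seasonal_amplitude * sin(2 * pi * (t - 1) / 52.18) +
    spec$christmas_uplift * wk$christmas +
    spec$easter_uplift * wk$easter
  if ("announcement" %in% include) {
    mu <- mu + spec$announcement_level_change * A +
      spec$announcement_slope_change * (t - tA) * A
  }
  if ("implementation" %in% include) {
    mu <- mu + spec$implementation_level_change * I +
      spec$implementation_slope_change * (t - tI) * I
  }
  mu
}

#' Expected weekly series implied by a configuration
#'
#' The deterministic per-household expectation for every configured
#' category and week, i.e. the ground truth the noisy panel fluctuates
#' around. Errors if any expected value is negative: such a configuration
#' cannot describe purchase volumes over the requested span.
#'
#' @param config A [sim_config()].
#' @return Tibble with `category`, `week`, `week_start_date`, `expected`.
#' @export
expected_series <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cal <- config$calendar
  out <- purrr::map(config$category_specs, function(sp) {
    tibble(
      category = sp$category_label,
      week = cal$weeks$week,
      week_start_date = cal$weeks$week_start_date,
      expected = expected_path(sp, cal)
    )
  }) |> bind_rows()
  if (any(out$expected < 0)) {
    bad <- out |> filter(expected < 0)
    abort(glue::glue(
      "configuration implies negative expected purchases, e.g. category ",
      "'{bad$category[1]}' at week {bad$week[1]} ({round(bad$expected[1], 2)})"
    ))
  }
  out
}

#' Simulate a weighted household purchase panel
#'
#' Generates purchase events for every configured category: each
#' household's weekly category outcome is the deterministic expectation
#' (trend + seasonality + holiday uplifts + interruption effects) plus a
#' common AR(1) weekly disturbance and a household random intercept, and
#' is split across the category's products by their market shares. One
#' lognormal panel weight (mean 1) is drawn per household and replicated
#' over weeks. The returned ground truth carries the exact expected series
#' and the configuration, so true intervention effects at any week are
#' available in closed form via [true_effect()].
#'
#' @param config A [sim_config()]; identical configs (same seed) give
#'   bit-identical panels.
#'
#' @return An object of class `levy_panel`: a list with `purchases`
#'   (`household_id`, `week`, `week_start_date`, `product_id`, `quantity`,
#'   `unit`, `spend`), `products` (the catalogue), `weights`
#'   (`household_id`, `week`, `week_start_date`, `weight`) and `truth`
#'   (list of `expected` series and `config`).
#' @examples
#' cfg <- sim_config(n_households = 5, seed = 7)
#' panel <- simulate_panel(cfg)
#' dplyr::count(panel$purchases, unit)
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  catalogue <- simulate_catalogue(config) # also seeds the RNG
  cal <- config$calendar
  truth_tbl <- expected_series(config)
  n_h <- config$n_households
  n_w <- cal$n_weeks
  households <- sprintf("H%04d", seq_len(n_h))

  w_h <- if (config$weight_sdlog > 0) {
    rlnorm(n_h, meanlog = -config$weight_sdlog^2 / 2, sdlog = config$weight_sdlog)
  } else {
    rep(1, n_h)
  }
  weights <- tidyr::expand_grid(
    household_id = households,
    week = seq_len(n_w)
  ) |>
    mutate(
      week_start_date = cal$weeks$week_start_date[week],
      weight = w_h[match(household_id, households)]
    )

  # unit price used only to give the spend column a realistic scale
  price_per_unit <- function(unit) ifelse(unit == "mL", 0.001, 0.005)

  sim_cat <- function(sp) {
    mu <- truth_tbl$expected[truth_tbl$category == sp$category_label]
    u <- ar1_noise(n_w, sp$noise_sd, sp$ar1_coefficient)
    b <- if (sp$household_sd > 0) rnorm(n_h, 0, sp$household_sd) else numeric(n_h)
    hh_week <- tibble(
      household_id = rep(households, each = n_w),
      week = rep(seq_len(n_w), times = n_h),
      x = rep(mu + u, times = n_h) + rep(b, each = n_w)
    )
    prods <- catalogue |>
      filter(intended_category == sp$category_label) |>
      select(product_id, market_share, unit)
    dplyr::cross_join(hh_week, prods) |>
      mutate(quantity = market_share * x) |>
      select(-x, -market_share)
  }

  purchases <- purrr::map(config$category_specs, sim_cat) |>
    bind_rows() |>
    mutate(
      week_start_date = cal$weeks$week_start_date[week],
      spend = quantity * price_per_unit(unit)
    ) |>
    select(household_id, week, week_start_date, product_id, quantity, unit, spend) |>
    arrange(household_id, week, product_id)

  structure(
    list(
      purchases = purchases,
      products = catalogue,
      weights = weights,
      truth = list(expected = truth_tbl, config = config)
    ),
    class = "levy_panel"
  )
}

#' @export
print.levy_panel <- function(x, ...) {
  cat(
    "<levy_panel> ", length(unique(x$weights$household_id)), " households, ",
    max(x$weights$week), " weeks, ", nrow(x$purchases), " purchase events, ",
    nrow(x$products), " products\n",
    sep = ""
  )
  invisible(x)
}

# stationary AR(1) disturbance with marginal sd `sd` and lag-1 corr `rho`
ar1_noise <- function(n, sd, rho) {
  if (sd == 0) {
    return(numeric(n))
  }
  e <- rnorm(n)
  u <- numeric(n)
  u[1] <- e[1]
  if (n > 1) {
    innov_sd <- sqrt(1 - rho^2)
    for (t in 2:n) u[t] <- rho * u[t - 1] + innov_sd * e[t]
  }
  u * sd
}

#' Closed-form true intervention effect
#'
#' The difference between the with-intervention and without-intervention
#' expected paths of a configured category at given weeks, and that
#' difference as a percentage of the counterfactual. Which interruption
#' terms count as "the intervention" follows the three-analysis design:
#' analysis 1 the announcement terms, analysis 2 the implementation terms,
#' analysis 3 both.
#'
#' @param config A [sim_config()].
#' @param category A configured category label.
#' @param analysis_id 1, 2 or 3.
#' @param week Week index (may be a vector), within the simulated span.
#'
#' @return Tibble with `week`, `absolute_change`, `relative_change_pct`
#'   and `counterfactual`.
#' @export
true_effect <- function(config, category, analysis_id, week) {
  stopifnot(inherits(config, "sim_config"), analysis_id %in% 1:3)
  sp <- config$category_specs[[category]]
  if (is.null(sp)) abort(glue::glue("category '{category}' not in config"))
  cal <- config$calendar
  week <- as.integer(week)
  if (any(week < 1L | week > cal$n_weeks)) abort("week outside simulated span")

  keep <- switch(as.character(analysis_id),
    "1" = "implementation", # announcement is the intervention
    "2" = "announcement", # implementation is the intervention
    "3" = character(0)
  )
  observed <- expected_path(sp, cal, week)
  counterfactual <- expected_path(sp, cal, week, include = keep)
  if (any(counterfactual <= 0)) {
    abort(
      "degenerate counterfactual (<= 0); evaluate at the last positive week instead",
      class = "levyeval_degenerate_counterfactual"
    )
  }
  absolute <- observed - counterfactual
  tibble(
    week = week,
    absolute_change = absolute,
    relative_change_pct = 100 * absolute / counterfactual,
    counterfactual = counterfactual
  )
}

#' Write / read a simulated panel as delimited text
#'
#' `write_panel()` writes `purchases.csv`, `products.csv`, `weights.csv`,
#' a `ground_truth.csv` sidecar with the expected weekly series, and
#' `config.json` describing the generating configuration. `read_panel()`
#' reads them back into a `levy_panel` (the configuration is restored from
#' the JSON, so [true_effect()] works on the round-tripped panel).
#'
#' @param panel A `levy_panel`.
#' @param dir Directory (created if needed).
#' @return `write_panel()` the directory, invisibly; `read_panel()` a
#'   `levy_panel`.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "levy_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(
    select(panel$purchases, household_id, week_start_date, product_id, quantity, unit, spend),
    file.path(dir, "purchases.csv")
  )
  readr::write_csv(panel$products, file.path(dir, "products.csv"))
  readr::write_csv(
    select(panel$weights, household_id, week_start_date, weight),
    file.path(dir, "weights.csv")
  )
  readr::write_csv(panel$truth$expected, file.path(dir, "ground_truth.csv"))
  cfg <- panel$truth$config
  jsonlite::write_json(
    list(
      n_households = cfg$n_households,
      weight_sdlog = cfg$weight_sdlog,
      small_share = cfg$small_share,
      seed = cfg$seed,
      calendar = list(
        start_date = format(cfg$calendar$start_date),
        n_weeks = cfg$calendar$n_weeks,
        announcement_date = format(cfg$calendar$announcement_date),
        implementation_date = format(cfg$calendar$implementation_date)
      ),
      category_specs = purrr::map(cfg$category_specs, unclass)
    ),
    file.path(dir, "config.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_panel
#' @export
read_panel <- function(dir) {
  js <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  cal <- study_calendar(
    start_date = as.Date(js$calendar$start_date),
    n_weeks = js$calendar$n_weeks,
    announcement_date = as.Date(js$calendar$announcement_date),
    implementation_date = as.Date(js$calendar$implementation_date)
  )
  specs <- purrr::map(js$category_specs, ~ do.call(category_spec, .x))
  cfg <- sim_config(
    n_households = js$n_households, calendar = cal, category_specs = specs,
    weight_sdlog = js$weight_sdlog, small_share = js$small_share, seed = js$seed
  )
  col_date <- readr::cols(week_start_date = readr::col_date())
  purchases <- readr::read_csv(
    file.path(dir, "purchases.csv"),
    col_types = readr::cols(week_start_date = readr::col_date(), .default = readr::col_guess())
  )
  weights <- readr::read_csv(file.path(dir, "weights.csv"), col_types = col_date)
  wk <- function(d) as.integer(floor(as.numeric(d - cal$start_date) / 7)) + 1L
  structure(
    list(
      purchases = mutate(purchases, week = wk(week_start_date)),
      products = readr::read_csv(file.path(dir, "products.csv"), col_types = readr::cols()),
      weights = mutate(weights, week = wk(week_start_date)),
      truth = list(
        expected = readr::read_csv(file.path(dir, "ground_truth.csv"), col_types = col_date),
        config = cfg
      )
    ),
    class = "levy_panel"
  )
}
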