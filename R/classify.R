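#' Levy category labels
#'
#' The mutually exclusive, exhaustive set of categories every accepted
#' product maps into: the two levy tiers, the two no-levy sugar bands,
#' bottled water, the four exemption routes (milk-based, alcoholic, 100%
#' juice, powder), confectionery, the toiletries control category, and
#' `excluded` for products outside the analysis (infant formula, medical
#' drinks, skimmed milk).
#'
#' @return Character vector of the twelve category labels.
#' @export
levy_category_labels <- function() {
  c(
    "high_tier", "low_tier", "no_levy_low_sugar", "no_levy_zero_sugar",
    "bottled_water", "exempt_milk_based", "exempt_alcohol", "exempt_juice",
    "exempt_powder", "confectionery", "toiletries", "excluded"
  )
}

#' Category labels counted as levy liable
#'
#' High tier, low tier and the two no-levy sugar bands: drinks that are not
#' levy exempt. Bottled water is kept separate throughout.
#'
#' @return Character vector.
#' @export
levy_liable_labels <- function() {
  c("high_tier", "low_tier", "no_levy_low_sugar", "no_levy_zero_sugar")
}

# product_group values routed before any composition rule
.toiletries_groups <- c("toiletries", "shampoo", "hair_conditioner", "liquid_soap")
.confectionery_groups <- c("confectionery", "sugar_confectionery", "chocolate_confectionery")
.excluded_groups <- c("infant_formula", "medical", "skimmed_milk")

#' Assign products to levy categories
#'
#' Classifies each product into exactly one levy category using the
#' following precedence:
#'
#' 1. panel product group: toiletries and confectionery groups are routed
#'    directly; infant formula, medical drinks and skimmed milk are
#'    `excluded`;
#' 2. exemptions: milk content > 75% (milk-based), alcohol > 1.2% ABV or an
#'    alcohol-replacement group (alcoholic), powders, and 100% juices with
#'    no added sugar;
#' 3. bottled water;
#' 4. sugar concentration thresholds: >= 8 g/100 mL high tier, >= 5 and
#'    < 8 g/100 mL low tier, > 0 and < 5 g/100 mL no-levy low sugar, and
#'    exactly 0 g/100 mL no-levy zero sugar.
#'
#' Boundary values sit in the upper band (8.0 is high tier, 5.0 is low
#' tier), matching the ">= " inequalities of the levy legislation.
#'
#' @param products A data frame of products with columns `product_id`,
#'   `product_group`, `sugar_g_per_100ml`, `milk_content_pct`, `abv_pct`,
#'   `physical_form` (`"liquid"`, `"powder"` or `"solid"`), `juice_pct`,
#'   `no_added_sugar` (logical) and `is_bottled_water` (logical). Missing
#'   composition columns are treated as 0 / `FALSE`, except sugar: a liquid
#'   drink with no sugar concentration and no exemption route is an error.
#'
#' @return The input as a tibble with a `levy_category` column appended.
#' @examples
#' products <- tibble::tibble(
#'   product_id = c("p1", "p2"),
#'   product_group = "soft_drink",
#'   sugar_g_per_100ml = c(9, 4),
#'   milk_content_pct = 0, abv_pct = 0, juice_pct = 0,
#'   physical_form = "liquid", no_added_sugar = FALSE,
#'   is_bottled_water = FALSE
#' )
#' assign_category(products)$levy_category
#' @export
assign_category <- function(products) {
  products <- as_tibble(products)
  stopifnot(all(c("product_id", "product_group") %in% names(products)))
  get0_ <- function(col, default) {
    if (col %in% names(products)) {
      out <- products[[col]]
      out[is.na(out)] <- default
      out
    } else {
      rep(default, nrow(products))
    }
  }
  sugar_raw <- if ("sugar_g_per_100ml" %in% names(products)) {
    products$sugar_g_per_100ml
  } else {
    rep(NA_real_, nrow(products))
  }
  milk <- get0_("milk_content_pct", 0)
  abv <- get0_("abv_pct", 0)
  juice <- get0_("juice_pct", 0)
  nas <- get0_("no_added_sugar", FALSE)
  water <- get0_("is_bottled_water", FALSE)
  form <- get0_("physical_form", "liquid")
  group <- products$product_group

  pct_ok <- function(p) all(p >= 0 & p <= 100)
  if (!pct_ok(milk) || !pct_ok(juice) || !all(abv >= 0)) {
    abort("milk_content_pct and juice_pct must lie in [0, 100]; abv_pct must be >= 0")
  }
  if (any(sugar_raw < 0, na.rm = TRUE)) {
    abort("sugar_g_per_100ml must be >= 0 where present")
  }

  sugar <- sugar_raw
  label <- case_when(
    group %in% .toiletries_groups ~ "toiletries",
    group %in% .confectionery_groups ~ "confectionery",
    group %in% .excluded_groups ~ "excluded",
    milk > 75 ~ "exempt_milk_based",
    abv > 1.2 | group == "alcohol_replacement" ~ "exempt_alcohol",
    form == "powder" ~ "exempt_powder",
    juice == 100 & nas ~ "exempt_juice",
    water ~ "bottled_water",
    !is.na(sugar) & sugar >= 8 ~ "high_tier",
    !is.na(sugar) & sugar >= 5 ~ "low_tier",
    !is.na(sugar) & sugar > 0 ~ "no_levy_low_sugar",
    !is.na(sugar) & sugar == 0 ~ "no_levy_zero_sugar",
    TRUE ~ NA_character_
  )
  if (anyNA(label)) {
    bad <- products$product_id[is.na(label)]
    abort(glue::glue(
      "cannot classify product(s) {paste(bad, collapse = ', ')}: ",
      "drink with no sugar concentration and no exemption route"
    ))
  }
  mutate(products, levy_category = label)
}

#' Flag small manufacturers
#'
#' The levy exempts manufacturers selling less than a threshold volume of
#' levy-liable drinks per year (1 million litres in legislation). With no
#' registry of exempt producers available, smallness is estimated from the
#' panel itself: levy-liable purchase volume is summed per manufacturer per
#' calendar year across the span of the data, the mean annual volume taken,
#' and a manufacturer is flagged small when that mean falls strictly below
#' the threshold. Manufacturers in the catalogue with no recorded liable
#' purchases are flagged small. A mean exactly equal to the threshold is
#' not small ("less than" in the legislation).
#'
#' @param purchases Purchase events (`product_id`, `week_start_date`,
#'   `quantity` in mL for liquids).
#' @param products Product catalogue; classified with [assign_category()]
#'   if it lacks a `levy_category` column.
#' @param threshold_litres_per_year Litres per year below which a
#'   manufacturer is small. Default 1e6; the stricter sensitivity analysis
#'   uses 5e5.
#'
#' @return Tibble with `manufacturer_id`, `mean_annual_litres`, `small`.
#' @export
small_manufacturer_flags <- function(purchases, products,
                                     threshold_litres_per_year = 1e6) {
  stopifnot(threshold_litres_per_year > 0)
  purchases <- as_tibble(purchases)
  if (nrow(purchases) == 0L) abort("empty purchase set")
  if (!"levy_category" %in% names(products)) products <- assign_category(products)

  liable <- products |>
    filter(levy_category %in% levy_liable_labels()) |>
    select(product_id, manufacturer_id)
  years <- as.integer(format(range(purchases$week_start_date), "%Y"))
  year_grid <- seq(years[1], years[2])

  per_year <- purchases |>
    inner_join(liable, by = "product_id") |>
    mutate(year = as.integer(format(week_start_date, "%Y"))) |>
    group_by(manufacturer_id, year) |>
    summarise(volume_l = sum(quantity) / 1000, .groups = "drop")

  # complete over all manufacturers in the catalogue and all calendar years
  tidyr::expand_grid(
    manufacturer_id = unique(products$manufacturer_id),
    year = year_grid
  ) |>
    left_join(per_year, by = c("manufacturer_id", "year")) |>
    mutate(volume_l = tidyr::replace_na(volume_l, 0)) |>
    group_by(manufacturer_id) |>
    summarise(mean_annual_litres = mean(volume_l), .groups = "drop") |>
    mutate(small = mean_annual_litres < threshold_litres_per_year)
}
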