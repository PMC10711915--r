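# helper to build one product row with sensible defaults
prod <- function(id = "p", group = "soft_drink", sugar = NA, milk = 0, abv = 0,
                 juice = 0, form = "liquid", nas = FALSE, water = FALSE,
                 manufacturer = "M01") {
  tibble::tibble(
    product_id = id, product_group = group, sugar_g_per_100ml = sugar,
    milk_content_pct = milk, abv_pct = abv, juice_pct = juice,
    physical_form = form, no_added_sugar = nas, is_bottled_water = water,
    manufacturer_id = manufacturer
  )
}

cat_of <- function(...) assign_category(prod(...))$levy_category

test_that("sugar thresholds land on the right side of each tier boundary", {
  cases <- list(
    list(sugar = 10, expect = "high_tier"),
    list(sugar = 8.0, expect = "high_tier"),
    list(sugar = 7.99, expect = "low_tier"),
    list(sugar = 6.5, expect = "low_tier"),
    list(sugar = 5.0, expect = "low_tier"),
    list(sugar = 4.99, expect = "no_levy_low_sugar"),
    list(sugar = 0.01, expect = "no_levy_low_sugar"),
    list(sugar = 0, expect = "no_levy_zero_sugar")
  )
  for (cs in cases) expect_equal(cat_of(sugar = cs$sugar), cs$expect)
})

test_that("exemptions and group routes take precedence over sugar content", {
  expect_equal(cat_of(sugar = 9, milk = 80), "exempt_milk_based")
  expect_equal(cat_of(sugar = 10, milk = 76), "exempt_milk_based")
  expect_equal(cat_of(sugar = 10, milk = 75), "high_tier") # > 75, not >=
  expect_equal(cat_of(sugar = 9, abv = 5), "exempt_alcohol")
  expect_equal(cat_of(sugar = 9, abv = 1.2), "high_tier") # > 1.2, not >=
  expect_equal(cat_of(group = "alcohol_replacement", sugar = 9), "exempt_alcohol")
  expect_equal(cat_of(sugar = 60, form = "powder"), "exempt_powder")
  expect_equal(cat_of(sugar = 9, juice = 100, nas = TRUE), "exempt_juice")
  expect_equal(cat_of(sugar = 9, juice = 100, nas = FALSE), "high_tier")
  expect_equal(cat_of(sugar = 0, water = TRUE), "bottled_water")
  expect_equal(cat_of(group = "shampoo", sugar = 9), "toiletries")
  expect_equal(cat_of(group = "chocolate_confectionery", sugar = 55, form = "solid"), "confectionery")
  expect_equal(cat_of(group = "infant_formula", sugar = 7), "excluded")
  expect_equal(cat_of(group = "skimmed_milk", sugar = 5, milk = 99), "excluded")
})

test_that("a drink without a sugar concentration or exemption route is rejected by name", {
  expect_error(cat_of(id = "mystery9", sugar = NA), "mystery9")
})

# independent re-reading of the category rules, written as nested branches
oracle_category <- function(p) {
  if (p$product_group %in% c("toiletries", "shampoo", "hair_conditioner", "liquid_soap")) {
    return("toiletries")
  }
  if (p$product_group %in% c("confectionery", "sugar_confectionery", "chocolate_confectionery")) {
    return("confectionery")
  }
  if (p$product_group %in% c("infant_formula", "medical", "skimmed_milk")) {
    return("excluded")
  }
  if (p$milk_content_pct > 75) {
    return("exempt_milk_based")
  }
  if (p$abv_pct > 1.2 || p$product_group == "alcohol_replacement") {
    return("exempt_alcohol")
  }
  if (p$physical_form == "powder") {
    return("exempt_powder")
  }
  if (p$juice_pct == 100 && p$no_added_sugar) {
    return("exempt_juice")
  }
  if (p$is_bottled_water) {
    return("bottled_water")
  }
  s <- p$sugar_g_per_100ml
  if (is.na(s)) {
    return(NA_character_)
  }
  if (s >= 8) {
    "high_tier"
  } else if (s >= 5) {
    "low_tier"
  } else if (s > 0) "no_levy_low_sugar" else "no_levy_zero_sugar"
}

random_products <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    product_id = sprintf("r%05d", seq_len(n)),
    product_group = sample(c(
      "soft_drink", "shampoo", "sugar_confectionery", "infant_formula",
      "alcohol_replacement", "juice", "dairy_drink", "beer"
    ), n, replace = TRUE),
    sugar_g_per_100ml = ifelse(
      stats::runif(n) < 0.1, NA,
      sample(c(0, 0.5, 4.99, 5, 7.99, 8, stats::runif(1, 0, 15)), n, replace = TRUE)
    ),
    milk_content_pct = sample(c(0, 50, 75, 75.1, 90), n, replace = TRUE),
    abv_pct = sample(c(0, 0.5, 1.2, 1.3, 5), n, replace = TRUE),
    juice_pct = sample(c(0, 50, 100), n, replace = TRUE),
    physical_form = sample(c("liquid", "powder", "solid"), n, replace = TRUE,
      prob = c(0.8, 0.15, 0.05)
    ),
    no_added_sugar = sample(c(TRUE, FALSE), n, replace = TRUE),
    is_bottled_water = stats::runif(n) < 0.05,
    manufacturer_id = "M01"
  )
}

test_that("every classifiable product receives exactly one category, matching an independent rule reading", {
  prods <- random_products(2000, seed = 42)
  oracle <- vapply(
    seq_len(nrow(prods)),
    function(i) oracle_category(as.list(prods[i, ])), character(1)
  )
  ok <- !is.na(oracle)
  got <- assign_category(prods[ok, ])$levy_category
  expect_equal(got, oracle[ok])
  expect_true(all(got %in% levy_category_labels()))
  expect_true(all(lengths(got) == 1))
  # the unclassifiable remainder errors rather than silently dropping
  if (any(!ok)) expect_error(assign_category(prods[!ok, ]), "sugar")
})

yearly_purchases <- function(manufacturer, litres_by_year) {
  purrr::imap(litres_by_year, function(litres, i) {
    tibble::tibble(
      household_id = "H1",
      week_start_date = as.Date(sprintf("%d-06-01", 2013 + i)),
      product_id = paste0(manufacturer, "_drink"),
      quantity = litres * 1000
    )
  }) |> dplyr::bind_rows()
}

test_that("small-manufacturer flags use the mean annual levy-liable volume", {
  products <- dplyr::bind_rows(
    prod(id = "A_drink", sugar = 9, manufacturer = "A"),
    prod(id = "B_drink", sugar = 9, manufacturer = "B"),
    prod(id = "C_drink", sugar = 9, manufacturer = "C")
  )
  purchases <- dplyr::bind_rows(
    yearly_purchases("A", c(0.8e6, 1.0e6, 0.9e6)), # mean 0.9M -> small at 1M
    yearly_purchases("B", c(0.6e6, 0.6e6, 0.6e6)) # mean 0.6M
  )
  flags1 <- small_manufacturer_flags(purchases, products, 1e6)
  expect_true(flags1$small[flags1$manufacturer_id == "A"])
  expect_equal(flags1$mean_annual_litres[flags1$manufacturer_id == "A"], 0.9e6)
  # no recorded purchases at all -> small
  expect_true(flags1$small[flags1$manufacturer_id == "C"])
  # mean 0.6M is above the 0.5M threshold
  flags05 <- small_manufacturer_flags(purchases, products, 0.5e6)
  expect_false(flags05$small[flags05$manufacturer_id == "B"])
  # raising the threshold never unflags anyone
  expect_true(all(flags1$small[flags05$small]))
  # a mean exactly at the threshold is not small ("less than")
  flags06 <- small_manufacturer_flags(purchases, products, 0.6e6)
  expect_false(flags06$small[flags06$manufacturer_id == "B"])
  expect_error(small_manufacturer_flags(purchases[0, ], products, 1e6), "empty")
})
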