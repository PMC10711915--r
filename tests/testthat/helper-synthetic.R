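# shared fixtures: a short calendar and small noiseless panels

short_calendar <- function(n_weeks = 150) {
  start <- as.Date("2014-02-26")
  study_calendar(
    start_date = start, n_weeks = n_weeks,
    announcement_date = start + 59 * 7, # falls in week 60
    implementation_date = start + 99 * 7 # falls in week 100
  )
}

# a one-target config with the toiletries control; noiseless by default
target_config <- function(target, n_households = 3, calendar = short_calendar(),
                          seed = 1, weight_sdlog = 0) {
  sim_config(
    n_households = n_households, calendar = calendar,
    category_specs = list(target, category_spec("toiletries", 123, -0.01)),
    weight_sdlog = weight_sdlog, seed = seed
  )
}

volume_series <- function(panel, label) {
  prods <- assign_category(panel$products)
  weekly_weighted_mean(panel$purchases, prods, panel$weights, label, "volume")
}

# constant-valued weekly series on a given grid (for arithmetic checks)
constant_series <- function(value, n = 10, measure = "sugar_mass", label = "c") {
  weekly_series(
    week_start_date = as.Date("2014-03-05") + 7 * (seq_len(n) - 1),
    value = rep(value, n), category = label, measure = measure
  )
}
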