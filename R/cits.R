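#' Interruption specification for one analysis design
#'
#' The three analysis designs around the levy: analysis 1 isolates the
#' announcement (fit window ends two years after it, announcement level and
#' slope terms are the intervention); analysis 2 isolates the
#' implementation (fitted over the full history with announcement terms as
#' nuisance covariates, implementation terms the intervention); analysis 3
#' takes announcement and implementation together as the intervention.
#'
#' @param analysis_id 1, 2 or 3.
#' @param calendar A [study_calendar()] providing the interruption weeks.
#' @param window Integer vector `c(first, last)` of week indices; defaults
#'   to `c(1, announcement_week + 103)` for analysis 1 (104 post-announcement
#'   weeks) and the full grid otherwise.
#' @param evaluation_week Week at which effects are evaluated; defaults to
#'   the last week of the window.
#'
#' @return An `interruption_spec` list.
#' @export
interruption_spec <- function(analysis_id, calendar = study_calendar(),
                              window = NULL, evaluation_week = NULL) {
  stopifnot(analysis_id %in% 1:3, inherits(calendar, "levy_calendar"))
  tA <- calendar$announcement_week
  tI <- calendar$implementation_week
  window <- window %||% if (analysis_id == 1) {
    c(1L, min(calendar$n_weeks, tA + 103L))
  } else {
    c(1L, calendar$n_weeks)
  }
  window <- as.integer(window)
  stopifnot(length(window) == 2, window[1] >= 1, window[2] <= calendar$n_weeks)
  if (tA <= window[1] || tA > window[2]) {
    abort("announcement week must fall strictly inside the fit window")
  }
  if (analysis_id != 1 && (tI <= window[1] || tI > window[2])) {
    abort("implementation week must fall strictly inside the fit window")
  }
  evaluation_week <- as.integer(evaluation_week %||% window[2])
  if (evaluation_week < window[1] || evaluation_week > window[2]) {
    abort("evaluation_week must lie within the fit window")
  }
  structure(
    list(
      analysis_id = analysis_id,
      announcement_week = tA,
      implementation_week = tI,
      window = window,
      evaluation_week = evaluation_week,
      calendar = calendar
    ),
    class = "interruption_spec"
  )
}

# which design columns are "the intervention" for each analysis
intervention_terms <- function(spec) {
  switch(as.character(spec$analysis_id),
    "1" = c("ann_level", "ann_slope"),
    "2" = c("imp_level", "imp_slope"),
    "3" = c("ann_level", "ann_slope", "imp_level", "imp_slope")
  )
}

#' Build the segmented-regression design matrix
#'
#' One row per week of the fit window: intercept; linear time; a
#' post-announcement indicator and weeks-since-announcement; (for analyses
#' 2 and 3) a post-implementation indicator and weeks-since-implementation;
#' `harmonics` sine/cosine pairs with annual period 52.18 weeks; a
#' Christmas-period indicator (week starting in December or January); an
#' optional Easter-week indicator; and, when supplied, the control series
#' as a covariate.
#'
#' @param spec An [interruption_spec()].
#' @param control_series Optional [weekly_series()] covering the window
#'   (the uncontrolled sensitivity variant omits it).
#' @param harmonics Number of annual harmonic pairs (default 2).
#' @param easter Include the Easter indicator (used for confectionery).
#'
#' @return A `cits_design` tibble (`week` plus the design columns) with the
#'   spec and intervention-term names attached as attributes.
#' @export
build_design <- function(spec, control_series = NULL, harmonics = 2,
                         easter = FALSE) {
  stopifnot(inherits(spec, "interruption_spec"), harmonics >= 1)
  cal <- spec$calendar
  weeks <- seq(spec$window[1], spec$window[2])
  wk <- cal$weeks[weeks, , drop = FALSE]
  t <- as.numeric(weeks)
  tA <- spec$announcement_week
  tI <- spec$implementation_week

  X <- tibble(
    week = weeks,
    intercept = 1,
    time = t - 1,
    ann_level = as.numeric(t >= tA),
    ann_slope = pmax(t - tA, 0)
  )
  if (spec$analysis_id != 1) {
    X <- mutate(X,
      imp_level = as.numeric(t >= tI),
      imp_slope = pmax(t - tI, 0)
    )
  }
  for (k in seq_len(harmonics)) {
    X[[paste0("sin", k)]] <- sin(2 * pi * k * (t - 1) / 52.18)
    X[[paste0("cos", k)]] <- cos(2 * pi * k * (t - 1) / 52.18)
  }
  X$christmas <- as.numeric(wk$christmas)
  if (easter) X$easter <- as.numeric(wk$easter)
  if (!is.null(control_series)) {
    ctrl <- control_series[match(weeks, control_series$week), , drop = FALSE]
    if (anyNA(ctrl$value)) {
      abort("control series must cover the fit window without missing values")
    }
    X$control <- ctrl$value
  }

  M <- as.matrix(X[setdiff(names(X), "week")])
  if (qr(M)$rank < ncol(M)) {
    abort(
      "design matrix is rank deficient over the fit window (e.g. a constant control series is collinear with the intercept)"
    )
  }
  structure(X,
    class = c("cits_design", class(X)),
    spec = spec, intervention = intervention_terms(spec)
  )
}

#' Fit a (controlled) interrupted time series model
#'
#' Ordinary least squares for the coefficients. Uncertainty either by a
#' Newey-West heteroskedasticity-and-autocorrelation-consistent covariance
#' with truncation lag \eqn{\lfloor 4 (n/100)^{2/9} \rfloor} and VAR(1)
#' prewhitening (`"hac"`, the default), or by AR(1) generalized least
#' squares (`"ar1"`), in which case the GLS coefficients and model-based
#' covariance are used.
#'
#' @param outcome A [weekly_series()] with no missing values over the
#'   design's window.
#' @param design A [build_design()] result.
#' @param error_model `"hac"` or `"ar1"`.
#'
#' @return A `cits_fit` object: coefficients, covariance, fitted values,
#'   residuals, the design, the outcome label, and the error-model record.
#' @export
fit_cits <- function(outcome, design, error_model = c("hac", "ar1")) {
  error_model <- arg_match(error_model)
  stopifnot(inherits(design, "cits_design"))
  spec <- attr(design, "spec")
  y <- outcome$value[match(design$week, outcome$week)]
  if (anyNA(y) || any(!is.finite(y))) {
    abort("outcome series has missing or non-finite values in the fit window")
  }
  terms <- setdiff(names(design), "week")
  n <- length(y)
  if (n < length(terms) + 10) {
    abort("fit window shorter than parameter count + 10 weeks")
  }
  dat <- as.data.frame(design[terms])
  dat$.y <- y
  fml <- stats::reformulate(terms, response = ".y", intercept = FALSE)
  ols <- lm(fml, data = dat)

  if (error_model == "hac") {
    lag <- floor(4 * (n / 100)^(2 / 9))
    beta <- coef(ols)
    # noiseless inputs make summary.lm warn about a perfect fit; harmless here
    Sigma <- withCallingHandlers(
      sandwich::NeweyWest(ols, lag = lag, prewhite = TRUE, adjust = TRUE),
      warning = function(w) {
        if (grepl("essentially perfect fit", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
  } else {
    lag <- NA_integer_
    dat$.t <- seq_len(n)
    g <- nlme::gls(fml,
      data = dat,
      correlation = nlme::corAR1(form = ~.t), method = "REML"
    )
    beta <- coef(g)
    Sigma <- as.matrix(vcov(g))
  }
  X <- as.matrix(design[terms])
  fit_vals <- drop(X %*% beta)

  structure(
    list(
      coefficients = beta,
      vcov = Sigma,
      fitted = tibble(week = design$week, value = fit_vals),
      residuals = y - fit_vals,
      observed = tibble(week = design$week, value = y),
      design = design,
      spec = spec,
      outcome_label = list(
        category = unique(outcome$category),
        measure = unique(outcome$measure)
      ),
      error_model = error_model,
      hac_lag = if (error_model == "hac") lag else NA_integer_,
      nobs = n
    ),
    class = "cits_fit"
  )
}

#' @export
print.cits_fit <- function(x, ...) {
  cat("<cits_fit> ", x$outcome_label$category, " / ", x$outcome_label$measure,
    ", analysis ", x$spec$analysis_id, ", n = ", x$nobs,
    ", error model ", x$error_model,
    if (x$error_model == "hac") paste0(" (lag ", x$hac_lag, ")"), "\n",
    sep = ""
  )
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @rdname fit_cits
#' @param x A `cits_fit`.
#' @param conf.level Confidence level for `tidy()` intervals.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cits_fit <- function(x, conf.level = 0.95, ...) {
  se <- sqrt(diag(x$vcov))
  z <- qnorm(1 - (1 - conf.level) / 2)
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(x$coefficients / se),
    p.value = 2 * stats::pnorm(-abs(unname(x$coefficients / se))),
    conf.low = unname(x$coefficients - z * se),
    conf.high = unname(x$coefficients + z * se)
  )
}

#' @rdname fit_cits
#' @exportS3Method generics::glance
glance.cits_fit <- function(x, ...) {
  y <- x$observed$value
  tibble(
    nobs = x$nobs,
    r.squared = 1 - sum(x$residuals^2) / sum((y - mean(y))^2),
    sigma = sd(x$residuals),
    error_model = x$error_model,
    hac_lag = x$hac_lag,
    analysis_id = x$spec$analysis_id
  )
}

#' Project the counterfactual series
#'
#' Model prediction over the fit window with the analysis' intervention
#' terms set to zero; trend, seasonality, holiday and control terms keep
#' their observed values. Before the first interruption the counterfactual
#' equals the fitted values.
#'
#' @param fit A [fit_cits()] result.
#' @return A [weekly_series()] with the counterfactual values (measure and
#'   category copied from the outcome; `n_households` NA).
#' @export
project_counterfactual <- function(fit) {
  stopifnot(inherits(fit, "cits_fit"))
  design <- fit$design
  terms <- setdiff(names(design), "week")
  X0 <- as.matrix(design[terms])
  X0[, intersect(attr(design, "intervention"), colnames(X0))] <- 0
  cal <- fit$spec$calendar
  weekly_series(
    week_start_date = cal$weeks$week_start_date[design$week],
    value = drop(X0 %*% fit$coefficients),
    category = fit$outcome_label$category %||% "series",
    measure = fit$outcome_label$measure %||% "volume",
    week = design$week
  )
}

#' Plot observed, fitted and counterfactual series
#'
#' @param object A `cits_fit`.
#' @param ... Unused.
#' @return A ggplot: observed points, fitted line, dashed counterfactual,
#'   dotted vertical lines at the interruptions.
#' @exportS3Method ggplot2::autoplot
autoplot.cits_fit <- function(object, ...) {
  cal <- object$spec$calendar
  dates <- cal$weeks$week_start_date
  obs <- mutate(object$observed, week_start_date = dates[week])
  fitted_tbl <- mutate(object$fitted, week_start_date = dates[week])
  cf <- project_counterfactual(object)
  ggplot2::ggplot(obs, ggplot2::aes(week_start_date, value)) +
    ggplot2::geom_point(colour = "grey55", size = 0.6) +
    ggplot2::geom_line(data = fitted_tbl, colour = "black") +
    ggplot2::geom_line(data = cf, colour = "red", linetype = "dashed") +
    ggplot2::geom_vline(
      xintercept = c(cal$announcement_date, cal$implementation_date),
      linetype = "dotted"
    ) +
    ggplot2::labs(
      x = NULL,
      y = paste0(
        object$outcome_label$category, " (",
        object$outcome_label$measure, " per household per week)"
      ),
      title = paste0("Interrupted time series, analysis ", object$spec$analysis_id)
    ) +
    ggplot2::theme_minimal()
}
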