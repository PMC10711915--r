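# levyeval

Evaluation pipeline for the purchasing effects of the UK Soft Drinks
Industry Levy (SDIL) — a two-tier manufacturer tax (£0.24/L for drinks
with ≥ 8 g sugar/100 mL, £0.18/L for ≥ 5 to < 8 g/100 mL) announced on
16 March 2016 and implemented on 6 April 2018. The package is aimed at
researchers evaluating fiscal food policy with household purchase-panel
data: it classifies products into levy categories, reduces weighted
purchase events to weekly per-household series, fits controlled
interrupted time series (CITS) models around the announcement and
implementation, and reports absolute and relative changes versus the
projected counterfactual with delta-method 95% CIs.

Because real purchase-panel data are proprietary, the package includes a
seeded synthetic panel generator with closed-form ground truth, so the
entire pipeline is testable end to end.

## The model

For a weekly per-household series $y_t$, the package fits the segmented
regression

$$
y_t = \beta_0 + \beta_1 t
    + \lambda_A A_t + \delta_A (t-t_A)A_t
    + \lambda_I I_t + \delta_I (t-t_I)I_t
    + \textstyle\sum_{k=1}^{2}\left[a_k \sin\frac{2\pi kt}{52.18} + b_k\cos\frac{2\pi kt}{52.18}\right]
    + \gamma_X X_t + \gamma_E E_t + \phi c_t + \varepsilon_t ,
$$

where $A_t, I_t$ indicate post-announcement and post-implementation
weeks, $X_t$ ($E_t$) flags Christmas-period (Easter) weeks, and $c_t$ is
a control series (toiletries). Coefficient uncertainty uses prewhitened
Newey–West HAC covariance with lag $\lfloor 4(n/100)^{2/9}\rfloor$, or
AR(1) GLS. The counterfactual zeroes the intervention terms (analysis 1:
announcement terms; 2: implementation; 3: both); the absolute change at
the evaluation week is the contrast $c^\top\beta$, and the relative
change $100(\hat y_{obs}-\hat y_{cf})/\hat y_{cf}$ gets a first-order
delta-method interval. Counterfactuals that cross zero move the
evaluation to the last positive week (flagged).

## Worked example

```r
library(levyeval)

cfg <- sim_config(n_households = 50, seed = 42)
panel <- simulate_panel(cfg)
products <- assign_category(panel$products)

outcome <- weekly_weighted_mean(panel$purchases, products, panel$weights,
                                "high_tier", "volume")
control <- weekly_weighted_mean(panel$purchases, products, panel$weights,
                                "toiletries", "volume")
spec <- interruption_spec(3, cfg$calendar)   # whole-intervention analysis
fit  <- fit_cits(outcome, build_design(spec, control_series = control))
fit
#> <cits_fit> high_tier / volume, analysis 3, n = 266, error model hac (lag 4)
#> intercept      time ann_level ann_slope imp_level imp_slope      sin1      cos1
#>  999.8698   -1.3325   29.1395    0.1979 -162.0090    0.2781   45.6630   -2.3283
#>      sin2      cos2 christmas   control
#>   -0.5182    5.6173  100.4663    0.4663
```

The fitted intercept sits near the configured 950 mL baseline plus the
sampled households' mean offset; the implementation level change (−162)
and the weekly trend (−1.33) estimate the injected −150 and −1.3. The
headline quantities compare the final week with the counterfactual:

```r
estimate_effect(fit)
#>   absolute_change  [-87.4]   95% CI [-147.9, -26.9]
#>   relative_change  [-11.9%]  95% CI [-19.3%, -4.6%]
#>   counterfactual_value 732.6   degenerate FALSE

true_effect(cfg, "high_tier", 3, spec$evaluation_week)
#>   week 266: absolute -108.8, relative -17.4%, counterfactual 624.5
```

So with 50 households the estimated whole-intervention effect (−87 mL per
household per week, CI −148 to −27) covers the closed-form truth
(−109 mL) injected by the generator. `autoplot(fit)` draws the observed,
fitted and counterfactual series; `tidy(fit)` and `glance(fit)` give
broom-style summaries. The full study (all categories × measures ×
analyses, combined-category secondary analysis, small-manufacturer and
no-control sensitivity analyses) runs via `run_primary()`,
`run_secondary_combined()` and `run_sensitivity()`.

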