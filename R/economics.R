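#' Discount factor
#'
#' Present-value weight for an accrual `t` years into the model,
#' `(1 + rate)^(-t)`. A 3% annual rate is applied to both costs and effects
#' by default throughout the package.
#'
#' @param rate Annual discount rate (fraction, >= 0).
#' @param t Time in years (>= 0); vectorised.
#' @return Dimensionless factor(s) in (0, 1].
#' @export
#' @examples
#' discount_factor(0.03, 19)
discount_factor <- function(rate, t) {
  if (!is.numeric(rate) || any(rate < 0)) abort("`rate` must be >= 0.")
  if (!is.numeric(t) || any(t < 0)) abort("`t` must be >= 0.")
  (1 + rate)^(-t)
}

#' Discounted cost and effect of a trajectory
#'
#' Collapses a [run_cohort()] trajectory into a single discounted cost and
#' discounted effect for its strategy. Each half-cycle's undiscounted accrual
#' is discounted at the time of its end boundary (`t = k/2` years for the
#' k-th half-cycle; no half-cycle correction). The per-tooth streams are then
#' scaled according to the `cost_aggregation` and `effect_aggregation`
#' settings (`"cohort_sum"` multiplies by `n_teeth`, `"per_tooth_mean"` does
#' not).
#'
#' @param trajectory A tibble from [run_cohort()].
#' @param params The `ce_parameters` object the trajectory was produced from.
#' @param strategy Strategy label recorded in the result.
#' @return A one-row tibble: `strategy`, `cost`, `effect`.
#' @export
accrue <- function(trajectory, params, strategy) {
  params <- validate_parameters(params)
  s <- match_strategy(strategy)
  st <- params$settings
  expected_len <- st$cycles_per_year * st$horizon_years + 1L
  if (nrow(trajectory) != expected_len) {
    abort(sprintf(
      "Trajectory has %d rows but the settings imply %d half-cycle boundaries.",
      nrow(trajectory), expected_len))
  }
  disc <- discount_factor(st$discount_rate, trajectory$time_years)
  cost <- sum(trajectory$cost * disc)
  effect <- sum(trajectory$effect * disc)
  if (st$cost_aggregation == "cohort_sum") cost <- cost * st$n_teeth
  if (st$effect_aggregation == "cohort_sum") effect <- effect * st$n_teeth
  tibble::tibble(strategy = s, cost = cost, effect = effect)
}

#' Evaluate both strategies on one parameter set
#'
#' Runs the cohort model under SDF and NaF and returns their discounted
#' costs and effects.
#'
#' @param params A validated `ce_parameters` object.
#' @return A two-row tibble (`strategy`, `cost`, `effect`), NaF first.
#' @export
evaluate_strategies <- function(params) {
  dplyr::bind_rows(
    accrue(run_cohort(params, "NAF"), params, "NAF"),
    accrue(run_cohort(params, "SDF"), params, "SDF")
  )
}

#' Incremental cost-effectiveness comparison
#'
#' Compares an intervention strategy `b` against a comparator `a`:
#' incremental cost and effect, the incremental cost-effectiveness ratio
#' (ICER) when both increments are positive, dominance flags when their signs
#' differ, per-strategy net monetary benefit `NMB = wtp * effect - cost`, and
#' the incremental NMB `nmb_b - nmb_a`. All derived quantities use unrounded
#' internal values.
#'
#' @param a,b One-row data frames (`strategy`, `cost`, `effect`) as returned
#'   by [accrue()]; `a` is the comparator (NaF in the base case), `b` the
#'   intervention (SDF).
#' @param wtp Willingness-to-pay per effect unit.
#' @return A `ce_result` object. `tidy()` gives the per-strategy table in
#'   publication layout; `glance()` the one-row incremental summary.
#' @export
#' @examples
#' a <- tibble::tibble(strategy = "NAF", cost = 8863, effect = 1.39)
#' b <- tibble::tibble(strategy = "SDF", cost = 16660, effect = 7.73)
#' compare(a, b, wtp = 50000)
compare <- function(a, b, wtp) {
  for (x in list(a, b)) {
    if (!all(c("strategy", "cost", "effect") %in% names(x)) ||
        nrow(x) != 1L) {
      abort("`a` and `b` must be one-row tibbles with strategy, cost, effect.")
    }
  }
  if (wtp < 0) abort("`wtp` must be >= 0.")
  delta_cost <- b$cost - a$cost
  delta_effect <- b$effect - a$effect

  dominance <- "none"
  icer <- NA_real_
  if (delta_effect == 0) {
    if (delta_cost != 0) dominance <- if (delta_cost < 0) "b_dominant" else "b_dominated"
  } else if (delta_cost <= 0 && delta_effect > 0) {
    dominance <- "b_dominant"
    icer <- delta_cost / delta_effect
  } else if (delta_cost >= 0 && delta_effect < 0) {
    dominance <- "b_dominated"
    icer <- delta_cost / delta_effect
  } else {
    icer <- delta_cost / delta_effect
  }

  nmb_a <- wtp * a$effect - a$cost
  nmb_b <- wtp * b$effect - b$cost
  structure(
    list(
      strategies = dplyr::bind_rows(a, b) |>
        dplyr::mutate(nmb = wtp * .data$effect - .data$cost),
      delta_cost = delta_cost,
      delta_effect = delta_effect,
      icer = icer,
      dominance = dominance,
      nmb = setNames(c(nmb_a, nmb_b), c(a$strategy, b$strategy)),
      incremental_nmb = nmb_b - nmb_a,
      wtp = wtp
    ),
    class = "ce_result"
  )
}

#' Base-case cost-effectiveness analysis
#'
#' Convenience wrapper: evaluates both strategies with [evaluate_strategies()]
#' and compares SDF (intervention) against NaF (comparator) at the configured
#' willingness-to-pay.
#'
#' @param params A validated `ce_parameters` object.
#' @param wtp Willingness-to-pay; defaults to `params$settings$wtp`.
#' @return A `ce_result` object.
#' @export
#' @examples
#' res <- base_case(generate_parameter_set(seed = 1))
#' glance(res)
base_case <- function(params, wtp = NULL) {
  params <- validate_parameters(params)
  wtp <- wtp %||% params$settings$wtp
  sr <- evaluate_strategies(params)
  compare(sr[sr$strategy == "NAF", ], sr[sr$strategy == "SDF", ], wtp)
}

#' @export
print.ce_result <- function(x, ...) {
  cat("<ce_result>  (comparator:", x$strategies$strategy[1],
      "| intervention:", x$strategies$strategy[2], ")\n")
  print(tidy(x), ...)
  cat(sprintf("dominance: %s | incremental NMB at WTP %s: %s\n",
              x$dominance, format(x$wtp, big.mark = " "),
              format(round(x$incremental_nmb), big.mark = " ")))
  invisible(x)
}

#' @describeIn compare Per-strategy table in the layout of a published
#'   cost-effectiveness table: cost, incremental cost, effectiveness,
#'   incremental effectiveness, ICER, NMB (increments on the intervention row
#'   only).
#' @param x A `ce_result` object.
#' @param ... Unused.
#' @export
tidy.ce_result <- function(x, ...) {
  s <- x$strategies
  tibble::tibble(
    strategy = s$strategy,
    cost = s$cost,
    incremental_cost = c(NA_real_, x$delta_cost),
    effect = s$effect,
    incremental_effect = c(NA_real_, x$delta_effect),
    icer = c(NA_real_, x$icer),
    nmb = s$nmb
  )
}

#' @describeIn compare One-row incremental summary (`delta_cost`,
#'   `delta_effect`, `icer`, `incremental_nmb`, `dominance`, `wtp`).
#' @export
glance.ce_result <- function(x, ...) {
  tibble::tibble(
    delta_cost = x$delta_cost,
    delta_effect = x$delta_effect,
    icer = x$icer,
    incremental_nmb = x$incremental_nmb,
    dominance = x$dominance,
    wtp = x$wtp
  )
}

#' Cost-effectiveness plane for a comparison
#'
#' @param object A `ce_result` object.
#' @param ... Unused.
#' @return A ggplot showing both strategies on the cost-effect plane with the
#'   willingness-to-pay line through the comparator.
#' @export
autoplot.ce_result <- function(object, ...) {
  s <- object$strategies
  comp <- s[1, ]
  ggplot2::ggplot(s, ggplot2::aes(x = .data$effect, y = .data$cost,
                                  colour = .data$strategy)) +
    ggplot2::geom_abline(intercept = comp$cost - object$wtp * comp$effect,
                         slope = object$wtp, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "Discounted effect (extraction-free tooth-years)",
                  y = "Discounted cost",
                  colour = "Strategy",
                  title = "Cost-effectiveness plane",
                  subtitle = sprintf("Dashed line: WTP = %s per tooth-year",
                                     format(object$wtp, big.mark = " "))) +
    ggplot2::theme_minimal()
}
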