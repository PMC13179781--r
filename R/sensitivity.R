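#' One-way sensitivity analysis
#'
#' Re-runs the full two-strategy comparison with one scalar parameter set to
#' each value in turn, holding everything else at base. The input parameter
#' set is not modified.
#'
#' @param params A validated `ce_parameters` object.
#' @param name Flat parameter name (see [get_parameter()]), typically a unit
#'   cost such as `"c_sdf"`.
#' @param values Numeric vector of values to test.
#' @return A tibble with columns `parameter`, `value`, `icer`,
#'   `incremental_nmb`, and a `base_icer` attribute (the untouched base-case
#'   ICER).
#' @export
#' @examples
#' p <- generate_parameter_set(seed = 1)
#' one_way(p, "c_sdf", c(31, 39, 47))
one_way <- function(params, name, values) {
  params <- validate_parameters(params)
  get_parameter(params, name) # errors early on unknown names
  base <- base_case(params)
  res <- purrr::map_dfr(values, function(v) {
    r <- base_case(set_parameter(params, name, v))
    tibble::tibble(parameter = name, value = v, icer = r$icer,
                   incremental_nmb = r$incremental_nmb)
  })
  attr(res, "base_icer") <- base$icer
  res
}

#' One-way analysis over every cost parameter
#'
#' Evaluates the ICER at each cost parameter's low, base, and high value —
#' the three printed test points of a one-way sensitivity table.
#'
#' @param params A validated `ce_parameters` object.
#' @return A tibble (`parameter`, `value`, `icer`, `incremental_nmb`) with 15
#'   rows (5 parameters x 3 values) and a `base_icer` attribute.
#' @export
one_way_table <- function(params) {
  params <- validate_parameters(params)
  res <- purrr::map_dfr(cost_parameter_names(), function(nm) {
    i <- match(nm, params$costs$parameter)
    vals <- c(params$costs$low[i], params$costs$base[i], params$costs$high[i])
    one_way(params, nm, vals)
  })
  attr(res, "base_icer") <- base_case(params)$icer
  res
}

# Internal: implied standard deviation of a 95% interval under the normal
# approximation, the conventional reading of a published range.
ci_implied_sd <- function(lo, hi) (hi - lo) / (2 * stats::qnorm(0.975))

#' Fit a beta distribution to a mean and 95% interval
#'
#' Finds beta shape parameters whose distribution has exactly the requested
#' mean and whose central 95% interval matches the requested one as closely
#' as the family allows. The mean constraint leaves one degree of freedom
#' (`beta = alpha * (1 - mean) / mean`), which is refined one-dimensionally
#' from a method-of-moments warm start (implied variance
#' `((high - low) / 3.92)^2`).
#'
#' @param mean Target mean, strictly inside (0, 1).
#' @param ci_low,ci_high Target central 95% interval, inside \[0, 1\].
#' @return A list: `alpha`, `beta`, `mean`, `ci_achieved` (2.5% and 97.5%
#'   quantiles of the fit), `max_ci_error`.
#' @export
#' @examples
#' fit_beta(0.5, 0.3, 0.7)
fit_beta <- function(mean, ci_low, ci_high) {
  check_dist_spec("beta", mean, ci_low, ci_high, key = "fit_beta")
  sd0 <- ci_implied_sd(ci_low, ci_high)
  v0 <- min(sd0^2, 0.95 * mean * (1 - mean)) # beta variance bound
  alpha0 <- mean * (mean * (1 - mean) / v0 - 1)
  alpha0 <- max(alpha0, 1e-3)
  loss <- function(log_alpha) {
    a <- exp(log_alpha)
    b <- a * (1 - mean) / mean
    (qbeta(0.025, a, b) - ci_low)^2 + (qbeta(0.975, a, b) - ci_high)^2
  }
  opt <- stats::optimize(loss, interval = log(alpha0) + c(-8, 8))
  alpha <- exp(opt$minimum)
  beta <- alpha * (1 - mean) / mean
  ci <- qbeta(c(0.025, 0.975), alpha, beta)
  list(alpha = alpha, beta = beta, mean = mean, ci_achieved = ci,
       max_ci_error = max(abs(ci - c(ci_low, ci_high))))
}

#' Fit a gamma distribution to a mean and 95% interval
#'
#' Same contract as [fit_beta()] for the gamma family: the mean is matched
#' exactly (`scale = mean / shape`), the shape is refined one-dimensionally
#' to reproduce the requested central 95% interval.
#'
#' @param mean Target mean, > 0.
#' @param ci_low,ci_high Target central 95% interval, `0 <= ci_low < ci_high`.
#' @return A list: `shape`, `scale`, `mean`, `ci_achieved`, `max_ci_error`.
#' @export
#' @examples
#' fit_gamma(39, 31, 47)
fit_gamma <- function(mean, ci_low, ci_high) {
  check_dist_spec("gamma", mean, ci_low, ci_high, key = "fit_gamma")
  sd0 <- ci_implied_sd(ci_low, ci_high)
  shape0 <- max((mean / sd0)^2, 1e-3)
  loss <- function(log_shape) {
    k <- exp(log_shape)
    th <- mean / k
    (qgamma(0.025, shape = k, scale = th) - ci_low)^2 +
      (qgamma(0.975, shape = k, scale = th) - ci_high)^2
  }
  opt <- stats::optimize(loss, interval = log(shape0) + c(-8, 8))
  shape <- exp(opt$minimum)
  scale <- mean / shape
  ci <- qgamma(c(0.025, 0.975), shape = shape, scale = scale)
  list(shape = shape, scale = scale, mean = mean, ci_achieved = ci,
       max_ci_error = max(abs(ci - c(ci_low, ci_high))))
}

# Internal: deterministic per-parameter substream seed. A single root seed
# spawns one substream per (parameter, round) in a name-keyed order, so adding
# or removing a parameter never perturbs another parameter's draws.
substream_seed <- function(seed, name, round = 1L) {
  codes <- utf8ToInt(name)
  h <- 0
  for (k in seq_along(codes)) {
    h <- (h * 131 + codes[k]) %% 2147483647
  }
  as.integer((h + seed * 2654435 + round * 97561) %% 2147483647)
}

#' Draw parameter sets for probabilistic sensitivity analysis
#'
#' Draws `n` complete parameter sets: each parameter named in the PSA
#' specification table is sampled independently from its fitted beta
#' (probabilities, utilities) or gamma (costs) distribution; parameters
#' without a specification stay at base. Draws that violate a structural
#' constraint (for example arrest plus extraction exceeding 1) are rejected
#' and redrawn, truncating the joint distribution to the feasible region.
#' The draw stream is a pure function of `seed`.
#'
#' @param params A validated `ce_parameters` object with a non-empty `psa`
#'   table.
#' @param n Number of draws (the published analysis used 1000).
#' @param seed Integer root seed.
#' @return A list of `n` validated `ce_parameters` objects.
#' @export
draw_psa <- function(params, n = 1000L, seed = 1L) {
  params <- validate_parameters(params)
  spec <- params$psa
  if (!nrow(spec)) {
    abort("No PSA specifications configured on this parameter set.",
          class = "rootcea_config_error")
  }
  fits <- lapply(seq_len(nrow(spec)), function(i) {
    if (spec$family[i] == "beta") {
      c(list(family = "beta"),
        fit_beta(spec$mean[i], spec$ci_low[i], spec$ci_high[i]))
    } else {
      c(list(family = "gamma"),
        fit_gamma(spec$mean[i], spec$ci_low[i], spec$ci_high[i]))
    }
  })
  names(fits) <- spec$parameter

  draw_round <- function(m, round) {
    draws <- matrix(0, nrow = m, ncol = nrow(spec),
                    dimnames = list(NULL, spec$parameter))
    for (nm in spec$parameter) {
      f <- fits[[nm]]
      set.seed(substream_seed(seed, nm, round))
      draws[, nm] <- if (f$family == "beta") {
        rbeta(m, f$alpha, f$beta)
      } else {
        rgamma(m, shape = f$shape, scale = f$scale)
      }
    }
    draws
  }

  build <- function(row) {
    p <- params
    for (nm in names(row)) p <- set_parameter_impl(p, nm, row[[nm]])
    validate_parameters(p)
  }
  draws <- draw_round(n, 1L)
  out <- vector("list", n)
  pending <- seq_len(n)
  round <- 1L
  while (length(pending)) {
    for (j in seq_along(pending)) {
      i <- pending[j]
      cand <- tryCatch(build(draws[j, ]), error = function(e) NULL)
      if (!is.null(cand)) {
        out[[i]] <- cand
        pending[j] <- NA_integer_
      }
    }
    pending <- pending[!is.na(pending)]
    if (length(pending)) {
      round <- round + 1L
      if (round > 100L) {
        abort("PSA rejection sampling failed to find feasible draws.",
              class = "rootcea_config_error")
      }
      draws <- draw_round(length(pending), round)
    }
  }
  out
}

#' Evaluate the model on a set of PSA draws
#'
#' Runs both strategies on every drawn parameter set and records the
#' discounted (cost, effect) pair per strategy per draw. Evaluation is
#' stateless: each draw is independent of the others.
#'
#' @param draws A list of `ce_parameters` objects from [draw_psa()].
#' @return A `psa_result` tibble: `draw`, `strategy`, `cost`, `effect`.
#' @export
run_psa <- function(draws) {
  if (!length(draws)) abort("`draws` must be a non-empty list.")
  res <- purrr::map_dfr(seq_along(draws), function(i) {
    r <- tryCatch(
      evaluate_strategies(draws[[i]]),
      error = function(e) {
        abort(sprintf("Model evaluation failed on PSA draw %d: %s",
                      i, conditionMessage(e)))
      }
    )
    dplyr::mutate(r, draw = i, .before = 1)
  })
  class(res) <- c("psa_result", class(res))
  res
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value on the grid, computes the fraction of
#' PSA draws in which each strategy has the strictly highest net monetary
#' benefit; exact ties contribute equally to the tied strategies, so the
#' probabilities sum to 1 at every grid point.
#'
#' @param psa A `psa_result` tibble from [run_psa()].
#' @param wtp_grid Ascending numeric grid of willingness-to-pay values.
#' @return A `ceac_curve` tibble: `wtp`, `strategy`, `probability`.
#' @export
ceac <- function(psa, wtp_grid) {
  if (!nrow(psa)) abort("`psa` must be non-empty.")
  if (!length(wtp_grid)) abort("`wtp_grid` must be non-empty.")
  if (is.unsorted(wtp_grid)) abort("`wtp_grid` must be sorted ascending.")
  wide <- tidyr::pivot_wider(psa, id_cols = "draw",
                             names_from = "strategy",
                             values_from = c("cost", "effect"))
  strat <- unique(psa$strategy)
  res <- purrr::map_dfr(wtp_grid, function(w) {
    nmb <- sapply(strat, function(s) {
      w * wide[[paste0("effect_", s)]] - wide[[paste0("cost_", s)]]
    })
    if (is.null(dim(nmb))) nmb <- matrix(nmb, nrow = 1)
    best <- apply(nmb, 1, max)
    is_best <- nmb == best
    share <- is_best / rowSums(is_best) # ties split equally
    tibble::tibble(wtp = w, strategy = strat,
                   probability = colMeans(share))
  })
  class(res) <- c("ceac_curve", class(res))
  res
}

#' Acceptability crossover willingness-to-pay
#'
#' The smallest willingness-to-pay at which a strategy's acceptability
#' reaches 0.5, linearly interpolated between the bracketing grid points.
#' Under mean-preserving parameter uncertainty this sits close to the
#' deterministic ICER of the strategy pair.
#'
#' @param curve A `ceac_curve` tibble from [ceac()].
#' @param strategy Strategy whose crossover is sought (default `"SDF"`).
#' @return The crossover WTP, or `NA` (with attribute `found = FALSE`) when
#'   the curve never reaches 0.5 on the grid.
#' @export
ceac_crossover <- function(curve, strategy = "SDF") {
  s <- match_strategy(strategy)
  cc <- curve[curve$strategy == s, ]
  cc <- cc[order(cc$wtp), ]
  at <- which(cc$probability >= 0.5)
  if (!length(at)) {
    return(structure(NA_real_, found = FALSE))
  }
  i <- at[1]
  if (i == 1L) {
    return(structure(cc$wtp[1], found = TRUE))
  }
  p0 <- cc$probability[i - 1]; p1 <- cc$probability[i]
  w0 <- cc$wtp[i - 1]; w1 <- cc$wtp[i]
  w <- if (p1 > p0) w0 + (0.5 - p0) / (p1 - p0) * (w1 - w0) else w1
  structure(w, found = TRUE)
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param object A `ceac_curve` tibble.
#' @param ... Unused.
#' @return A ggplot: acceptability probability against willingness-to-pay,
#'   one line per strategy.
#' @export
autoplot.ceac_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wtp, y = .data$probability,
                                       colour = .data$strategy)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted",
                        colour = "grey40") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness-to-pay per extraction-free tooth-year",
                  y = "Probability cost-effective",
                  colour = "Strategy",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' Scatter of PSA draws on the cost-effectiveness plane
#'
#' @param object A `psa_result` tibble.
#' @param ... Unused.
#' @return A ggplot of per-draw (effect, cost) pairs by strategy.
#' @export
autoplot.psa_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$effect, y = .data$cost,
                                       colour = .data$strategy)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "Discounted effect (extraction-free tooth-years)",
                  y = "Discounted cost", colour = "Strategy",
                  title = "Probabilistic sensitivity analysis draws") +
    ggplot2::theme_minimal()
}
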