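test_that("one-way analysis at the base value reproduces the base-case ICER", {
  p <- test_params(seed = 1)
  base_icer <- base_case(p)$icer
  res <- one_way(p, "c_exam", c(27, 36, 45))
  expect_equal(res$icer[res$value == 36], base_icer, tolerance = 1e-12)
  expect_equal(attr(res, "base_icer"), base_icer)
  expect_error(one_way(p, "c_unknown", 1), class = "rootcea_lookup_error")
})

test_that("one-way table covers every cost parameter at low/base/high", {
  p <- manual_params()
  tab <- one_way_table(p)
  expect_equal(nrow(tab), 15)
  expect_setequal(unique(tab$parameter),
                  c("c_sdf", "c_naf", "c_exam", "c_xray", "c_access"))
  # intervention-cost rows rise with the price; comparator-cost rows fall
  sdf_rows <- tab[tab$parameter == "c_sdf", ]
  expect_true(all(diff(sdf_rows$icer[order(sdf_rows$value)]) > 0))
  naf_rows <- tab[tab$parameter == "c_naf", ]
  expect_true(all(diff(naf_rows$icer[order(naf_rows$value)]) < 0))
})

test_that("beta fits match a symmetric target and round-trip their own
           quantiles", {
  sym <- fit_beta(0.5, 0.3, 0.7)
  expect_equal(sym$alpha, sym$beta, tolerance = 1e-6)

  # fixed point: a CI generated by a beta distribution is recovered
  a <- 12; b <- 30
  ci <- qbeta(c(0.025, 0.975), a, b)
  fit <- fit_beta(a / (a + b), ci[1], ci[2])
  expect_lt(fit$max_ci_error, 1e-3)
  expect_equal(fit$alpha / (fit$alpha + fit$beta), a / (a + b),
               tolerance = 1e-12) # mean is matched exactly

  expect_error(fit_beta(0.5, 0.4, 0.4)) # degenerate interval
  expect_error(fit_beta(1.2, 0.1, 0.9))
})

test_that("gamma fits hold the mean exactly and reproduce requested
           quantiles", {
  shape <- 23; scale <- 1.7
  ci <- qgamma(c(0.025, 0.975), shape = shape, scale = scale)
  fit <- fit_gamma(shape * scale, ci[1], ci[2])
  expect_lt(fit$max_ci_error, 1e-3)
  expect_equal(fit$shape * fit$scale, shape * scale, tolerance = 1e-9)
  expect_error(fit_gamma(0, 1, 2))
})

test_that("PSA draws are reproducible and parameter-stable under the
           substream protocol", {
  p <- test_params(seed = 2)
  d1 <- draw_psa(p, n = 8, seed = 77)
  d2 <- draw_psa(p, n = 8, seed = 77)
  expect_equal(d1, d2)
  d3 <- draw_psa(p, n = 8, seed = 78)
  expect_false(isTRUE(all.equal(
    get_parameter(d1[[1]], "SDF.p_arrest"),
    get_parameter(d3[[1]], "SDF.p_arrest")
  )))

  # dropping a parameter's spec must not perturb the other substreams
  q <- p
  q$psa <- q$psa[q$psa$parameter != "c_access", ]
  d4 <- draw_psa(q, n = 8, seed = 77)
  expect_equal(get_parameter(d4[[3]], "SDF.p_arrest"),
               get_parameter(d1[[3]], "SDF.p_arrest"))
  expect_equal(get_parameter(d4[[3]], "c_access"),
               get_parameter(p, "c_access")) # held at base without a spec
})

test_that("empirical PSA draw means converge to the specified means", {
  p <- test_params(seed = 2)
  n <- 2000L
  draws <- draw_psa(p, n = n, seed = 5)
  for (nm in c("SDF.p_arrest", "NAF.p_extract_caries", "c_sdf", "c_access")) {
    i <- match(nm, p$psa$parameter)
    vals <- vapply(draws, get_parameter, numeric(1), name = nm)
    sd_spec <- ci_implied_sd_for_test(p$psa$family[i], p$psa$mean[i],
                                      p$psa$ci_low[i], p$psa$ci_high[i])
    expect_lt(abs(mean(vals) - p$psa$mean[i]), 3 * sd_spec / sqrt(n))
  }
})

test_that("model evaluation on draws is stateless and base draws reproduce
           the base case", {
  p <- manual_params()
  p$psa <- build_psa_specs(p)
  p <- validate_parameters(p)
  base <- evaluate_strategies(p)
  res <- run_psa(list(p, p))
  expect_equal(res$cost[res$draw == 1], base$cost)
  expect_equal(res$cost[res$draw == 2], base$cost)
  expect_equal(res$effect[res$draw == 1], base$effect)

  draws <- draw_psa(p, n = 4, seed = 3)
  r1 <- run_psa(draws)
  r2 <- run_psa(c(draws, draws))
  expect_equal(r2[r2$draw <= 4, ], r1, ignore_attr = TRUE)
})

test_that("the acceptability curve is a pointwise partition and is monotone
           for the more effective strategy", {
  p <- test_params(seed = 1)
  psa <- run_psa(draw_psa(p, n = 60, seed = 11))
  grid <- seq(0, 20000, by = 500)
  curve <- ceac(psa, grid)
  sums <- tapply(curve$probability, curve$wtp, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  p_sdf <- curve$probability[curve$strategy == "SDF"]
  p_naf <- curve$probability[curve$strategy == "NAF"]
  expect_true(all(diff(p_sdf) >= -1e-12))
  expect_true(all(diff(p_naf) <= 1e-12))
  expect_true(all(curve$probability >= 0 & curve$probability <= 1))
})

test_that("at zero WTP the cheaper strategy wins each draw; a single draw
           yields a step at its ICER", {
  pair <- tibble::tibble(
    draw = c(1L, 1L), strategy = c("NAF", "SDF"),
    cost = c(100, 300), effect = c(1, 3)
  )
  class(pair) <- c("psa_result", class(pair))
  curve <- ceac(pair, c(0, 50, 99, 101, 200))
  at0 <- curve[curve$wtp == 0, ]
  expect_equal(at0$probability[at0$strategy == "NAF"], 1)
  # draw ICER = 200/2 = 100: SDF wins strictly above it
  expect_equal(curve$probability[curve$strategy == "SDF" & curve$wtp == 99], 0)
  expect_equal(curve$probability[curve$strategy == "SDF" & curve$wtp == 101], 1)
  expect_equal(as.numeric(ceac_crossover(curve, "SDF")), 100)
  expect_error(ceac(pair, numeric(0)))
})

test_that("crossover detection interpolates and flags missing crossings", {
  curve <- tibble::tibble(
    wtp = rep(c(0, 100, 200), each = 2),
    strategy = rep(c("NAF", "SDF"), 3),
    probability = c(1, 0, 0.6, 0.4, 0.2, 0.8)
  )
  class(curve) <- c("ceac_curve", class(curve))
  w <- ceac_crossover(curve, "SDF")
  expect_equal(as.numeric(w), 125) # linear between (100, .4) and (200, .8)

  always <- curve; always$probability <- rep(c(0, 1), 3)
  expect_equal(as.numeric(ceac_crossover(always, "SDF")), 0)

  never <- curve; never$probability <- rep(c(1, 0), 3)
  expect_true(is.na(ceac_crossover(never, "SDF")))
  expect_false(attr(ceac_crossover(never, "SDF"), "found"))
})
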