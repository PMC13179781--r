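test_that("discount factors match the closed form", {
  expect_equal(discount_factor(0.03, 0), 1)
  expect_equal(discount_factor(0.03, 1), 1 / 1.03)
  expect_equal(discount_factor(0.03, 1), 0.970874, tolerance = 1e-6)
  expect_equal(discount_factor(0.03, 19), 1.03^-19)
  expect_equal(discount_factor(0.03, 19), 0.570286, tolerance = 1e-6)
  expect_equal(discount_factor(0, 7), 1)
  expect_error(discount_factor(0.03, -1))
  expect_error(discount_factor(-0.01, 1))
})

test_that("zero-cost parameters accrue zero cost", {
  p <- manual_params()
  p$costs$base <- rep(0, 5)
  p$costs$low <- rep(0, 5)
  p$costs$high <- rep(0, 5)
  p <- validate_parameters(p)
  sr <- accrue(run_cohort(p, "SDF"), p, "SDF")
  expect_equal(sr$cost, 0)
})

test_that("with no extraction, unit utilities and no discounting the effect
           equals the full horizon", {
  p <- manual_params(
    sdf = list(p_incidence_tx = 0.05, p_extract_nocaries = 0, p_arrest = 0.6,
               p_extract_caries = 0),
    naf = list(p_incidence_tx = 0.1, p_extract_nocaries = 0, p_arrest = 0,
               p_extract_caries = 0),
    settings = list(discount_rate = 0, effect_aggregation = "per_tooth_mean")
  )
  sr <- accrue(run_cohort(p, "SDF"), p, "SDF")
  expect_equal(sr$effect, 19)
})

test_that("with no extraction the discounted effect is the geometric
           half-cycle annuity", {
  p <- manual_params(
    sdf = list(p_incidence_tx = 0.05, p_extract_nocaries = 0, p_arrest = 0.6,
               p_extract_caries = 0),
    naf = list(p_incidence_tx = 0.1, p_extract_nocaries = 0, p_arrest = 0,
               p_extract_caries = 0)
  )
  sr <- accrue(run_cohort(p, "SDF"), p, "SDF")
  k <- 1:38
  expect_equal(sr$effect, sum(0.5 * 1.03^(-k / 2)), tolerance = 1e-12)

  # discounting can only shrink the effect
  p0 <- p; p0$settings$discount_rate <- 0
  sr0 <- accrue(run_cohort(validate_parameters(p0), "SDF"),
                validate_parameters(p0), "SDF")
  expect_lt(sr$effect, sr0$effect)
})

test_that("trajectory length mismatches are rejected", {
  p <- manual_params()
  traj <- run_cohort(p, "SDF")
  expect_error(accrue(traj[-1, ], p, "SDF"), "half-cycle boundaries")
})

test_that("aggregation switches scale costs and effects by the tooth count", {
  p <- manual_params()
  pc <- p
  pc$settings$cost_aggregation <- "per_tooth_mean"
  pc$settings$effect_aggregation <- "cohort_sum"
  pc <- validate_parameters(pc)
  a <- accrue(run_cohort(p, "SDF"), p, "SDF")
  b <- accrue(run_cohort(pc, "SDF"), pc, "SDF")
  n <- p$settings$n_teeth
  expect_equal(a$cost, b$cost * n, tolerance = 1e-12)
  expect_equal(b$effect, a$effect * n, tolerance = 1e-12)
})

test_that("compare reproduces simple incremental arithmetic and dominance", {
  a <- tibble::tibble(strategy = "NAF", cost = 100, effect = 2)
  same <- compare(a, dplyr::mutate(a, strategy = "SDF"), wtp = 1000)
  expect_equal(same$delta_cost, 0)
  expect_equal(same$delta_effect, 0)
  expect_equal(same$incremental_nmb, 0)
  expect_identical(same$dominance, "none")

  b <- tibble::tibble(strategy = "SDF", cost = 200, effect = 4)
  r <- compare(a, b, wtp = 1000)
  expect_equal(r$icer, 50)
  expect_equal(r$incremental_nmb, unname(r$nmb["SDF"] - r$nmb["NAF"]))

  dom <- compare(a, tibble::tibble(strategy = "SDF", cost = 50, effect = 4),
                 wtp = 1000)
  expect_identical(dom$dominance, "b_dominant")
  dominated <- compare(a, tibble::tibble(strategy = "SDF", cost = 150,
                                         effect = 1), wtp = 1000)
  expect_identical(dominated$dominance, "b_dominated")

  flat <- compare(a, tibble::tibble(strategy = "SDF", cost = 150, effect = 2),
                  wtp = 1000)
  expect_true(is.na(flat$icer)) # no division by a zero effect difference
  expect_identical(flat$dominance, "b_dominated")
})

test_that("compare is antisymmetric in its arguments", {
  a <- tibble::tibble(strategy = "NAF", cost = 8863, effect = 1.39)
  b <- tibble::tibble(strategy = "SDF", cost = 16660, effect = 7.73)
  ab <- compare(a, b, wtp = 50000)
  ba <- compare(b, a, wtp = 50000)
  expect_equal(ab$delta_cost, -ba$delta_cost)
  expect_equal(ab$delta_effect, -ba$delta_effect)
  expect_equal(ab$incremental_nmb, -ba$incremental_nmb)
})

test_that("incremental NMB sign agrees with WTP relative to the ICER", {
  set.seed(99)
  for (i in 1:20) {
    a <- tibble::tibble(strategy = "NAF", cost = runif(1, 0, 2e4),
                        effect = runif(1, 0, 5))
    b <- tibble::tibble(strategy = "SDF", cost = a$cost + runif(1, 1, 1e4),
                        effect = a$effect + runif(1, 0.1, 10))
    w <- runif(1, 0, 1e5)
    r <- compare(a, b, w)
    expect_equal(sign(r$incremental_nmb), sign(w - r$icer))
  }
})

test_that("effect decreases monotonically in every extraction probability", {
  for (nm in c("SDF.p_extract_nocaries", "SDF.p_extract_caries")) {
    effects <- vapply(c(0.02, 0.1, 0.3), function(v) {
      p <- set_parameter(manual_params(), nm, v)
      accrue(run_cohort(p, "SDF"), p, "SDF")$effect
    }, numeric(1))
    expect_true(all(diff(effects) < 0))
  }
})

test_that("tidy and glance expose the publication-shaped summaries", {
  res <- base_case(manual_params())
  td <- tidy(res)
  expect_named(td, c("strategy", "cost", "incremental_cost", "effect",
                     "incremental_effect", "icer", "nmb"))
  expect_equal(nrow(td), 2)
  expect_equal(td$strategy, c("NAF", "SDF"))
  gl <- glance(res)
  expect_equal(gl$icer, res$icer)
  expect_equal(gl$incremental_nmb, res$incremental_nmb)
  expect_s3_class(autoplot(res), "ggplot")
})
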