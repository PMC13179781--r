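test_that("initial distribution splits mass between the two disease states", {
  expect_equal(initial_distribution(0.68),
               occupancy(no_caries = 0.32, root_caries = 0.68))
  expect_equal(initial_distribution(0)[["NO_CARIES"]], 1)
  expect_equal(initial_distribution(1)[["ROOT_CARIES"]], 1)
  expect_error(initial_distribution(1.3))
  expect_error(initial_distribution(-0.1))
})

test_that("natural-history step only moves caries-free teeth to caries", {
  tp <- manual_params()$transition
  occ <- occupancy(no_caries = 1)
  tp0 <- tp; tp0$p_incidence_nat <- 0
  expect_equal(natural_history_step(occ, tp0), occ)

  tp3 <- tp; tp3$p_incidence_nat <- 0.3
  expect_equal(natural_history_step(occ, tp3),
               occupancy(no_caries = 0.7, root_caries = 0.3))

  mixed <- occupancy(no_caries = 0.2, root_caries = 0.3, extracted = 0.5)
  out <- natural_history_step(mixed, tp3)
  expect_equal(out[["EXTRACTED"]], 0.5) # absorbing mass untouched
  expect_equal(sum(out), 1)
})

test_that("treatment step follows the strategy-specific branch structure", {
  tp <- manual_params()$transition
  occ <- occupancy(root_caries = 1)
  out <- treatment_step(occ, tp, "SDF") # arrest .6, extract .1 -> persist .3
  expect_equal(unname(out),
               c(0, 0, 0.6, 0.3, 0.1))

  # all branch probabilities zero: caries mass all becomes persistent
  tp0 <- tp
  tp0$SDF <- list(p_incidence_tx = 0, p_extract_nocaries = 0, p_arrest = 0,
                  p_extract_caries = 0)
  mix <- occupancy(no_caries = 0.4, root_caries = 0.6)
  out0 <- treatment_step(mix, tp0, "SDF")
  expect_equal(out0[["NO_CARIES"]], 0.4)
  expect_equal(out0[["PERSISTENT"]], 0.6)

  # NaF never produces arrest
  out_naf <- treatment_step(occ, tp, "NAF")
  expect_equal(out_naf[["ARREST"]], 0)
  expect_error(treatment_step(occ, tp, "fluoride"))
})

test_that("cycle-start relabelling collapses transient states, conserving mass", {
  occ <- occupancy(no_caries = 0.2, root_caries = 0.1, arrest = 0.3,
                   persistent = 0.3, extracted = 0.1)
  expect_equal(relabel_cycle_start(occ),
               occupancy(no_caries = 0.5, root_caries = 0.4, extracted = 0.1))
  clean <- occupancy(no_caries = 0.7, root_caries = 0.2, extracted = 0.1)
  expect_equal(relabel_cycle_start(clean), clean)

  set.seed(42)
  for (i in 1:25) {
    occ <- random_occupancy()
    out <- relabel_cycle_start(occ)
    expect_equal(sum(out), 1, tolerance = 1e-12)
    expect_equal(out[["EXTRACTED"]], occ[["EXTRACTED"]])
    expect_equal(out[["ARREST"]] + out[["PERSISTENT"]], 0)
  }
})

test_that("cohort trajectories have the contracted length and conserve mass", {
  p <- test_params(seed = 1)
  for (s in strategies()) {
    traj <- run_cohort(p, s)
    expect_equal(nrow(traj),
                 p$settings$cycles_per_year * p$settings$horizon_years + 1)
    expect_true(all(abs(rowSums(occ_matrix(traj)) - 1) < 1e-12))
    expect_true(all(diff(traj$extracted) >= -1e-15)) # absorbing, monotone
  }

  p1 <- p; p1$settings$horizon_years <- 1L
  expect_equal(nrow(run_cohort(validate_parameters(p1), "SDF")), 3)
})

test_that("extraction mass stays zero when no extraction path is open", {
  p <- manual_params(
    sdf = list(p_incidence_tx = 0.05, p_extract_nocaries = 0,
               p_arrest = 0.6, p_extract_caries = 0),
    naf = list(p_incidence_tx = 0.1, p_extract_nocaries = 0,
               p_arrest = 0, p_extract_caries = 0)
  )
  for (s in strategies()) {
    expect_true(all(run_cohort(p, s)$extracted == 0))
  }
})

test_that("SDF keeps no more teeth in the extracted state than NaF when it
           can arrest and parameters are otherwise equal", {
  shared <- list(p_incidence_tx = 0.1, p_extract_nocaries = 0.02,
                 p_arrest = 0, p_extract_caries = 0.2)
  sdf <- shared; sdf$p_arrest <- 0.5
  p <- manual_params(sdf = sdf, naf = shared)
  t_sdf <- run_cohort(p, "SDF")
  t_naf <- run_cohort(p, "NAF")
  expect_true(all(t_sdf$extracted <= t_naf$extracted + 1e-12))
})

test_that("strategies with identical transition parameters yield identical
           trajectories", {
  shared <- list(p_incidence_tx = 0.08, p_extract_nocaries = 0.015,
                 p_arrest = 0, p_extract_caries = 0.25)
  p <- manual_params(sdf = shared, naf = shared)
  t_sdf <- run_cohort(p, "SDF")
  t_naf <- run_cohort(p, "NAF")
  expect_equal(occ_matrix(t_sdf), occ_matrix(t_naf), tolerance = 1e-15)
})

test_that("microsimulation is reproducible and matches the cohort exactly in
           the degenerate all-or-nothing case", {
  p <- test_params(seed = 4)
  a <- simulate_microsim(p, "SDF", n_teeth = 500, seed = 9)
  b <- simulate_microsim(p, "SDF", n_teeth = 500, seed = 9)
  expect_identical(a, b)

  pd <- manual_params(
    p_init = 1, p_nat = 0,
    sdf = list(p_incidence_tx = 0, p_extract_nocaries = 0, p_arrest = 1,
               p_extract_caries = 0),
    naf = list(p_incidence_tx = 0, p_extract_nocaries = 0, p_arrest = 0,
               p_extract_caries = 1)
  )
  for (s in strategies()) {
    ms <- simulate_microsim(pd, s, n_teeth = 50, seed = 1)
    co <- run_cohort(pd, s)
    expect_equal(occ_matrix(ms), occ_matrix(co), tolerance = 1e-15)
  }
})

test_that("cohort occupancies are the expectations of the microsimulation", {
  p <- test_params(seed = 1)
  n <- 20000L
  for (s in strategies()) {
    co <- occ_matrix(run_cohort(p, s))
    ms <- occ_matrix(simulate_microsim(p, s, n_teeth = n, seed = 123))
    se <- sqrt(co * (1 - co) / n)
    expect_true(all(abs(ms - co) <= 3 * se + 1e-12))
  }
})
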