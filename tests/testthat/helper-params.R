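# Shared fixtures built in code.

# A small deterministic parameter set used across tests.
test_params <- function(seed = 1L) {
  generate_parameter_set(seed = seed)
}

# A parameter set with hand-picked round transition probabilities, convenient
# for closed-form checks.
manual_params <- function(p_init = 0.68,
                          p_nat = 0.1,
                          sdf = list(p_incidence_tx = 0.05,
                                     p_extract_nocaries = 0.01,
                                     p_arrest = 0.6,
                                     p_extract_caries = 0.1),
                          naf = list(p_incidence_tx = 0.1,
                                     p_extract_nocaries = 0.01,
                                     p_arrest = 0,
                                     p_extract_caries = 0.3),
                          utilities = default_utilities_vec(),
                          settings = list()) {
  ce_parameters(
    transition = list(p_init_caries = p_init, p_incidence_nat = p_nat,
                      SDF = sdf, NAF = naf),
    costs = tibble::tibble(
      parameter = c("c_sdf", "c_naf", "c_exam", "c_xray", "c_access"),
      base = c(39, 33, 36, 45, 129),
      low = c(31, 27, 27, 37, 93),
      high = c(47, 39, 45, 53, 165)
    ),
    utilities = utilities,
    settings = settings
  )
}

default_utilities_vec <- function() {
  stats::setNames(c(1, 1, 1, 1, 0), health_states())
}

# Random valid occupancy vectors for property tests.
random_occupancy <- function() {
  x <- stats::runif(5)
  occupancy(no_caries = x[1] / sum(x), root_caries = x[2] / sum(x),
            arrest = x[3] / sum(x), persistent = x[4] / sum(x),
            extracted = x[5] / sum(x))
}

# Standard deviation of the fitted PSA distribution for a spec row.
ci_implied_sd_for_test <- function(family, mean, lo, hi) {
  if (family == "beta") {
    f <- fit_beta(mean, lo, hi)
    s <- f$alpha + f$beta
    sqrt(f$alpha * f$beta / (s^2 * (s + 1)))
  } else {
    f <- fit_gamma(mean, lo, hi)
    sqrt(f$shape) * f$scale
  }
}

occ_matrix <- function(traj) {
  as.matrix(traj[, c("no_caries", "root_caries", "arrest", "persistent",
                     "extracted")])
}
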