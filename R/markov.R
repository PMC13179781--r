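#' Initial occupancy of the tooth cohort
#'
#' At model start a tooth carries an active root-caries lesion with the
#' initial prevalence and is caries-free otherwise; no tooth starts arrested,
#' persistent, or extracted.
#'
#' @param p_init Initial root-caries prevalence in \[0, 1\].
#' @return A named occupancy vector.
#' @export
#' @examples
#' initial_distribution(0.68)
initial_distribution <- function(p_init) {
  if (!is.numeric(p_init) || length(p_init) != 1L || is.na(p_init) ||
      p_init < 0 || p_init > 1) {
    abort("`p_init` must be a probability in [0, 1].")
  }
  occupancy(no_caries = 1 - p_init, root_caries = p_init)
}

#' Natural-history half-cycle transition
#'
#' The first 6-month transition of each annual cycle: disease progresses with
#' no intervention. Caries-free teeth develop an active root-caries lesion
#' with probability `p_incidence_nat`; all other states are untouched (no
#' spontaneous remission, no extraction outside the treatment visit).
#'
#' @param occ Occupancy vector at the start of the half-cycle.
#' @param tp Transition-probability block (`params$transition`).
#' @return Occupancy at the end of the half-cycle.
#' @export
natural_history_step <- function(occ, tp) {
  check_occupancy(occ)
  p <- tp$p_incidence_nat
  out <- occ
  out[["NO_CARIES"]] <- occ[["NO_CARIES"]] * (1 - p)
  out[["ROOT_CARIES"]] <- occ[["ROOT_CARIES"]] + occ[["NO_CARIES"]] * p
  out
}

#' Treatment half-cycle transition
#'
#' The second 6-month transition: the assigned strategy is applied at the
#' semiannual visit. Caries-free teeth stay caries-free, develop a lesion
#' (`p_incidence_tx`, the strategy's preventive failure rate), or are
#' extracted (`p_extract_nocaries`; extraction in this safety-net setting is
#' not restricted to root-caries aetiology). Teeth with an active lesion are
#' arrested (`p_arrest`), extracted (`p_extract_caries`), or remain persistent
#' (the remainder). Under NaF the arrest branch is structurally closed — a
#' carious tooth either persists or is extracted.
#'
#' @param occ Occupancy vector entering the treatment visit.
#' @param tp Transition-probability block (`params$transition`).
#' @param strategy `"SDF"` or `"NAF"`.
#' @return Occupancy at the end of the half-cycle.
#' @export
treatment_step <- function(occ, tp, strategy) {
  check_occupancy(occ)
  s <- match_strategy(strategy)
  b <- tp[[s]]
  nc <- occ[["NO_CARIES"]]
  rc <- occ[["ROOT_CARIES"]]
  out <- occ
  out[["NO_CARIES"]] <- nc * (1 - b$p_incidence_tx - b$p_extract_nocaries)
  out[["ROOT_CARIES"]] <- nc * b$p_incidence_tx
  out[["ARREST"]] <- occ[["ARREST"]] + rc * b$p_arrest
  out[["PERSISTENT"]] <- occ[["PERSISTENT"]] +
    rc * (1 - b$p_arrest - b$p_extract_caries)
  out[["EXTRACTED"]] <- occ[["EXTRACTED"]] + nc * b$p_extract_nocaries +
    rc * b$p_extract_caries
  out
}

#' Cycle-start relabelling
#'
#' At the beginning of each annual cycle the transient post-treatment states
#' are folded back onto the two disease states: arrested teeth are counted as
#' caries-free, persistent lesions as active root caries. Extracted teeth stay
#' extracted. Total mass is conserved.
#'
#' @param occ Occupancy vector at the end of a treatment half-cycle.
#' @return Occupancy with `ARREST` and `PERSISTENT` emptied.
#' @export
relabel_cycle_start <- function(occ) {
  check_occupancy(occ)
  out <- occ
  out[["NO_CARIES"]] <- occ[["NO_CARIES"]] + occ[["ARREST"]]
  out[["ROOT_CARIES"]] <- occ[["ROOT_CARIES"]] + occ[["PERSISTENT"]]
  out[["ARREST"]] <- 0
  out[["PERSISTENT"]] <- 0
  out
}

#' Run the Markov cohort model for one strategy
#'
#' Evolves the expected occupancy of a single tooth from the initial
#' distribution through `horizon_years` annual cycles, each a natural-history
#' half-cycle followed by a treatment half-cycle, with the transient states
#' relabelled at every cycle start. Occupancy is recorded at the initial
#' boundary and at the end of each half-cycle (before relabelling), giving
#' `2 * horizon_years + 1` rows.
#'
#' Each recorded boundary also carries its undiscounted per-tooth accruals for
#' that half-cycle: `effect` is half a year weighted by the utility-weighted
#' non-extracted occupancy; `cost` is the per-tooth application cost plus the
#' allocated share of visit-level costs (see [ce_parameters()] for the
#' allocation and schedule switches). The initial boundary accrues nothing.
#'
#' @param params A validated `ce_parameters` object.
#' @param strategy `"SDF"` or `"NAF"`.
#' @return A tibble with columns `half_cycle` (0-based), `time_years`,
#'   `phase` (`"initial"`, `"natural"`, `"treatment"`), the five state
#'   occupancies (lower-case column names), and undiscounted `cost` and
#'   `effect` accruals for the step ending at that boundary.
#' @export
#' @examples
#' traj <- run_cohort(generate_parameter_set(seed = 1), "SDF")
#' head(traj)
run_cohort <- function(params, strategy) {
  params <- validate_parameters(params)
  s <- match_strategy(strategy)
  tp <- params$transition
  st <- params$settings
  n_years <- st$horizon_years
  n_steps <- 2L * n_years

  occ <- initial_distribution(tp$p_init_caries)
  occs <- matrix(0, nrow = n_steps + 1L, ncol = 5L,
                 dimnames = list(NULL, health_states()))
  occs[1L, ] <- occ
  phase <- c("initial", rep(c("natural", "treatment"), n_years))
  for (y in seq_len(n_years)) {
    occ <- natural_history_step(occ, tp)
    occs[2L * y, ] <- occ
    occ <- treatment_step(occ, tp, s)
    occs[2L * y + 1L, ] <- occ
    occ <- relabel_cycle_start(occ)
  }

  acc <- step_accruals(occs, phase, params, s)
  tibble::tibble(
    half_cycle = 0:n_steps,
    time_years = (0:n_steps) / 2,
    phase = phase,
    no_caries = occs[, "NO_CARIES"],
    root_caries = occs[, "ROOT_CARIES"],
    arrest = occs[, "ARREST"],
    persistent = occs[, "PERSISTENT"],
    extracted = occs[, "EXTRACTED"],
    cost = acc$cost,
    effect = acc$effect
  )
}

# Internal: undiscounted per-tooth cost and effect accrued over the step that
# ends at each recorded boundary. Effect: 0.5 y times utility-weighted
# occupancy at the boundary. Cost: application cost per non-extracted tooth
# plus the tooth's share of visit-level costs, at each visit boundary per the
# cost schedule.
step_accruals <- function(occs, phase, params, strategy) {
  st <- params$settings
  u <- params$utilities[health_states()]
  cost_of <- function(nm) {
    params$costs$base[match(nm, params$costs$parameter)]
  }
  c_app <- if (strategy == "SDF") cost_of("c_sdf") else cost_of("c_naf")
  c_visit <- cost_of("c_exam") + cost_of("c_xray") + cost_of("c_access")

  n <- nrow(occs)
  weighted <- as.numeric(occs %*% u)
  surviving <- 1 - occs[, "EXTRACTED"]
  effect <- 0.5 * weighted
  effect[1L] <- 0

  visit_boundary <- if (st$cost_schedule == "semiannual") {
    phase %in% c("natural", "treatment")
  } else {
    phase == "treatment"
  }
  app_cost <- c_app * surviving
  visit_share <- switch(
    st$cost_allocation,
    per_tooth = c_visit / st$n_teeth * surviving,
    # shared: the full visit fee is incurred while at least one of the
    # subject's teeth remains; expressed per tooth for the per-tooth stream
    per_visit_shared =
      c_visit / st$n_teeth * (1 - occs[, "EXTRACTED"]^st$n_teeth)
  )
  cost <- ifelse(visit_boundary, app_cost + visit_share, 0)
  cost[1L] <- 0
  list(cost = cost, effect = effect)
}

#' Microsimulation cross-check of the cohort model
#'
#' Simulates `n_teeth` independent tooth histories with the same transition
#' rules as [run_cohort()] and returns empirical occupancy fractions at every
#' half-cycle boundary. Used as a stochastic oracle: cohort occupancies are
#' the exact expectations of these fractions, so the two agree within binomial
#' sampling error.
#'
#' @param params A validated `ce_parameters` object.
#' @param strategy `"SDF"` or `"NAF"`.
#' @param n_teeth Number of simulated teeth.
#' @param seed Integer seed; the run is fully reproducible.
#' @return A tibble shaped like [run_cohort()]'s occupancy columns
#'   (`half_cycle`, `time_years`, `phase`, five state fractions).
#' @export
simulate_microsim <- function(params, strategy, n_teeth = 10000L, seed = 1L) {
  params <- validate_parameters(params)
  s <- match_strategy(strategy)
  if (n_teeth < 1L) abort("`n_teeth` must be at least 1.")
  tp <- params$transition
  b <- tp[[s]]
  n_years <- params$settings$horizon_years

  set.seed(seed)
  # state codes 1..5 in canonical order
  state <- ifelse(runif(n_teeth) < tp$p_init_caries, 2L, 1L)
  record <- matrix(0L, nrow = 2L * n_years + 1L, ncol = 5L,
                   dimnames = list(NULL, health_states()))
  tallies <- function(state) tabulate(state, nbins = 5L)
  record[1L, ] <- tallies(state)

  for (y in seq_len(n_years)) {
    # natural history: NO_CARIES -> ROOT_CARIES
    i <- state == 1L
    state[i][runif(sum(i)) < tp$p_incidence_nat] <- 2L
    record[2L * y, ] <- tallies(state)
    # treatment visit (branch index sets fixed before any reassignment)
    i_nc <- which(state == 1L)
    i_rc <- which(state == 2L)
    if (length(i_nc)) {
      u <- runif(length(i_nc))
      new <- rep(1L, length(i_nc))
      new[u < b$p_incidence_tx] <- 2L
      new[u >= b$p_incidence_tx &
            u < b$p_incidence_tx + b$p_extract_nocaries] <- 5L
      state[i_nc] <- new
    }
    if (length(i_rc)) {
      u <- runif(length(i_rc))
      new <- rep(4L, length(i_rc))
      new[u < b$p_arrest] <- 3L
      new[u >= b$p_arrest & u < b$p_arrest + b$p_extract_caries] <- 5L
      state[i_rc] <- new
    }
    record[2L * y + 1L, ] <- tallies(state)
    # cycle-start relabelling
    state[state == 3L] <- 1L
    state[state == 4L] <- 2L
  }

  frac <- record / n_teeth
  tibble::tibble(
    half_cycle = 0:(2L * n_years),
    time_years = (0:(2L * n_years)) / 2,
    phase = c("initial", rep(c("natural", "treatment"), n_years)),
    no_caries = frac[, "NO_CARIES"],
    root_caries = frac[, "ROOT_CARIES"],
    arrest = frac[, "ARREST"],
    persistent = frac[, "PERSISTENT"],
    extracted = frac[, "EXTRACTED"]
  )
}
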