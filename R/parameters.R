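#' Assemble a validated model parameter set
#'
#' A `ce_parameters` object is the single source of truth for one model run:
#' semiannual transition probabilities, unit costs with one-way ranges,
#' per-state utility weights, economic settings, and the beta/gamma
#' distribution specifications used by probabilistic sensitivity analysis.
#' All probabilities are stored per 6-month transition, the model's native
#' step; nothing is annualised.
#'
#' @param transition A list with elements `p_init_caries` (initial root-caries
#'   prevalence), `p_incidence_nat` (no-caries to root-caries in the
#'   natural-history half-cycle), and for each strategy (`SDF`, `NAF`) a list
#'   with `p_incidence_tx`, `p_extract_nocaries`, `p_arrest`,
#'   `p_extract_caries`. `NAF$p_arrest` must be 0: the varnish is modelled as
#'   preventive only, with no lesion-arrest pathway.
#' @param costs A data frame with columns `parameter`
#'   (`c_sdf`, `c_naf`, `c_exam`, `c_xray`, `c_access`), `base`, `low`,
#'   `high` — unit costs per application or per visit with their one-way
#'   sensitivity ranges, in the currency given by `currency`.
#' @param utilities Named numeric vector of per-state effect weights in
#'   \[0, 1\]; `EXTRACTED` must be 0. Defaults to 1 for every non-extracted
#'   state (plain extraction-free tooth-years).
#' @param settings A list of economic settings; see Details.
#' @param psa A data frame of distribution specifications with columns
#'   `parameter`, `family` (`"beta"` or `"gamma"`), `mean`, `ci_low`,
#'   `ci_high`. Each `mean` must equal the corresponding base value. May be
#'   empty (no probabilistic analysis configured).
#' @param currency Currency label for all costs.
#'
#' @details
#' `settings` elements (with defaults):
#' \describe{
#'   \item{discount_rate}{Annual discount rate for costs and effects (0.03).}
#'   \item{horizon_years}{Model horizon in years (19).}
#'   \item{cycles_per_year}{Half-cycles per year; fixed at 2 (a natural-history
#'     and a treatment 6-month transition).}
#'   \item{n_teeth}{Teeth per subject (21).}
#'   \item{start_age}{Subject age at model start (45).}
#'   \item{wtp}{Willingness-to-pay per effect unit (50000).}
#'   \item{cost_allocation}{How visit-level costs (exam, radiography,
#'     care-assistance/transport) are allocated: `"per_tooth"` divides each
#'     visit's cost equally over the `n_teeth` teeth and charges the share for
#'     every non-extracted tooth; `"per_visit_shared"` charges the full visit
#'     cost once per visit while the subject still has at least one
#'     non-extracted tooth.}
#'   \item{cost_aggregation, effect_aggregation}{`"cohort_sum"` scales the
#'     per-tooth expectation by `n_teeth`; `"per_tooth_mean"` reports the
#'     per-tooth expectation. Defaults: costs as cohort sums, effects as
#'     per-tooth means.}
#'   \item{cost_schedule}{`"semiannual"` accrues application and visit costs at
#'     both half-cycle boundaries of each year (twice-yearly visits);
#'     `"annual"` accrues them at the treatment half-cycle only.}
#' }
#'
#' @return A validated object of class `ce_parameters`.
#' @seealso [read_parameters()], [write_parameters()], [default_parameters()],
#'   [generate_parameter_set()]
#' @export
ce_parameters <- function(transition,
                          costs,
                          utilities = default_utilities(),
                          settings = list(),
                          psa = empty_psa_spec(),
                          currency = "2025 US$") {
  settings <- modifyList(default_settings(), as.list(settings))
  params <- structure(
    list(
      transition = transition,
      costs = tibble::as_tibble(costs),
      utilities = utilities,
      settings = settings,
      psa = tibble::as_tibble(psa),
      currency = currency
    ),
    class = "ce_parameters"
  )
  validate_parameters(params)
}

default_settings <- function() {
  list(
    discount_rate = 0.03,
    horizon_years = 19L,
    cycles_per_year = 2L,
    n_teeth = 21L,
    start_age = 45L,
    wtp = 50000,
    cost_allocation = "per_tooth",
    cost_aggregation = "cohort_sum",
    effect_aggregation = "per_tooth_mean",
    cost_schedule = "semiannual"
  )
}

default_utilities <- function() {
  setNames(c(1, 1, 1, 1, 0), health_states())
}

empty_psa_spec <- function() {
  tibble::tibble(parameter = character(), family = character(),
                 mean = numeric(), ci_low = numeric(), ci_high = numeric())
}

cost_parameter_names <- function() {
  c("c_sdf", "c_naf", "c_exam", "c_xray", "c_access")
}

strategy_transition_names <- function() {
  c("p_incidence_tx", "p_extract_nocaries", "p_arrest", "p_extract_caries")
}

#' Validate a model parameter set
#'
#' Enforces every structural invariant: probabilities in \[0, 1\] with branch
#' masses summing to at most 1, the structural zero on NaF arrest, cost ranges
#' bracketing their base values, utility weights in \[0, 1\] with zero weight
#' on extraction, positive settings, and PSA means equal to base values.
#'
#' @param params A `ce_parameters` object (or plain list with the same shape).
#' @return `params`, invisibly classed as `ce_parameters`, if valid; otherwise
#'   an error naming the offending field.
#' @export
validate_parameters <- function(params) {
  bad <- function(key, msg) {
    abort(sprintf("Invalid parameter `%s`: %s", key, msg),
          class = "rootcea_validation_error")
  }
  tr <- params$transition
  need_prob <- function(x, key) {
    if (is.null(x) || !is.numeric(x) || length(x) != 1L || is.na(x)) {
      bad(key, "missing or non-numeric")
    }
    if (x < 0 || x > 1) bad(key, sprintf("probability %g outside [0, 1]", x))
    x
  }
  need_prob(tr$p_init_caries, "transition.p_init_caries")
  need_prob(tr$p_incidence_nat, "transition.p_incidence_nat")
  for (s in strategies()) {
    st <- tr[[s]]
    if (is.null(st)) bad(paste0("transition.", s), "strategy block missing")
    for (nm in strategy_transition_names()) {
      need_prob(st[[nm]], sprintf("transition.%s.%s", s, nm))
    }
    if (st$p_incidence_tx + st$p_extract_nocaries > 1 + 1e-12) {
      bad(sprintf("transition.%s", s),
          "p_incidence_tx + p_extract_nocaries exceeds 1")
    }
    if (st$p_arrest + st$p_extract_caries > 1 + 1e-12) {
      bad(sprintf("transition.%s", s),
          "p_arrest + p_extract_caries exceeds 1")
    }
  }
  if (tr$NAF$p_arrest != 0) {
    bad("transition.NAF.p_arrest",
        "must be 0: NaF varnish is preventive only, it cannot arrest a lesion")
  }

  costs <- params$costs
  if (!all(c("parameter", "base", "low", "high") %in% names(costs))) {
    bad("costs", "needs columns parameter, base, low, high")
  }
  missing_costs <- setdiff(cost_parameter_names(), costs$parameter)
  if (length(missing_costs)) {
    bad(paste0("costs.", missing_costs[1]), "cost parameter missing")
  }
  for (i in seq_len(nrow(costs))) {
    key <- paste0("costs.", costs$parameter[i])
    if (any(is.na(costs[i, c("base", "low", "high")]))) bad(key, "missing value")
    if (costs$base[i] < 0) bad(key, "costs must be non-negative")
    if (costs$low[i] > costs$base[i] || costs$base[i] > costs$high[i]) {
      bad(key, "requires low <= base <= high")
    }
  }

  u <- params$utilities
  if (!identical(sort(names(u)), sort(health_states()))) {
    bad("utilities", "must name all five health states")
  }
  u <- u[health_states()]
  if (any(u < 0 | u > 1)) bad("utilities", "weights must lie in [0, 1]")
  if (u[["EXTRACTED"]] != 0) bad("utilities.EXTRACTED", "must be 0")
  params$utilities <- u

  st <- params$settings
  if (st$discount_rate < 0) bad("settings.discount_rate", "must be >= 0")
  if (st$horizon_years < 1) bad("settings.horizon_years", "must be >= 1")
  if (st$cycles_per_year != 2L) {
    bad("settings.cycles_per_year",
        "the cycle structure is fixed at 2 half-cycles per year")
  }
  if (st$n_teeth < 1) bad("settings.n_teeth", "must be >= 1")
  if (st$wtp < 0) bad("settings.wtp", "must be >= 0")
  if (!st$cost_allocation %in% c("per_tooth", "per_visit_shared")) {
    bad("settings.cost_allocation", "must be per_tooth or per_visit_shared")
  }
  for (nm in c("cost_aggregation", "effect_aggregation")) {
    if (!st[[nm]] %in% c("per_tooth_mean", "cohort_sum")) {
      bad(paste0("settings.", nm), "must be per_tooth_mean or cohort_sum")
    }
  }
  if (!st$cost_schedule %in% c("semiannual", "annual")) {
    bad("settings.cost_schedule", "must be semiannual or annual")
  }

  psa <- params$psa
  if (nrow(psa)) {
    if (!all(c("parameter", "family", "mean", "ci_low", "ci_high") %in%
             names(psa))) {
      bad("psa", "needs columns parameter, family, mean, ci_low, ci_high")
    }
    for (i in seq_len(nrow(psa))) {
      key <- paste0("psa.", psa$parameter[i])
      if (!psa$family[i] %in% c("beta", "gamma")) {
        bad(key, "family must be beta or gamma")
      }
      base <- get_parameter(params, psa$parameter[i])
      if (abs(psa$mean[i] - base) > 1e-9) {
        bad(key, sprintf("PSA mean %g must equal the base value %g",
                         psa$mean[i], base))
      }
      check_dist_spec(psa$family[i], psa$mean[i], psa$ci_low[i],
                      psa$ci_high[i], key)
    }
  }

  class(params) <- "ce_parameters"
  invisible(params)
}

# Internal: validity of one distribution specification.
check_dist_spec <- function(family, mean, lo, hi, key = "psa") {
  bad <- function(msg) abort(sprintf("Invalid parameter `%s`: %s", key, msg),
                             class = "rootcea_validation_error")
  if (!(lo < hi)) bad("ci95 requires low < high")
  if (family == "beta") {
    if (!(mean > 0 && mean < 1)) bad("beta mean must lie strictly in (0, 1)")
    if (lo < 0 || hi > 1) bad("beta ci95 must lie in [0, 1]")
  } else {
    if (!(mean > 0)) bad("gamma mean must be positive")
    if (lo < 0) bad("gamma ci95 low must be >= 0")
  }
  invisible(TRUE)
}

#' Look up or replace a scalar parameter by name
#'
#' Scalar parameters are addressed by flat names: transition probabilities as
#' `p_init_caries`, `p_incidence_nat`, or `<strategy>.<name>` (for example
#' `SDF.p_arrest`); unit costs by their cost name (`c_sdf`, ..., `c_access`);
#' utilities as `u.<STATE>`. Used by the one-way sensitivity analysis and the
#' PSA draw machinery.
#'
#' @param params A `ce_parameters` object.
#' @param name Flat parameter name.
#' @param value Replacement value (for `set_parameter`).
#' @return `get_parameter`: the scalar value. `set_parameter`: a new validated
#'   `ce_parameters` object (when a cost base moves outside its one-way range,
#'   the range is widened to keep bracketing it).
#' @export
get_parameter <- function(params, name) {
  if (name %in% cost_parameter_names()) {
    return(params$costs$base[match(name, params$costs$parameter)])
  }
  if (name %in% c("p_init_caries", "p_incidence_nat")) {
    return(params$transition[[name]])
  }
  if (grepl("^u\\.", name)) {
    state <- sub("^u\\.", "", name)
    if (state %in% health_states()) return(params$utilities[[state]])
  }
  if (grepl("\\.", name)) {
    parts <- strsplit(name, ".", fixed = TRUE)[[1]]
    if (length(parts) == 2L && toupper(parts[1]) %in% strategies() &&
        parts[2] %in% strategy_transition_names()) {
      return(params$transition[[toupper(parts[1])]][[parts[2]]])
    }
  }
  abort(sprintf("Unknown parameter name '%s'.", name),
        class = "rootcea_lookup_error")
}

#' @rdname get_parameter
#' @export
set_parameter <- function(params, name, value) {
  validate_parameters(set_parameter_impl(params, name, value))
}

# Internal: field update without revalidation (draw_psa validates per draw).
set_parameter_impl <- function(params, name, value) {
  if (name %in% cost_parameter_names()) {
    i <- match(name, params$costs$parameter)
    params$costs$base[i] <- value
    params$costs$low[i] <- min(params$costs$low[i], value)
    params$costs$high[i] <- max(params$costs$high[i], value)
  } else if (name %in% c("p_init_caries", "p_incidence_nat")) {
    params$transition[[name]] <- value
  } else if (grepl("^u\\.", name) &&
             sub("^u\\.", "", name) %in% health_states()) {
    params$utilities[[sub("^u\\.", "", name)]] <- value
  } else if (grepl("\\.", name)) {
    parts <- strsplit(name, ".", fixed = TRUE)[[1]]
    if (length(parts) == 2L && toupper(parts[1]) %in% strategies() &&
        parts[2] %in% strategy_transition_names()) {
      params$transition[[toupper(parts[1])]][[parts[2]]] <- value
    } else {
      abort(sprintf("Unknown parameter name '%s'.", name),
            class = "rootcea_lookup_error")
    }
  } else {
    abort(sprintf("Unknown parameter name '%s'.", name),
          class = "rootcea_lookup_error")
  }
  if (nrow(params$psa) && name %in% params$psa$parameter) {
    params$psa$mean[params$psa$parameter == name] <- value
  }
  params
}

#' Read a parameter set from file
#'
#' Two interchangeable on-disk forms are supported, selected by extension:
#' a structured-key YAML document (sections `transition`, `costs`,
#' `utilities`, `settings`, `psa`) and a flat CSV table with columns
#' `section`, `parameter`, `value`, `low`, `high`, `distribution` mirroring a
#' supplementary parameter table. Both round-trip losslessly through
#' [write_parameters()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.csv` parameter file.
#' @return A validated `ce_parameters` object.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Parameter file '%s' does not exist.", path))
  }
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    read_parameters_yaml(path)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    read_parameters_csv(path)
  } else {
    abort("Parameter files must be .yaml/.yml or .csv.")
  }
}

read_parameters_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  for (sec in c("transition", "costs", "settings")) {
    if (is.null(doc[[sec]])) {
      abort(sprintf("Invalid parameter `%s`: section missing from '%s'.",
                    sec, path),
            class = "rootcea_validation_error")
    }
  }
  costs <- purrr::map_dfr(cost_parameter_names(), function(nm) {
    entry <- doc$costs[[nm]]
    if (is.null(entry)) {
      abort(sprintf("Invalid parameter `costs.%s`: missing.", nm),
            class = "rootcea_validation_error")
    }
    tibble::tibble(parameter = nm, base = as.numeric(entry$base),
                   low = as.numeric(entry$low), high = as.numeric(entry$high))
  })
  utilities <- default_utilities()
  if (!is.null(doc$utilities)) {
    for (sname in names(doc$utilities)) {
      utilities[[toupper(sname)]] <- as.numeric(doc$utilities[[sname]])
    }
  }
  psa <- empty_psa_spec()
  if (length(doc$psa)) {
    psa <- purrr::map_dfr(names(doc$psa), function(nm) {
      sp <- doc$psa[[nm]]
      tibble::tibble(parameter = nm, family = sp$family,
                     mean = as.numeric(sp$mean),
                     ci_low = as.numeric(sp$ci95[[1]]),
                     ci_high = as.numeric(sp$ci95[[2]]))
    })
  }
  tr <- doc$transition
  names(tr) <- ifelse(names(tr) %in% c("sdf", "naf"), toupper(names(tr)),
                      names(tr))
  ce_parameters(
    transition = tr,
    costs = costs,
    utilities = utilities,
    settings = doc$settings,
    psa = psa,
    currency = doc$currency %||% "2025 US$"
  )
}

read_parameters_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("section", "parameter", "value", "low", "high", "distribution")
  if (!all(need %in% names(tab))) {
    abort(sprintf("Invalid parameter `table`: CSV needs columns %s.",
                  paste(need, collapse = ", ")),
          class = "rootcea_validation_error")
  }
  pick <- function(section, parameter) {
    i <- which(tab$section == section & tab$parameter == parameter)
    if (!length(i)) {
      abort(sprintf("Invalid parameter `%s.%s`: row missing.",
                    section, parameter),
            class = "rootcea_validation_error")
    }
    tab[i[1], , drop = FALSE]
  }
  num <- function(section, parameter) as.numeric(pick(section, parameter)$value)

  tr <- list(p_init_caries = num("transition", "p_init_caries"),
             p_incidence_nat = num("transition", "p_incidence_nat"))
  for (s in strategies()) {
    tr[[s]] <- setNames(
      lapply(strategy_transition_names(),
             function(nm) num("transition", paste(s, nm, sep = "."))),
      strategy_transition_names()
    )
  }
  costs <- purrr::map_dfr(cost_parameter_names(), function(nm) {
    row <- pick("costs", nm)
    tibble::tibble(parameter = nm, base = as.numeric(row$value),
                   low = as.numeric(row$low), high = as.numeric(row$high))
  })
  utilities <- default_utilities()
  for (s in health_states()) {
    i <- which(tab$section == "utilities" & tab$parameter == s)
    if (length(i)) utilities[[s]] <- as.numeric(tab$value[i[1]])
  }
  settings <- default_settings()
  for (nm in names(settings)) {
    i <- which(tab$section == "settings" & tab$parameter == nm)
    if (length(i)) {
      v <- tab$value[i[1]]
      settings[[nm]] <- if (is.numeric(settings[[nm]])) as.numeric(v) else v
    }
  }
  psa_rows <- tab[tab$section == "psa", , drop = FALSE]
  psa <- if (nrow(psa_rows)) {
    tibble::tibble(parameter = psa_rows$parameter,
                   family = psa_rows$distribution,
                   mean = as.numeric(psa_rows$value),
                   ci_low = as.numeric(psa_rows$low),
                   ci_high = as.numeric(psa_rows$high))
  } else {
    empty_psa_spec()
  }
  cur <- tab$value[tab$section == "meta" & tab$parameter == "currency"]
  ce_parameters(transition = tr, costs = costs, utilities = utilities,
                settings = settings, psa = psa,
                currency = if (length(cur)) cur[1] else "2025 US$")
}

#' Write a parameter set to file
#'
#' Inverse of [read_parameters()]; the format follows the file extension.
#'
#' @param params A validated `ce_parameters` object.
#' @param path Destination `.yaml`/`.yml` or `.csv` path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  params <- validate_parameters(params)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    doc <- list(
      currency = params$currency,
      transition = params$transition,
      costs = setNames(
        lapply(seq_len(nrow(params$costs)), function(i) {
          list(base = params$costs$base[i], low = params$costs$low[i],
               high = params$costs$high[i])
        }),
        params$costs$parameter
      ),
      utilities = as.list(params$utilities),
      settings = params$settings,
      psa = setNames(
        lapply(seq_len(nrow(params$psa)), function(i) {
          list(family = params$psa$family[i], mean = params$psa$mean[i],
               ci95 = c(params$psa$ci_low[i], params$psa$ci_high[i]))
        }),
        params$psa$parameter
      )
    )
    ok <- tryCatch({
      yaml::write_yaml(doc, path, precision = 15L)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok || !file.exists(path)) {
      abort(sprintf("Could not write parameter file '%s'.", path))
    }
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    rows <- parameter_table(params)
    ok <- tryCatch({
      write.csv(rows, path, row.names = FALSE)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) abort(sprintf("Could not write parameter file '%s'.", path))
  } else {
    abort("Parameter files must be .yaml/.yml or .csv.")
  }
  invisible(path)
}

#' Flatten a parameter set to a supplementary-style table
#'
#' One row per scalar parameter with its value, one-way/credible range and
#' assigned PSA distribution — the layout of a published parameter table.
#'
#' @param params A `ce_parameters` object.
#' @return A tibble with columns `section`, `parameter`, `value`, `low`,
#'   `high`, `distribution`.
#' @export
parameter_table <- function(params) {
  tr <- params$transition
  psa_for <- function(nm) {
    i <- match(nm, params$psa$parameter)
    if (is.na(i)) list(family = NA_character_, low = NA_real_, high = NA_real_)
    else list(family = params$psa$family[i], low = params$psa$ci_low[i],
              high = params$psa$ci_high[i])
  }
  tr_names <- c("p_init_caries", "p_incidence_nat",
                paste("SDF", strategy_transition_names(), sep = "."),
                paste("NAF", strategy_transition_names(), sep = "."))
  tr_rows <- purrr::map_dfr(tr_names, function(nm) {
    sp <- psa_for(nm)
    tibble::tibble(section = "transition", parameter = nm,
                   value = as.character(get_parameter(params, nm)),
                   low = sp$low, high = sp$high, distribution = sp$family)
  })
  cost_rows <- tibble::tibble(
    section = "costs", parameter = params$costs$parameter,
    value = as.character(params$costs$base),
    low = params$costs$low, high = params$costs$high,
    distribution = purrr::map_chr(params$costs$parameter,
                                  function(nm) psa_for(nm)$family)
  )
  util_rows <- tibble::tibble(
    section = "utilities", parameter = health_states(),
    value = as.character(params$utilities[health_states()]),
    low = NA_real_, high = NA_real_, distribution = NA_character_
  )
  set_rows <- tibble::tibble(
    section = "settings", parameter = names(params$settings),
    value = purrr::map_chr(params$settings, ~ format(.x, scientific = FALSE)),
    low = NA_real_, high = NA_real_, distribution = NA_character_
  )
  psa_rows <- tibble::tibble(
    section = "psa", parameter = params$psa$parameter,
    value = as.character(params$psa$mean),
    low = params$psa$ci_low, high = params$psa$ci_high,
    distribution = params$psa$family
  )
  meta <- tibble::tibble(section = "meta", parameter = "currency",
                         value = params$currency, low = NA_real_,
                         high = NA_real_, distribution = NA_character_)
  dplyr::bind_rows(tr_rows, cost_rows, util_rows, set_rows, psa_rows, meta)
}

#' The packaged default parameter set
#'
#' Loads the calibrated synthetic parameter fixture shipped with the package.
#' Its cost bases and one-way ranges are the published unit costs; its
#' transition probabilities and caries-state utility weights are *derived*
#' stand-ins, calibrated with [calibrate_base_case()] so that the model
#' reproduces the published base-case costs and effects. They are not the
#' source study's estimated probabilities, which were never published in the
#' article body; replace them with the original values for exact replication.
#'
#' @return A validated `ce_parameters` object.
#' @export
default_parameters <- function() {
  path <- system.file("extdata", "synthetic_default_parameters.yaml",
                      package = "rootcea", mustWork = TRUE)
  read_parameters(path)
}

#' @export
print.ce_parameters <- function(x, ...) {
  st <- x$settings
  cat("<ce_parameters>\n")
  cat(sprintf("  horizon %d y, %d half-cycles/y, %d teeth, discount %.1f%%, WTP %s %s\n",
              st$horizon_years, st$cycles_per_year, st$n_teeth,
              100 * st$discount_rate, format(st$wtp, big.mark = " "),
              x$currency))
  cat(sprintf("  initial root-caries prevalence: %.3f\n",
              x$transition$p_init_caries))
  for (s in strategies()) {
    tr <- x$transition[[s]]
    cat(sprintf("  %s: inc_tx %.3f, arrest %.3f, extract(caries) %.3f, extract(no caries) %.3f\n",
                s, tr$p_incidence_tx, tr$p_arrest, tr$p_extract_caries,
                tr$p_extract_nocaries))
  }
  cat(sprintf("  costs (%s): %s\n", x$currency,
              paste(sprintf("%s=%g", x$costs$parameter, x$costs$base),
                    collapse = ", ")))
  cat(sprintf("  PSA specs: %d parameters\n", nrow(x$psa)))
  invisible(x)
}
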