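#' Run the base-case analysis and write publication-style outputs
#'
#' Loads a parameter file, runs both strategies, and writes to `out_dir`:
#' `base_case.csv` (two strategy rows with cost, incremental cost,
#' effectiveness, incremental effectiveness, ICER, NMB), one trajectory CSV
#' per strategy, and a JSON run manifest.
#'
#' @param config Path to a parameter file readable by [read_parameters()].
#' @param out_dir Output directory (created if absent).
#' @param wtp Optional willingness-to-pay override.
#' @param timestamp Manifest timestamp; inject a fixed value for reproducible
#'   outputs in tests.
#' @return The run manifest (a list), invisibly.
#' @export
report_base_case <- function(config, out_dir, wtp = NULL,
                             timestamp = format(Sys.time(), tz = "UTC")) {
  params <- read_parameters(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- base_case(params, wtp = wtp)

  out_table <- file.path(out_dir, "base_case.csv")
  write.csv(tidy(res), out_table, row.names = FALSE)
  traj_paths <- vapply(strategies(), function(s) {
    p <- file.path(out_dir, sprintf("trajectory_%s.csv", tolower(s)))
    write.csv(run_cohort(params, s), p, row.names = FALSE)
    p
  }, character(1))

  write_manifest(
    command = "base_case", config = config, seed = NA_integer_,
    out_dir = out_dir, outputs = c(out_table, traj_paths),
    timestamp = timestamp
  )
}

#' Run the one-way sensitivity analysis and write its table
#'
#' Evaluates the ICER at the low, base, and high value of each unit-cost
#' parameter and writes `one_way.csv` (parameter, value, icer,
#' incremental_nmb) plus a JSON run manifest.
#'
#' @inheritParams report_base_case
#' @return The run manifest, invisibly.
#' @export
report_one_way <- function(config, out_dir,
                           timestamp = format(Sys.time(), tz = "UTC")) {
  params <- read_parameters(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- one_way_table(params)
  out_table <- file.path(out_dir, "one_way.csv")
  write.csv(tab, out_table, row.names = FALSE)
  write_manifest(
    command = "one_way", config = config, seed = NA_integer_,
    out_dir = out_dir, outputs = out_table, timestamp = timestamp,
    extra = list(base_icer = attr(tab, "base_icer"))
  )
}

#' Run the probabilistic sensitivity analysis and write its outputs
#'
#' Draws `n` parameter sets, evaluates both strategies on each, and writes
#' `psa_draws.csv` (per-draw cost/effect pairs), `ceac.csv` (willingness-to-
#' pay grid with each strategy's acceptability), and a JSON manifest
#' recording the seed and the estimated crossover WTP.
#'
#' @inheritParams report_base_case
#' @param n Number of Monte Carlo draws.
#' @param seed Integer root seed.
#' @param wtp_grid Willingness-to-pay grid for the acceptability curve.
#' @return The run manifest, invisibly.
#' @export
report_psa <- function(config, out_dir, n = 1000L, seed = 1L,
                       wtp_grid = seq(0, 5000, by = 50),
                       timestamp = format(Sys.time(), tz = "UTC")) {
  params <- read_parameters(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  draws <- draw_psa(params, n = n, seed = seed)
  psa <- run_psa(draws)
  curve <- ceac(psa, wtp_grid)
  crossover <- ceac_crossover(curve, "SDF")

  draws_path <- file.path(out_dir, "psa_draws.csv")
  write.csv(psa, draws_path, row.names = FALSE)
  ceac_path <- file.path(out_dir, "ceac.csv")
  ceac_wide <- tidyr::pivot_wider(curve, names_from = "strategy",
                                  values_from = "probability",
                                  names_prefix = "p_")
  names(ceac_wide) <- tolower(names(ceac_wide))
  write.csv(ceac_wide, ceac_path, row.names = FALSE)

  write_manifest(
    command = "psa", config = config, seed = seed, out_dir = out_dir,
    outputs = c(draws_path, ceac_path), timestamp = timestamp,
    extra = list(n_draws = n,
                 ceac_crossover = if (is.na(crossover)) NULL
                 else as.numeric(crossover))
  )
}

# Internal: write the run manifest JSON and return it.
write_manifest <- function(command, config, seed, out_dir, outputs,
                           timestamp, extra = list()) {
  manifest <- c(
    list(
      command = command,
      config = config,
      seed = seed,
      package_version = as.character(utils::packageVersion("rootcea")),
      timestamp = timestamp,
      outputs = as.character(outputs)
    ),
    extra
  )
  path <- file.path(out_dir, sprintf("manifest_%s.json", command))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  manifest$manifest_path <- path
  missing <- outputs[!file.exists(outputs)]
  if (length(missing)) {
    abort(sprintf("Declared outputs missing after run: %s",
                  paste(missing, collapse = ", ")))
  }
  invisible(manifest)
}
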