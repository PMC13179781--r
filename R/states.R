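#' Tooth health states
#'
#' The model tracks each tooth through five states. `EXTRACTED` is the unique
#' absorbing state: once a tooth is extracted it stays extracted. `ARREST` and
#' `PERSISTENT` are transient within an annual cycle — they exist only between
#' the treatment half-cycle that creates them and the relabelling at the start
#' of the next cycle, which folds `ARREST` into `NO_CARIES` and `PERSISTENT`
#' into `ROOT_CARIES`.
#'
#' @return Character vector of the five state labels, in the fixed order used
#'   by every occupancy vector in the package.
#' @export
#' @examples
#' health_states()
health_states <- function() {
  c("NO_CARIES", "ROOT_CARIES", "ARREST", "PERSISTENT", "EXTRACTED")
}

#' Treatment strategies
#'
#' Two strategies are compared: semiannual 38% silver diamine fluoride
#' (`"SDF"`, both preventive and caries-arresting) and 5% sodium fluoride
#' varnish (`"NAF"`, preventive only — its arrest probability is structurally
#' zero).
#'
#' @return Character vector of the two strategy labels.
#' @export
strategies <- function() {
  c("SDF", "NAF")
}

# Internal: validate a strategy label, returning it normalised to upper case.
match_strategy <- function(strategy) {
  if (length(strategy) != 1L || !is.character(strategy)) {
    abort("`strategy` must be a single character label.")
  }
  s <- toupper(strategy)
  if (!s %in% strategies()) {
    abort(sprintf("Unknown strategy '%s'; expected one of %s.",
                  strategy, paste(strategies(), collapse = ", ")))
  }
  s
}

#' Construct an occupancy vector
#'
#' An occupancy is a probability distribution over the five health states at a
#' half-cycle boundary: non-negative entries summing to 1.
#'
#' @param no_caries,root_caries,arrest,persistent,extracted State masses.
#' @return Named numeric vector over [health_states()].
#' @export
#' @examples
#' occupancy(no_caries = 0.32, root_caries = 0.68)
occupancy <- function(no_caries = 0, root_caries = 0, arrest = 0,
                      persistent = 0, extracted = 0) {
  occ <- c(NO_CARIES = no_caries, ROOT_CARIES = root_caries, ARREST = arrest,
           PERSISTENT = persistent, EXTRACTED = extracted)
  check_occupancy(occ)
  occ
}

# Internal: assert a valid occupancy vector (names, non-negativity, unit sum).
check_occupancy <- function(occ, tol = 1e-9) {
  if (!is.numeric(occ) || length(occ) != 5L) {
    abort("An occupancy must be a numeric vector of length 5.")
  }
  if (is.null(names(occ))) names(occ) <- health_states()
  if (!identical(names(occ), health_states())) {
    abort("Occupancy names must be the five health states in canonical order.")
  }
  if (any(occ < -tol)) abort("Occupancy entries must be non-negative.")
  if (abs(sum(occ) - 1) > tol) {
    abort(sprintf("Occupancy must sum to 1 (got %.12f).", sum(occ)))
  }
  invisible(occ)
}
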