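#' Generation-equivalence calibration parameters
#'
#' A Fermi-style bridge from simulation updates to bacterial generations:
#' along the lineage of the most abundant pathogen, a full 250,000-update
#' run accumulates on the order of 400 task substitutions; treating one
#' fixed substitution as one substitution in an *E. coli*-like microbe, at
#' 0.0001--0.0002 substitutions per generation, converts updates to an
#' equivalent range of bacterial generations.
#'
#' @param subs_per_run Substitutions along the focal lineage over a full
#'   run (default 400).
#' @param run_length Run length in updates (default 250,000).
#' @param mu_low,mu_high Substitutions per bacterial generation (defaults
#'   0.0001 and 0.0002).
#' @return A `calibration_params` list.
#' @export
calibration_params <- function(subs_per_run = 400, run_length = 250000,
                               mu_low = 1e-4, mu_high = 2e-4) {
  if (subs_per_run <= 0 || run_length <= 0 || mu_low <= 0 || mu_high <= 0) {
    stop("all calibration parameters must be positive")
  }
  if (mu_low > mu_high) stop("mu_low must not exceed mu_high")
  structure(list(subs_per_run = subs_per_run, run_length = run_length,
                 mu_low = mu_low, mu_high = mu_high),
            class = "calibration_params")
}

#' Substitutions along a lineage
#'
#' Total task substitutions accumulated along the path from a genotype back
#' to its ancestor: the sum of `mutations_from_parent` over the root path.
#'
#' @param phylo Phylogeny table.
#' @param tip_id Genotype id.
#' @return Non-negative integer count (0 for an ancestor).
#' @export
lineage_substitutions <- function(phylo, tip_id) {
  idx <- match(tip_id, phylo$id)
  if (is.na(idx)) stop("unknown genotype id: ", tip_id)
  total <- 0L
  cur <- idx
  while (!is.na(phylo$parent_id[cur])) {
    total <- total + phylo$mutations_from_parent[cur]
    cur <- match(phylo$parent_id[cur], phylo$id)
  }
  total
}

#' Convert simulation updates to equivalent bacterial generations
#'
#' Scales updates linearly to expected substitutions
#' (`updates * subs_per_run / run_length`) and divides by the bounds of the
#' per-generation substitution rate: the low generation bound uses the high
#' rate and vice versa. With the defaults, 50,000 updates correspond to
#' 400,000--800,000 generations and a full run to 2--4 million.
#'
#' @param updates Number of simulation updates (positive).
#' @param params A [calibration_params()] list.
#' @return Named numeric vector `c(low =, high =)` of equivalent
#'   generations.
#' @export
#' @examples
#' generations_equivalent(250000) # c(low = 2e6, high = 4e6)
generations_equivalent <- function(updates, params = calibration_params()) {
  if (any(updates <= 0)) stop("updates must be positive")
  subs <- updates * params$subs_per_run / params$run_length
  c(low = subs / params$mu_high, high = subs / params$mu_low)
}
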