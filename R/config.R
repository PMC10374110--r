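#' Build a seeded simulation configuration
#'
#' Draws one random world configuration: grid size, resource biochemistry
#' (which resources flow in, the task-to-resource assignment, and the
#' by-product network with input-output ratios in `[0, 0.5]`), and fixes all
#' dynamical parameters. At `scale = 1` the world has 2,500--15,000 grid
#' cells and runs for 250,000 updates; a single scale factor shrinks the
#' world size, the run length, and every analysis window proportionally, so
#' the full protocol runs in minutes at `scale = 0.04` (worlds of 100--600
#' cells, 10,000 updates).
#'
#' The same `(master_seed, scale)` always yields an identical configuration.
#'
#' @param master_seed Integer seed for the configuration draw; also stored as
#'   the run seed (`$seed`) unless overridden later.
#' @param scale Positive scale factor applied to world size, run length and
#'   analysis windows.
#' @param ... Named overrides for any configuration field (applied after the
#'   random draw; overriding a drawn field makes the config non-random in
#'   that field).
#' @return An object of class `sim_config`: a named list of all simulation
#'   parameters.
#' @export
build_config <- function(master_seed, scale = 1, ...) {
  if (!is.numeric(scale) || length(scale) != 1L || is.na(scale) || scale <= 0) {
    stop("`scale` must be a positive number")
  }
  master_seed <- as.integer(master_seed)
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(master_seed)

  total_updates <- max(100L, as.integer(round(250000 * scale)))
  n_target <- as.integer(round(stats::runif(1, 2500 * scale, 15000 * scale)))
  dims <- .grid_dims(n_target, lo = ceiling(2500 * scale), hi = floor(15000 * scale))

  ## Resource biochemistry: each of the nine resources is consumed by exactly
  ## one task (a random permutation); a random subset of 3--9 resources
  ## receives inflow (the rest are effectively absent, spanning scarce to
  ## rich environments); each task excretes a by-product into a random
  ## resource pool at a ratio drawn in [0, 0.5].
  task_resource <- sample.int(9L)
  n_avail <- sample(3:9, 1L)
  avail <- sample.int(9L, n_avail)
  inflow_max <- numeric(9L)
  inflow_max[avail] <- 10^stats::runif(n_avail, -1.7, 0) * dims$n_cells
  outflow_max <- stats::runif(9L, 0.01, 0.10)
  byproduct_resource <- sample.int(9L, 9L, replace = TRUE)
  byproduct_ratio <- stats::runif(9L, 0, 0.5)

  cfg <- list(
    seed = master_seed,
    scale = scale,
    n_rows = dims$n_rows,
    n_cols = dims$n_cols,
    n_cells = dims$n_cells,
    total_updates = total_updates,
    ## scheduler and organism economics
    cpu_per_org = 30,
    host_repl_cost = 150,
    task_cost_factor = 0.35,
    path_repl_cost = 100,
    theft_fraction = 0.5,
    path_age_cap = 100L,
    n_propagules = 1L,
    consumption_cap = 1,
    ## mutation (per task bit, per replication)
    host_mutation = 0.002,
    path_mutation = 0.005,
    ## ancestors: both perform NOT so the epidemic can start
    host_ancestor_mask = 1L,
    path_ancestor_mask = 1L,
    ## pathogen ancestors introduced as a small population once hosts fill in
    pathogen_intro_update = as.integer(round(0.05 * total_updates)),
    injection_fraction = 0.05,
    ## resource model
    task_resource = task_resource,
    inflow_max = inflow_max,
    outflow_max = outflow_max,
    byproduct_resource = byproduct_resource,
    byproduct_ratio = byproduct_ratio,
    ## recording cadence: fine resolution throughout (100 updates at scale 1)
    record_step = max(1L, as.integer(round(100 * scale))),
    ## analysis windows (all fractions of the 250,000-update protocol)
    sample_window = as.integer(round(c(0.2, 0.6) * total_updates)),
    manipulate_window = as.integer(round(c(0.6, 0.8) * total_updates)),
    persistence_cap = as.integer(round(0.2 * total_updates)),
    auc_window = max(1L, as.integer(round(0.01 * total_updates))),
    auc_resolution = max(1L, as.integer(round(100 * scale)))
  )

  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  cfg <- .normalize_config(cfg)
  validate_config(cfg)
  structure(cfg, class = "sim_config")
}

# Choose grid dimensions with n_rows * n_cols inside [lo, hi], near n_target.
.grid_dims <- function(n_target, lo, hi) {
  n_rows <- max(2L, as.integer(floor(sqrt(n_target))))
  n_cols <- max(2L, as.integer(round(n_target / n_rows)))
  n <- n_rows * n_cols
  while (n < lo) {
    n_cols <- n_cols + 1L
    n <- n_rows * n_cols
  }
  while (n > hi && n_cols > 2L) {
    n_cols <- n_cols - 1L
    n <- n_rows * n_cols
  }
  list(n_rows = n_rows, n_cols = n_cols, n_cells = n)
}

.normalize_config <- function(cfg) {
  int_fields <- c(
    "seed", "n_rows", "n_cols", "n_cells", "total_updates", "path_age_cap",
    "n_propagules", "host_ancestor_mask", "path_ancestor_mask",
    "pathogen_intro_update", "task_resource", "byproduct_resource",
    "record_step", "sample_window", "manipulate_window", "persistence_cap",
    "auc_window", "auc_resolution"
  )
  for (f in int_fields) cfg[[f]] <- as.integer(cfg[[f]])
  num_fields <- c(
    "scale", "cpu_per_org", "host_repl_cost", "task_cost_factor",
    "path_repl_cost", "theft_fraction", "consumption_cap", "host_mutation",
    "path_mutation", "inflow_max", "outflow_max", "byproduct_ratio",
    "injection_fraction"
  )
  for (f in num_fields) cfg[[f]] <- as.numeric(cfg[[f]])
  cfg
}

#' Validate a simulation configuration
#'
#' Checks the structural invariants every configuration must satisfy:
#' probabilities in `[0, 1]`, by-product ratios in `[0, 0.5]`, a positive run
#' length, an injection fraction in `(0, 1)`, and a task-to-resource map that
#' is a permutation of the nine resources.
#'
#' @param cfg A `sim_config`.
#' @return `cfg`, invisibly; errors on violation.
#' @export
validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$total_updates <= 0L) stop("total_updates must be positive")
  if (cfg$n_cells != cfg$n_rows * cfg$n_cols) stop("n_cells must equal n_rows * n_cols")
  for (p in c("host_mutation", "path_mutation", "theft_fraction")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  }
  if (cfg$injection_fraction <= 0 || cfg$injection_fraction >= 1) {
    stop("injection_fraction must be in (0, 1)")
  }
  if (!setequal(cfg$task_resource, 1:9)) stop("task_resource must be a permutation of 1..9")
  if (any(cfg$byproduct_ratio < 0 | cfg$byproduct_ratio > 0.5)) {
    stop("by-product ratios must be in [0, 0.5]")
  }
  if (any(cfg$inflow_max < 0) || any(cfg$outflow_max < 0)) {
    stop("resource bounds must be non-negative")
  }
  if (cfg$record_step < 1L) stop("record_step must be >= 1")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  seed %d, scale %.3g\n", x$seed, x$scale))
  cat(sprintf("  world %d x %d = %d cells, %d updates\n",
              x$n_rows, x$n_cols, x$n_cells, x$total_updates))
  cat(sprintf("  resources with inflow: %d/9; record step %d\n",
              sum(x$inflow_max > 0), x$record_step))
  invisible(x)
}

# RNG bookkeeping helpers: used wherever a routine must not perturb (or must
# temporarily replace) the caller's RNG stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_rng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Evaluate `expr` under a temporary seed, restoring the caller's RNG after.
.with_seed <- function(seed, expr) {
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive k child seeds from one master seed (all < 2^31).
.derive_seeds <- function(master_seed, k) {
  .with_seed(master_seed, sample.int(.Machine$integer.max - 1L, k))
}
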