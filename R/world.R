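# Genotype registry: a mutable, preallocated columnar store. One row per
# genotype ever created ("species" = distinct genotype, a node of the
# phylogeny). Children always have larger ids than their parents.
.new_registry <- function(capacity = 1024L) {
  reg <- new.env(parent = emptyenv())
  reg$n <- 0L
  reg$parent <- integer(capacity)
  reg$kind <- integer(capacity)     # 1 = host, 2 = pathogen
  reg$birth <- integer(capacity)
  reg$mut <- integer(capacity)      # task-bit flips from parent
  reg$mask <- integer(capacity)     # 9-bit task profile
  reg
}

.registry_grow <- function(reg, need) {
  cap <- length(reg$parent)
  if (reg$n + need <= cap) return(invisible(reg))
  new_cap <- max(cap * 2L, reg$n + need)
  for (f in c("parent", "kind", "birth", "mut", "mask")) {
    v <- reg[[f]]
    length(v) <- new_cap
    reg[[f]] <- v
  }
  invisible(reg)
}

# Register `k` genotypes; returns their new ids.
.registry_add <- function(reg, parent, kind, birth, mut, mask) {
  k <- length(mask)
  if (k == 0L) return(integer(0))
  .registry_grow(reg, k)
  ids <- reg$n + seq_len(k)
  reg$parent[ids] <- parent
  reg$kind[ids] <- kind
  reg$birth[ids] <- birth
  reg$mut[ids] <- mut
  reg$mask[ids] <- mask
  reg$n <- reg$n + k
  ids
}

# Registry -> plain data frame (the phylogeny table).
.registry_df <- function(reg) {
  n <- reg$n
  data.frame(
    id = seq_len(n),
    parent_id = ifelse(reg$parent[seq_len(n)] == 0L, NA_integer_, reg$parent[seq_len(n)]),
    kind = c("host", "pathogen")[reg$kind[seq_len(n)]],
    birth_update = reg$birth[seq_len(n)],
    mutations_from_parent = reg$mut[seq_len(n)],
    task_bits = .mask_string(reg$mask[seq_len(n)])
  )
}

.mask_string <- function(mask) {
  m <- outer(as.integer(mask), 2L^(0:8), function(x, b) as.integer(bitwAnd(x, b) > 0L))
  apply(m, 1L, paste0, collapse = "")
}

.string_mask <- function(s) {
  vapply(strsplit(s, ""), function(bits) {
    as.integer(sum(2L^(0:8) * (bits == "1")))
  }, integer(1))
}

#' Initialise a world from a configuration
#'
#' Seeds the grid with a single host ancestor (centre cell) and registers the
#' two ancestral genotypes (host and pathogen). The pathogen ancestor enters
#' the world later, at `cfg$pathogen_intro_update`, as a small injected
#' population (see [step_world()]).
#'
#' The world is a mutable environment: one host at most per grid cell, one
#' pathogen at most per host, per-organism accumulated CPU, and nine global
#' resource pools.
#'
#' @param cfg A `sim_config` from [build_config()].
#' @return An object of class `sim_world` (an environment).
#' @export
init_world <- function(cfg) {
  validate_config(cfg)
  w <- new.env(parent = emptyenv())
  w$cfg <- cfg
  n <- cfg$n_cells
  w$host_g <- integer(n)      # genotype id per cell, 0 = empty
  w$host_cpu <- numeric(n)
  w$path_g <- integer(n)      # pathogen genotype id per cell, 0 = none
  w$path_cpu <- numeric(n)
  w$path_birth <- integer(n)  # update the resident pathogen individual was born
  w$pools <- numeric(9L)
  w$update <- 0L
  w$reg <- .new_registry()
  host_anc <- .registry_add(w$reg, 0L, 1L, 0L, 0L, cfg$host_ancestor_mask)
  path_anc <- .registry_add(w$reg, 0L, 2L, cfg$pathogen_intro_update, 0L,
                            cfg$path_ancestor_mask)
  w$host_ancestor <- host_anc
  w$path_ancestor <- path_anc
  centre <- (cfg$n_rows %/% 2L) * cfg$n_cols + cfg$n_cols %/% 2L + 1L
  w$host_g[centre] <- host_anc
  w$n_hosts <- 1L
  w$n_paths <- 0L
  class(w) <- "sim_world"
  w
}

#' @export
print.sim_world <- function(x, ...) {
  cat(sprintf("<sim_world> update %d: %d hosts, %d pathogens on %d cells\n",
              x$update, x$n_hosts, x$n_paths, x$cfg$n_cells))
  invisible(x)
}

#' Advance a world by one update
#'
#' One update executes, in order: (1) randomised resource inflow/outflow
#' within the configured bounds; (2) task performance against the resource
#' pools -- hosts consume the resource mapped to each task they carry,
#' excrete the by-product into the configured pool at the configured ratio,
#' and earn merit multiplicative in `2^complexity`, scaled by per-capita
#' resource availability (crowded resources confer a diminishing advantage,
#' which is what sustains coexistence); (3) merit-proportional allocation of
#' a global CPU budget of `cpu_per_org` cycles per host, with infected hosts
#' yielding the theft fraction of their cycles to their pathogen;
#' (4) pathogen deaths by age cap; (5) replication -- hosts whose
#' accumulated CPU reaches the replication cost (which grows with summed
#' task complexity) place one offspring in a random Moore-neighbouring cell,
#' overwriting any occupant and its pathogen, while pathogens emit
#' propagules to uniformly random cells, surviving only on a susceptible,
#' uninfected host; offspring task bits mutate independently per bit. At the
#' configured introduction update the ancestral pathogen population is
#' injected into `injection_fraction` of the cells.
#'
#' The update loop is implemented in compiled code; this wrapper advances a
#' single update for interactive inspection and testing. The world is
#' modified in place (and returned invisibly). All randomness comes from the
#' global R RNG stream, so identical seeds give bit-identical histories.
#'
#' @param w A `sim_world`.
#' @param audit If `TRUE`, run the full invariant audit after the update and
#'   stop on any violation.
#' @return The world, invisibly.
#' @export
step_world <- function(w, audit = FALSE) {
  cpp_run_segment(w, w$update + 1L, integer(0), if (audit) 1L else 0L)
  invisible(w)
}

#' Audit the structural invariants of a world
#'
#' Verifies every invariant the representation is supposed to maintain: at
#' most one host per cell and one pathogen per host (pathogens cannot sit on
#' empty cells), every infection satisfies [can_infect()], the incremental
#' population counters equal the grid census, resource pools are
#' non-negative, no organism references an unregistered genotype, and kinds
#' never interconvert.
#'
#' @param w A `sim_world`.
#' @return `TRUE` invisibly; stops with a description on the first violation.
#' @export
audit_world <- function(w) {
  cpp_audit(w)
  invisible(TRUE)
}

# Inject `fraction * n_cells` propagules of one genotype into distinct random
# cells; only susceptible, uninfected resident hosts become infected. Used by
# the experiment engine at manipulation time (under its dedicated RNG
# stream). Returns the number of infections established.
.inject_genotype <- function(w, genotype_id, fraction, update = w$update) {
  cfg <- w$cfg
  n_target <- min(cfg$n_cells, as.integer(ceiling(fraction * cfg$n_cells)))
  cells <- sample.int(cfg$n_cells, n_target)
  gmask <- w$reg$mask[genotype_id]
  ok <- w$host_g[cells] > 0L & w$path_g[cells] == 0L
  cells <- cells[ok]
  if (length(cells)) {
    ok2 <- bitwAnd(gmask, w$reg$mask[w$host_g[cells]]) > 0L
    cells <- cells[ok2]
  }
  if (length(cells)) {
    w$path_g[cells] <- genotype_id
    w$path_cpu[cells] <- 0
    w$path_birth[cells] <- as.integer(update)
    w$n_paths <- w$n_paths + length(cells)
  }
  length(cells)
}
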