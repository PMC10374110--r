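#' Draw the sampling and manipulation times for a pair
#'
#' The invader's source snapshot is drawn uniformly from the window spanning
#' 20--60% of the run (updates 50,000--150,000 at full scale) and the
#' manipulation time uniformly from 60--80% (150,000--200,000), both snapped
#' to recorded snapshots, so the source always precedes the invasion.
#'
#' Uses the current RNG stream.
#'
#' @param cfg A `sim_config`.
#' @param snapshots Recorded updates to snap to (defaults to the default
#'   recorder's schedule).
#' @return List with integers `t_sample` and `t_manipulate`.
#' @export
schedule_times <- function(cfg, snapshots = recorder_updates(default_recorder(cfg), cfg$total_updates)) {
  sw <- cfg$sample_window
  mw <- cfg$manipulate_window
  s_cand <- snapshots[snapshots >= sw[1] & snapshots <= sw[2]]
  m_cand <- snapshots[snapshots > mw[1] & snapshots <= mw[2]]
  if (!length(s_cand) || !length(m_cand)) stop("recording cadence too coarse for the windows")
  list(t_sample = s_cand[sample.int(length(s_cand), 1L)],
       t_manipulate = m_cand[sample.int(length(m_cand), 1L)])
}

#' Sample a time-travelling invader from a trajectory
#'
#' Chooses a source snapshot uniformly among the recorded snapshots inside
#' `window` that contain at least one living pathogen, then samples one
#' pathogen genotype with probability proportional to its abundance in that
#' snapshot. Uses the current RNG stream.
#'
#' @param traj A `sim_trajectory`.
#' @param window Integer vector of length 2: update interval to sample from
#'   (defaults to the configuration's sampling window).
#' @return List with `genotype_id`, `task_bits` mask, `t_sample` (the source
#'   snapshot) and `abundance` (the genotype's abundance there).
#' @export
sample_invader <- function(traj, window = traj$config$sample_window) {
  cen <- traj$census
  in_win <- cen$update >= window[1] & cen$update <= window[2] & cen$kind == "pathogen"
  if (!any(in_win)) stop("empty-window: no pathogens recorded in the sampling window")
  cand_ups <- unique(cen$update[in_win])
  u <- cand_ups[sample.int(length(cand_ups), 1L)]
  rows <- cen[cen$update == u & cen$kind == "pathogen", , drop = FALSE]
  i <- sample.int(nrow(rows), 1L, prob = rows$abundance)
  g <- rows$genotype_id[i]
  list(genotype_id = g,
       task_mask = .string_mask(traj$phylogeny$task_bits[match(g, traj$phylogeny$id)]),
       t_sample = u,
       abundance = rows$abundance[i])
}

#' Inject a pathogen genotype into a world
#'
#' Implements the invasion manipulation: `ceiling(fraction * n_cells)`
#' distinct cells are chosen uniformly at random; in each chosen cell the
#' resident host becomes infected by a new instance of the genotype if and
#' only if the host exists, is currently uninfected, and is susceptible
#' (shares at least one task with the invader). Propagules landing anywhere
#' else die. Injection draws come from a dedicated RNG stream (`seed`), so
#' in a paired experiment the post-manipulation divergence is attributable
#' solely to the manipulation.
#'
#' The genotype must already exist in the world's phylogeny (in a paired
#' replay the recipient's registry is identical to the source's, so the
#' invader's full ancestry is present by construction).
#'
#' @param w A `sim_world`.
#' @param genotype_id Pathogen genotype id to inject.
#' @param fraction Fraction of the world's cells to target, in (0, 1).
#' @param seed Integer seed of the dedicated injection stream.
#' @return Number of infections established, invisibly.
#' @export
inject_invader <- function(w, genotype_id, fraction = w$cfg$injection_fraction, seed) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (genotype_id > w$reg$n || genotype_id < 1L) {
    stop("unknown genotype id: ", genotype_id)
  }
  if (w$reg$kind[genotype_id] != 2L) stop("refusing to inject a host genotype as a pathogen")
  n <- .with_seed(seed, .inject_genotype(w, as.integer(genotype_id), fraction))
  invisible(n)
}

#' Run one paired experiment
#'
#' Runs the control trajectory to the end of the run, schedules the
#' manipulation, and replays the treated trajectory from the same seed so
#' both histories are bit-identical up to the manipulation update. At that
#' update the treated run receives, according to `kind`:
#'
#' * `"time_travel"`: a pathogen genotype sampled (abundance-weighted) from
#'   a past snapshot of the same community, required to have no living
#'   descendants at manipulation time (resampled up to `max_tries` times
#'   otherwise);
#' * `"contemporary"`: an extant pathogen genotype sampled
#'   abundance-weighted from the manipulation snapshot (controls for the
#'   density shock of injection itself);
#' * `"control_control"`: no injection; the treated run simply switches to a
#'   fresh RNG stream, giving an alternative future of the same community.
#'
#' Pairs whose pathogens are globally extinct before the manipulation are
#' flagged excluded (`"pathogen_extinct_pre_invasion"`) and carry no treated
#' trajectory, mirroring the campaign-level exclusion filter. The control
#' trajectory is the a-priori reference of every pair.
#'
#' @param cfg A `sim_config` (its `$seed` is the shared seed of the pair).
#' @param kind One of `"time_travel"`, `"control_control"`, `"contemporary"`.
#' @param pair_seed Integer seed for everything but the shared run stream:
#'   scheduling, invader sampling, injection, and the control-control
#'   reseed.
#' @param max_tries Resampling attempts for the extinct-lineage requirement.
#' @param audit_every Passed to [run_simulation()].
#' @return An object of class `sim_pair`.
#' @export
run_pair <- function(cfg, kind = c("time_travel", "control_control", "contemporary"),
                     pair_seed = cfg$seed, max_tries = 30L, audit_every = 0L) {
  kind <- match.arg(kind)
  seeds <- .derive_seeds(pair_seed, 3L)
  meta_seed <- seeds[1]
  inject_seed <- seeds[2]
  reseed_seed <- seeds[3]

  control <- run_simulation(cfg, audit_every = audit_every)

  res <- .with_seed(meta_seed, {
    times <- schedule_times(cfg, control$snapshots)
    out <- list(times = times, invader = NULL, reason = NULL)
    path_at_tman <- census_at(control, times$t_manipulate, "pathogen")
    if (nrow(path_at_tman) == 0L) {
      out$reason <- "pathogen_extinct_pre_invasion"
    } else if (kind == "time_travel") {
      win <- c(cfg$sample_window[1], cfg$sample_window[2])
      found <- FALSE
      for (i in seq_len(max_tries)) {
        inv <- tryCatch(sample_invader(control, win), error = function(e) NULL)
        if (is.null(inv)) break
        alive <- path_at_tman$genotype_id
        if (!any(.is_descendant_or_self(control$phylogeny, inv$genotype_id, alive))) {
          out$invader <- inv
          out$times$t_sample <- inv$t_sample
          found <- TRUE
          break
        }
      }
      if (!found) out$reason <- "invader_lineage_not_extinct"
    } else if (kind == "contemporary") {
      i <- sample.int(nrow(path_at_tman), 1L, prob = path_at_tman$abundance)
      out$invader <- list(genotype_id = path_at_tman$genotype_id[i],
                          t_sample = times$t_manipulate,
                          abundance = path_at_tman$abundance[i])
    }
    out
  })

  pair <- structure(list(
    kind = kind,
    config = cfg,
    pair_seed = pair_seed,
    t_sample = if (kind == "control_control") NA_integer_ else
      if (kind == "contemporary") res$times$t_manipulate else res$times$t_sample,
    t_manipulate = res$times$t_manipulate,
    invader = res$invader,
    n_injected = NA_integer_,
    reference = "control",
    control = control,
    treated = NULL,
    included = is.null(res$reason),
    exclusion_reason = if (is.null(res$reason)) NA_character_ else res$reason
  ), class = "sim_pair")
  if (!pair$included) return(pair)

  t_man <- pair$t_manipulate
  injected <- new.env(parent = emptyenv())
  ev <- switch(kind,
    time_travel = ,
    contemporary = list(list(update = t_man, fn = function(w) {
      injected$n <- inject_invader(w, pair$invader$genotype_id,
                                   cfg$injection_fraction, inject_seed)
    })),
    control_control = list(list(update = t_man, fn = function(w) {
      set.seed(reseed_seed)
    }))
  )
  pair$treated <- run_simulation(cfg, events = ev, audit_every = audit_every)
  pair$n_injected <- if (kind == "control_control") NA_integer_ else injected$n
  pair
}

# Which of `ids` are the root itself or descend from it? Children always
# have larger ids than their parents, so a single increasing pass suffices.
.is_descendant_or_self <- function(phylo, root, ids) {
  n <- nrow(phylo)
  parent <- phylo$parent_id
  desc <- logical(n)
  desc[root] <- TRUE
  if (root < n) {
    for (i in (root + 1L):n) {
      p <- parent[i]
      if (!is.na(p) && desc[p]) desc[i] <- TRUE
    }
  }
  desc[ids]
}

#' @export
print.sim_pair <- function(x, ...) {
  cat(sprintf("<sim_pair> %s, seed %d: t_sample %s, t_manipulate %d, %s\n",
              x$kind, x$pair_seed,
              ifelse(is.na(x$t_sample), "-", x$t_sample), x$t_manipulate,
              if (x$included) sprintf("included (injected %s)", x$n_injected)
              else paste0("excluded: ", x$exclusion_reason)))
  invisible(x)
}

#' Run a campaign of paired experiments
#'
#' Draws `n_configs` random world configurations and runs
#' `replicates_per_config` pairs of each, deriving every seed reproducibly
#' from `master_seed`. Pairs whose pathogens went extinct before the
#' manipulation are flagged excluded, mirroring the protocol's exclusion
#' filter.
#'
#' @param n_configs Number of random world configurations.
#' @param replicates_per_config Pairs per configuration.
#' @param kind Manipulation kind, as in [run_pair()].
#' @param master_seed Master seed for the whole campaign.
#' @param scale Scale factor passed to [build_config()].
#' @param ... Config overrides passed to [build_config()].
#' @param progress Print one line per completed pair.
#' @return An object of class `sim_campaign`: list of `sim_pair`s plus an
#'   inclusion summary.
#' @export
run_campaign <- function(n_configs, replicates_per_config = 1L,
                         kind = c("time_travel", "control_control", "contemporary"),
                         master_seed = 1L, scale = 0.04, ..., progress = FALSE) {
  kind <- match.arg(kind)
  stopifnot(n_configs >= 1L, replicates_per_config >= 1L)
  n_pairs <- n_configs * replicates_per_config
  seeds <- matrix(.derive_seeds(master_seed, 2L * n_pairs), ncol = 2L)
  pairs <- vector("list", n_pairs)
  k <- 0L
  for (i in seq_len(n_configs)) {
    for (j in seq_len(replicates_per_config)) {
      k <- k + 1L
      cfg <- build_config(seeds[k, 1L], scale = scale, ...)
      pairs[[k]] <- run_pair(cfg, kind, pair_seed = seeds[k, 2L])
      if (progress) {
        cat(sprintf("pair %d/%d (config %d, rep %d): %s\n", k, n_pairs, i, j,
                    if (pairs[[k]]$included) "included" else pairs[[k]]$exclusion_reason))
      }
    }
  }
  included <- vapply(pairs, `[[`, TRUE, "included")
  structure(list(
    pairs = pairs,
    kind = kind,
    master_seed = master_seed,
    scale = scale,
    included = included,
    exclusion_reason = vapply(pairs, `[[`, "", "exclusion_reason")
  ), class = "sim_campaign")
}

#' @export
print.sim_campaign <- function(x, ...) {
  cat(sprintf("<sim_campaign> %s: %d pairs, %d included\n",
              x$kind, length(x$pairs), sum(x$included)))
  if (any(!x$included)) {
    print(table(x$exclusion_reason[!x$included]))
  }
  invisible(x)
}
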