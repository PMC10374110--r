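#' Recording schedule for a run
#'
#' A recorder is a set of cadence segments `(from, to, step)`: the community
#' census is recorded at every update in `seq(from, to, by = step)` for each
#' segment, plus always at update 0. The full-scale protocol records every
#' 100 updates; the default recorder keeps that fine cadence (scaled)
#' throughout the run, which at reduced scale is cheap and gives every
#' analysis window full resolution.
#'
#' @param cfg A `sim_config`.
#' @param segments Optional data frame with columns `from`, `to`, `step`
#'   overriding the default single fine-cadence segment.
#' @return A `data.frame` of cadence segments.
#' @export
default_recorder <- function(cfg, segments = NULL) {
  if (is.null(segments)) {
    segments <- data.frame(from = 0L, to = cfg$total_updates, step = cfg$record_step)
  }
  stopifnot(all(c("from", "to", "step") %in% names(segments)), all(segments$step >= 1L))
  segments
}

#' Updates touched by a recorder
#'
#' @param recorder Cadence segments (see [default_recorder()]).
#' @param until Last update of the run.
#' @return Sorted integer vector of recorded updates (always includes 0).
#' @export
recorder_updates <- function(recorder, until) {
  ups <- unlist(lapply(seq_len(nrow(recorder)), function(i) {
    seq(recorder$from[i], min(recorder$to[i], until), by = recorder$step[i])
  }))
  sort(unique(c(0L, as.integer(ups[ups <= until & ups >= 0L]))))
}

#' Run a simulation
#'
#' Executes a world from a fresh initial state to `until`, recording the
#' community census (genotype abundances of hosts and pathogens, plus
#' pathogen-to-host infection edges) on the recorder's schedule. The run is
#' bit-deterministic given the configuration: the global RNG is seeded from
#' `cfg$seed` at the start, and every subsequent draw comes from that
#' stream.
#'
#' `events` supports the paired-experiment protocol: each event is a list
#' `list(update =, fn =)`; `fn(world)` is called after the dynamics of that
#' update and before the census of that update is recorded, so a
#' manipulation at update `t` is visible in the snapshot at `t` but in none
#' before it.
#'
#' @param cfg A `sim_config`.
#' @param until Final update (defaults to `cfg$total_updates`); must not
#'   exceed `cfg$total_updates`.
#' @param recorder Cadence segments from [default_recorder()].
#' @param events Optional list of manipulation events (see Details).
#' @param audit_every Audit the world invariants every this many updates
#'   (0 = never).
#' @return A `sim_trajectory`: list with `census`, `infections` and
#'   `phylogeny` data frames, the vector of recorded `snapshots`, the
#'   configuration, and the final world.
#' @export
run_simulation <- function(cfg, until = cfg$total_updates, recorder = default_recorder(cfg),
                           events = NULL, audit_every = 0L) {
  until <- as.integer(until)
  if (until > cfg$total_updates) stop("`until` exceeds cfg$total_updates")
  set.seed(cfg$seed)
  w <- init_world(cfg)
  rec_ups <- recorder_updates(recorder, until)
  chunks <- list()

  if (0L %in% rec_ups) chunks[[length(chunks) + 1L]] <- cpp_snapshot(w)

  ev_ups <- integer(0)
  if (length(events)) {
    ev_ups <- vapply(events, function(e) as.integer(e$update), 1L)
    ord <- order(ev_ups)
    events <- events[ord]
    ev_ups <- ev_ups[ord]
    if (any(ev_ups <= 0L) || any(duplicated(ev_ups))) {
      stop("event updates must be positive and distinct")
    }
  }

  cur <- 0L
  for (i in seq_along(ev_ups)) {
    b <- min(ev_ups[i], until)
    if (b > cur) {
      ## record everything in (cur, b) on schedule; the snapshot at b itself
      ## is taken only after the event has been applied
      chunks[[length(chunks) + 1L]] <-
        cpp_run_segment(w, b, setdiff(rec_ups, b), as.integer(audit_every))
      cur <- b
    }
    if (ev_ups[i] <= until) {
      events[[i]]$fn(w)
      if (b %in% rec_ups) chunks[[length(chunks) + 1L]] <- cpp_snapshot(w)
    }
  }
  if (until > cur) {
    chunks[[length(chunks) + 1L]] <-
      cpp_run_segment(w, until, rec_ups, as.integer(audit_every))
  }
  .assemble_trajectory(cfg, w, chunks)
}

.assemble_trajectory <- function(cfg, w, chunks) {
  census <- data.frame(
    update = unlist(lapply(chunks, `[[`, "cen_update")),
    genotype_id = unlist(lapply(chunks, `[[`, "cen_id")),
    kind = c("host", "pathogen")[unlist(lapply(chunks, `[[`, "cen_kind"))],
    abundance = unlist(lapply(chunks, `[[`, "cen_abund"))
  )
  infections <- data.frame(
    update = unlist(lapply(chunks, `[[`, "inf_update")),
    pathogen_genotype = unlist(lapply(chunks, `[[`, "inf_p")),
    host_genotype = unlist(lapply(chunks, `[[`, "inf_h")),
    count = unlist(lapply(chunks, `[[`, "inf_n"))
  )
  if (nrow(census) == 0L) census$kind <- character(0)
  structure(list(
    census = census,
    infections = infections,
    phylogeny = .registry_df(w$reg),
    snapshots = unique(census$update),
    config = cfg,
    final_world = w
  ), class = "sim_trajectory")
}

#' @export
print.sim_trajectory <- function(x, ...) {
  cat(sprintf("<sim_trajectory> %d snapshots (updates %d..%d), %d genotypes\n",
              length(x$snapshots),
              if (length(x$snapshots)) min(x$snapshots) else NA_integer_,
              if (length(x$snapshots)) max(x$snapshots) else NA_integer_,
              nrow(x$phylogeny)))
  invisible(x)
}

#' Census of one recorded update
#'
#' @param traj A `sim_trajectory`.
#' @param update A recorded update.
#' @param kind Optionally restrict to `"host"` or `"pathogen"` rows.
#' @return The census rows of that snapshot.
#' @export
census_at <- function(traj, update, kind = NULL) {
  rows <- traj$census[traj$census$update == update, , drop = FALSE]
  if (!is.null(kind)) rows <- rows[rows$kind == kind, , drop = FALSE]
  rows
}

#' Per-snapshot content hashes of a trajectory
#'
#' One hash per recorded update, covering the census rows and infection
#' edges of that snapshot. Two runs agree at an update if and only if the
#' hashes agree; this is the paired-replay identity check.
#'
#' @param traj A `sim_trajectory`.
#' @return Named character vector, one hash per recorded update.
#' @export
snapshot_hashes <- function(traj) {
  ups <- traj$snapshots
  h <- vapply(ups, function(u) {
    ci <- traj$census$update == u
    ii <- traj$infections$update == u
    rlang::hash(list(
      traj$census$genotype_id[ci], traj$census$kind[ci], traj$census$abundance[ci],
      traj$infections$pathogen_genotype[ii], traj$infections$host_genotype[ii],
      traj$infections$count[ii]
    ))
  }, "")
  stats::setNames(h, ups)
}

#' Hash an entire trajectory
#' @param traj A `sim_trajectory`.
#' @return A single content hash of census, infections and phylogeny.
#' @export
trajectory_hash <- function(traj) {
  rlang::hash(list(traj$census, traj$infections, traj$phylogeny))
}
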