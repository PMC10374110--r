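#' Shannon diversity of a community
#'
#' `H' = -sum(p_i * log(p_i))` with `p_i = n_i / N` the proportion of
#' individuals carrying the i-th genotype, in natural log units.
#'
#' @param abundances Positive abundance vector, one entry per genotype.
#' @return Shannon `H'` in nats; 0 for a single genotype.
#' @export
#' @examples
#' shannon(c(25, 25, 25, 25)) # log(4)
shannon <- function(abundances) {
  if (length(abundances) == 0L) stop("empty community")
  if (any(abundances <= 0)) stop("abundances must be positive")
  p <- abundances / sum(abundances)
  -sum(p * log(p))
}

#' Pielou evenness
#'
#' `J = H' / log(S)`; 1 when all genotypes are equally abundant. Defined as
#' 1 for a single-genotype community.
#'
#' @param abundances Positive abundance vector.
#' @return Evenness in `[0, 1]`.
#' @export
pielou <- function(abundances) {
  s <- length(abundances)
  if (s <= 1L) return(1)
  shannon(abundances) / log(s)
}

#' Faith's phylogenetic diversity
#'
#' Sum of the branch lengths of the minimal subtree connecting a set of
#' extant genotypes to the root(s) of the genotype phylogeny. Branch
#' lengths are measured in accumulated task substitutions
#' (`mutations_from_parent`) by default, or in updates between parent and
#' child birth times.
#'
#' @param phylo Phylogeny table (`id`, `parent_id`, `birth_update`,
#'   `mutations_from_parent`).
#' @param extant_ids Genotype ids alive in the snapshot.
#' @param branch_unit `"mutations"` or `"updates"`.
#' @return Total branch length of the spanning subtree.
#' @export
faith_pd <- function(phylo, extant_ids, branch_unit = c("mutations", "updates")) {
  branch_unit <- match.arg(branch_unit)
  if (length(extant_ids) == 0L) return(0)
  idx <- match(extant_ids, phylo$id)
  if (anyNA(idx)) stop("unknown genotype id(s): ",
                       paste(extant_ids[is.na(idx)], collapse = ", "))
  blen <- if (branch_unit == "mutations") {
    phylo$mutations_from_parent
  } else {
    phylo$birth_update - ifelse(is.na(phylo$parent_id), phylo$birth_update,
                                phylo$birth_update[match(phylo$parent_id, phylo$id)])
  }
  ## climb from every extant tip to the root, marking visited edges once
  in_tree <- logical(nrow(phylo))
  cur <- unique(idx)
  while (length(cur)) {
    fresh <- cur[!in_tree[cur]]
    if (!length(fresh)) break
    in_tree[fresh] <- TRUE
    par <- phylo$parent_id[fresh]
    cur <- match(par[!is.na(par)], phylo$id)
  }
  roots <- is.na(phylo$parent_id)
  sum(blen[in_tree & !roots])
}

#' Diversity series of a trajectory
#'
#' Per recorded update: genotype richness `S`, total abundance `N`, Shannon
#' `H'`, Pielou evenness, and (optionally) Faith's phylogenetic diversity,
#' restricted to one kind of organism (free-living hosts by default, as in
#' the community-impact analyses).
#'
#' @param traj A `sim_trajectory`.
#' @param kind `"host"` or `"pathogen"`.
#' @param updates Optional subset of recorded updates.
#' @param include_pd Also compute Faith's PD (costlier) per update.
#' @param branch_unit Branch-length unit for PD, see [faith_pd()].
#' @return A `data.frame` with one row per update.
#' @export
diversity_series <- function(traj, kind = "host", updates = NULL,
                             include_pd = FALSE, branch_unit = "mutations") {
  cen <- traj$census[traj$census$kind == kind, , drop = FALSE]
  if (!is.null(updates)) cen <- cen[cen$update %in% updates, , drop = FALSE]
  ups <- unique(cen$update)
  out <- data.frame(
    update = ups,
    richness = as.integer(tapply(cen$genotype_id, cen$update, length)[as.character(ups)]),
    abundance = as.integer(tapply(cen$abundance, cen$update, sum)[as.character(ups)]),
    shannon = as.numeric(tapply(cen$abundance, cen$update, shannon)[as.character(ups)]),
    evenness = as.numeric(tapply(cen$abundance, cen$update, pielou)[as.character(ups)])
  )
  if (include_pd) {
    out$pd <- vapply(ups, function(u) {
      faith_pd(traj$phylogeny, cen$genotype_id[cen$update == u], branch_unit)
    }, 1)
  }
  out[order(out$update), , drop = FALSE]
}

#' Relative diversity change between paired trajectories (AUC)
#'
#' Computes the area under the curve of a diversity measure versus time over
#' a fixed post-manipulation window (2,500 updates at 100-update resolution
#' at full scale, i.e. 1% of the run) for the control and treated series,
#' and quantifies the manipulation's effect as the relative percent change
#' `100 * (A_con - A_inv) / A_con`. Positive values are diversity losses in
#' the treated community, negative values gains. A per-timepoint change
#' series `100 * (div_con - div_inv) / div_con` accompanies the overall
#' statistic.
#'
#' @param control,treated Diversity series ([diversity_series()]) covering
#'   `[t0, t0 + window]` at `resolution`.
#' @param t0 Start of the window (the manipulation update).
#' @param window Window length in updates.
#' @param resolution Sampling resolution in updates.
#' @param metric Column to compare (default `"richness"`, as reported in the
#'   headline analyses).
#' @return An object of class `auc_change`: list with `window`,
#'   `signed_change`, `abs_change`, the AUCs, and the per-timepoint series.
#' @export
auc_change <- function(control, treated, t0, window, resolution, metric = "richness") {
  grid <- seq(t0, t0 + window, by = resolution)
  ic <- match(grid, control$update)
  it <- match(grid, treated$update)
  if (anyNA(ic) || anyNA(it)) stop("series do not cover the window at this resolution")
  yc <- control[[metric]][ic]
  yt <- treated[[metric]][it]
  a_con <- pracma::trapz(grid, yc)
  a_inv <- pracma::trapz(grid, yt)
  if (a_con == 0) stop("control AUC is zero; relative change undefined")
  signed <- 100 * (a_con - a_inv) / a_con
  structure(list(
    window = window,
    metric = metric,
    auc_control = a_con,
    auc_treated = a_inv,
    signed_change = signed,
    abs_change = abs(signed),
    timepoints = data.frame(
      update = grid,
      control = yc,
      treated = yt,
      change = ifelse(yc == 0, NA_real_, 100 * (yc - yt) / yc)
    )
  ), class = "auc_change")
}

#' @export
print.auc_change <- function(x, ...) {
  cat(sprintf("<auc_change> %s over %d updates: signed %+.3f%% (|%.3f%%|)\n",
              x$metric, x$window, x$signed_change, x$abs_change))
  invisible(x)
}

#' Diversity change of a pair
#'
#' Convenience wrapper: computes the control and treated diversity series of
#' a pair over the post-manipulation window and returns [auc_change()].
#' For control-control pairs the control run is the a-priori reference.
#'
#' @param pair An included `sim_pair`.
#' @param window Window length (defaults to the configuration's window).
#' @param resolution Resolution (defaults to the configuration's).
#' @param metric Diversity column, see [auc_change()].
#' @return An `auc_change` object.
#' @export
pair_change <- function(pair, window = pair$config$auc_window,
                        resolution = pair$config$auc_resolution,
                        metric = "richness") {
  if (!pair$included || is.null(pair$treated)) stop("pair carries no treated trajectory")
  t0 <- pair$t_manipulate
  ups <- seq(t0, t0 + window, by = resolution)
  con <- diversity_series(pair$control, "host", updates = ups)
  trt <- diversity_series(pair$treated, "host", updates = ups)
  auc_change(con, trt, t0, window, resolution, metric)
}

#' Sensitivity of the change statistic to the window length
#'
#' Recomputes the relative diversity change for a grid of window lengths
#' (500--5,000 updates at full scale, scaled proportionally).
#'
#' @param pair An included `sim_pair`.
#' @param windows Integer vector of window lengths; defaults to the
#'   `{500, 1000, 2500, 5000}` grid scaled by the configuration.
#' @param metric Diversity column.
#' @return A `data.frame` with one row per window: `window`,
#'   `signed_change`, `abs_change`.
#' @export
window_sensitivity <- function(pair, windows = NULL, metric = "richness") {
  cfg <- pair$config
  if (is.null(windows)) {
    windows <- unique(pmax(cfg$auc_resolution,
                           as.integer(round(c(500, 1000, 2500, 5000) * cfg$scale))))
  }
  res <- lapply(windows, function(w) {
    ch <- pair_change(pair, window = w, metric = metric)
    data.frame(window = w, signed_change = ch$signed_change, abs_change = ch$abs_change)
  })
  do.call(rbind, res)
}

#' Exceedance of treated changes over a null distribution
#'
#' Fraction of treated diversity changes exceeding the given percentile of
#' the null (control-control) change distribution.
#'
#' @param treated_changes Numeric vector of changes from manipulated pairs.
#' @param null_changes Numeric vector of changes from control-control pairs.
#' @param percentile Percentile of the null distribution (default 95).
#' @return Fraction in `[0, 1]`.
#' @export
exceedance_vs_null <- function(treated_changes, null_changes, percentile = 95) {
  if (!length(treated_changes) || !length(null_changes)) stop("both samples must be non-empty")
  thr <- stats::quantile(null_changes, percentile / 100, names = FALSE)
  mean(treated_changes > thr)
}
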