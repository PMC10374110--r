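# Membership of census genotypes in lineages rooted at given genotypes.
# A genotype belongs to the lineage of root r iff it is r or descends from
# it. Returns a logical matrix [length(gids) x length(roots)].
.lineage_membership <- function(phylo, gids, roots) {
  ug <- unique(gids)
  parent <- phylo$parent_id
  m <- matrix(FALSE, length(ug), length(roots))
  cur <- ug
  repeat {
    active <- which(!is.na(cur))
    if (!length(active)) break
    hit <- match(cur[active], roots)
    found <- which(!is.na(hit))
    if (length(found)) m[cbind(active[found], hit[found])] <- TRUE
    cur[active] <- parent[cur[active]]
  }
  m[match(gids, ug), , drop = FALSE]
}

#' Post-manipulation persistence of a lineage
#'
#' The persistence of a lineage (a root genotype plus all its descendants)
#' is the number of updates after the manipulation during which the lineage
#' remains extant, assessed on the recorded cadence with the last-seen
#' convention -- a lineage recorded alive at snapshot `s` and gone at the
#' next is credited through `s` -- and capped at `cap` updates (one fifth of
#' the run, 50,000 updates at full scale). The same convention applies to
#' invaders and native pathogens alike, so comparisons are fair.
#'
#' @param traj A `sim_trajectory` (normally the treated run of a pair).
#' @param root Root genotype id of the lineage.
#' @param t_manipulate Manipulation update (must be a recorded snapshot).
#' @param cap Horizon in updates (defaults to the configuration's cap).
#' @return Persistence in updates, in `[0, cap]`.
#' @export
lineage_persistence <- function(traj, root, t_manipulate,
                                cap = traj$config$persistence_cap) {
  if (root < 1L || root > nrow(traj$phylogeny)) stop("unknown root genotype: ", root)
  cen <- traj$census
  sel <- cen$update > t_manipulate & cen$update <= t_manipulate + cap &
    cen$kind == "pathogen"
  if (!any(sel)) return(0L)
  gids <- cen$genotype_id[sel]
  member <- .lineage_membership(traj$phylogeny, gids, root)[, 1L]
  if (!any(member)) return(0L)
  min(max(cen$update[sel][member]) - t_manipulate, cap)
}

#' Persistence table for all pathogen lineages of a pair
#'
#' One row per pathogen genotype alive at the manipulation update in the
#' treated community (the invader plus the natives), with its
#' post-manipulation lineage persistence, its population size at
#' manipulation time, and the invader flag.
#'
#' @param pair A `sim_pair` (must be included and carry a treated run).
#' @param cap Persistence horizon in updates.
#' @return A `data.frame` with columns `genotype_id`, `persistence`,
#'   `n_at_manipulation`, `is_invader`.
#' @export
persistence_table <- function(pair, cap = pair$config$persistence_cap) {
  if (!pair$included || is.null(pair$treated)) stop("pair carries no treated trajectory")
  traj <- pair$treated
  t_man <- pair$t_manipulate
  rows <- census_at(traj, t_man, "pathogen")
  if (nrow(rows) == 0L) stop("no pathogens alive at the manipulation update")
  inv_id <- if (!is.null(pair$invader)) pair$invader$genotype_id else NA_integer_
  if (!is.na(inv_id) && !inv_id %in% rows$genotype_id) {
    ## a failed injection (zero propagules established) still yields an
    ## invader row: persistence 0, population 0
    rows <- rbind(rows, data.frame(update = t_man, genotype_id = inv_id,
                                   kind = "pathogen", abundance = 0L))
  }
  cen <- traj$census
  sel <- cen$update > t_man & cen$update <= t_man + cap & cen$kind == "pathogen"
  roots <- rows$genotype_id
  persistence <- integer(length(roots))
  if (any(sel)) {
    gids <- cen$genotype_id[sel]
    ups <- cen$update[sel]
    member <- .lineage_membership(traj$phylogeny, gids, roots)
    for (j in seq_along(roots)) {
      if (any(member[, j])) {
        persistence[j] <- min(max(ups[member[, j]]) - t_man, cap)
      }
    }
  }
  data.frame(
    genotype_id = roots,
    persistence = persistence,
    n_at_manipulation = rows$abundance,
    is_invader = !is.na(inv_id) & roots == inv_id
  )
}

#' Fraction of qualifying natives less persistent than the invader
#'
#' Compares the invader's lineage persistence with that of the native
#' pathogens of the invaded community, restricted to natives whose
#' population size at manipulation time is at least the invader's (removing
#' the bias from differing initial population sizes). Returns the fraction
#' of those qualifying natives that are strictly less persistent than the
#' invader.
#'
#' @param table A persistence table from [persistence_table()].
#' @return Fraction in `[0, 1]`.
#' @export
native_comparison <- function(table) {
  inv <- table[table$is_invader, , drop = FALSE]
  if (nrow(inv) != 1L) stop("persistence table must contain exactly one invader row")
  natives <- table[!table$is_invader, , drop = FALSE]
  qual <- natives[natives$n_at_manipulation >= inv$n_at_manipulation, , drop = FALSE]
  if (nrow(qual) == 0L) {
    stop("no qualifying natives: every native is smaller than the invader")
  }
  mean(qual$persistence < inv$persistence)
}

#' Invader prevalence series
#'
#' At each recorded update after the manipulation, the invader lineage's
#' share of pathogen species (distinct genotypes) and of pathogen
#' individuals, in percent. Updates with no pathogens at all are omitted.
#'
#' @param traj The treated `sim_trajectory`.
#' @param root Invader genotype id.
#' @param t_manipulate Manipulation update.
#' @param cap Horizon in updates (default: to the end of the run).
#' @return A `data.frame` with columns `update`, `species_share`,
#'   `individual_share` (percent).
#' @export
prevalence_series <- function(traj, root, t_manipulate, cap = Inf) {
  cen <- traj$census
  sel <- cen$update > t_manipulate & cen$update <= t_manipulate + cap &
    cen$kind == "pathogen"
  if (!any(sel)) {
    return(data.frame(update = integer(0), species_share = numeric(0),
                      individual_share = numeric(0)))
  }
  sub <- cen[sel, , drop = FALSE]
  member <- .lineage_membership(traj$phylogeny, sub$genotype_id, root)[, 1L]
  sp <- tapply(member, sub$update, mean)
  ind <- tapply(sub$abundance * member, sub$update, sum) /
    tapply(sub$abundance, sub$update, sum)
  data.frame(update = as.integer(names(sp)),
             species_share = 100 * as.numeric(sp),
             individual_share = 100 * as.numeric(ind))
}

#' Exact excess-persistence test
#'
#' Upper-tail binomial probability of observing at least `k` highly
#' persistent invaders among `n`, if each independently reached the
#' persistence cap with the baseline probability `q` (the campaign-wide
#' fraction of native lineages reaching the cap). Computed in log space via
#' the binomial distribution function, so astronomically small tails are
#' representable.
#'
#' @param k Observed number of highly persistent invaders.
#' @param n Number of invaders.
#' @param q Baseline probability of high persistence, in (0, 1).
#' @return P(X >= k) for X ~ Binomial(n, q).
#' @export
excess_persistence_test <- function(k, n, q) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  if (k < 0 || k > n) stop("k must be in [0, n]")
  if (k == 0) return(1)
  exp(stats::pbinom(k - 1, n, q, lower.tail = FALSE, log.p = TRUE))
}
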