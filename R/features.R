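# Root path of a genotype: ids from the genotype up to its root, with
# cumulative branch lengths (mutation counts) from the genotype.
.root_path <- function(phylo, id) {
  ids <- integer(0)
  dist <- numeric(0)
  d <- 0
  cur <- id
  while (!is.na(cur)) {
    ids <- c(ids, cur)
    dist <- c(dist, d)
    p <- phylo$parent_id[cur]
    if (!is.na(p)) d <- d + phylo$mutations_from_parent[cur]
    cur <- p
  }
  list(ids = ids, dist = dist)
}

#' Patristic distance between genotypes
#'
#' Path length between two genotypes on the genotype phylogeny, in
#' accumulated task substitutions (`mutations_from_parent`).
#'
#' @param phylo Phylogeny table.
#' @param a,b Genotype ids (`b` may be a vector).
#' @return Numeric distance(s); `Inf` between different roots' trees.
#' @export
phylo_distance <- function(phylo, a, b) {
  pa <- .root_path(phylo, a)
  vapply(b, function(bb) {
    d <- 0
    cur <- bb
    while (!is.na(cur)) {
      hit <- match(cur, pa$ids)
      if (!is.na(hit)) return(d + pa$dist[hit])
      d <- d + phylo$mutations_from_parent[cur]
      cur <- phylo$parent_id[cur]
    }
    Inf
  }, 1)
}

#' Extract the invasion-predictor features of a pair
#'
#' Populates the 21 features of the invader and the invaded community used
#' in the correlation screen, plus the three outcomes (invader persistence,
#' signed and absolute relative diversity change). Features i--iii describe
#' the simulated environment (world size, net resource inflow per update,
#' number of distinct available resources); iv--ix the recipient community
#' at the time of invasion (free-living and pathogen richness, abundance,
#' and density); x--xiii the invader's first, pre-invasion existence
#' (lineage persistence, mean and total abundance across the updates where
#' it was present, and abundance in the source snapshot); xiv--xv its task
#' repertoire (count and maximum complexity); xvi--xvii its generalism
#' (distinct host species infected in the source community, and the median
#' over the post-invasion window); xviii the mean phylogenetic distance to
#' the native pathogens; and xix--xxi the timing variables (source-invasion
#' time difference, invader age at sampling, recipient community age).
#'
#' The 17-feature modelling subset used by the random-forest models drops
#' i--iii and xvii; it is recorded in the `modelling` attribute.
#'
#' @param pair An included `sim_pair` with an invader (time-travel or
#'   contemporary kind).
#' @param ptab Persistence table of the pair (computed if missing).
#' @param change `auc_change` of the pair (computed if missing).
#' @return A one-row `data.frame` of features and outcomes.
#' @export
extract_features <- function(pair, ptab = persistence_table(pair),
                             change = pair_change(pair)) {
  if (!pair$included || is.null(pair$treated)) stop("pair carries no treated trajectory")
  if (is.null(pair$invader)) stop("pair has no injected genotype")
  cfg <- pair$config
  con <- pair$control
  t_man <- pair$t_manipulate
  inv_id <- pair$invader$genotype_id

  hosts <- census_at(con, t_man, "host")
  paths <- census_at(con, t_man, "pathogen")

  ## invader pre-invasion lineage presence in the source (control) history
  cen <- con$census
  pre <- cen$update <= t_man & cen$kind == "pathogen"
  member <- .lineage_membership(con$phylogeny, cen$genotype_id[pre], inv_id)[, 1L]
  pre_ups <- cen$update[pre][member]
  pre_ab <- cen$abundance[pre][member]
  lineage_span <- if (length(pre_ups)) max(pre_ups) - min(pre_ups) else 0L
  per_update_ab <- if (length(pre_ups)) tapply(pre_ab, pre_ups, sum) else numeric(0)

  ## source-community generalism: distinct host genotypes carrying the
  ## invader genotype in the source snapshot
  inf_src <- con$infections
  src_sel <- inf_src$update == pair$t_sample & inf_src$pathogen_genotype == inv_id
  generalism_src <- length(unique(inf_src$host_genotype[src_sel]))

  ## post-invasion generalism: per window snapshot, distinct host genotypes
  ## infected by the invader lineage (0 when absent); median over snapshots
  trt <- pair$treated
  w_ups <- trt$snapshots[trt$snapshots > t_man & trt$snapshots <= t_man + cfg$auc_window]
  inf_trt <- trt$infections
  w_sel <- inf_trt$update %in% w_ups
  gen_post <- stats::setNames(numeric(length(w_ups)), w_ups)
  if (any(w_sel)) {
    sub <- inf_trt[w_sel, , drop = FALSE]
    memb <- .lineage_membership(trt$phylogeny, sub$pathogen_genotype, inv_id)[, 1L]
    sub <- sub[memb, , drop = FALSE]
    if (nrow(sub)) {
      cnt <- tapply(sub$host_genotype, sub$update, function(h) length(unique(h)))
      gen_post[names(cnt)] <- cnt
    }
  }

  ## mean phylogenetic distance to native pathogens at invasion time
  natives <- setdiff(paths$genotype_id, inv_id)
  mean_pd <- if (length(natives)) mean(phylo_distance(con$phylogeny, inv_id, natives)) else NA_real_

  inv_mask <- .string_mask(con$phylogeny$task_bits[match(inv_id, con$phylogeny$id)])
  inv_row <- ptab[ptab$is_invader, , drop = FALSE]

  out <- data.frame(
    world_size = cfg$n_cells,
    net_resources = sum(cfg$inflow_max) / 2,   # expected total inflow per update
    resource_types = sum(cfg$inflow_max > 0),
    host_richness = nrow(hosts),
    path_richness = nrow(paths),
    host_abundance = sum(hosts$abundance),
    path_abundance = sum(paths$abundance),
    host_density = sum(hosts$abundance) / cfg$n_cells,
    path_density = sum(paths$abundance) / cfg$n_cells,
    inv_pre_persistence = lineage_span,
    inv_pre_mean_abundance = if (length(per_update_ab)) mean(per_update_ab) else 0,
    inv_pre_total_abundance = sum(pre_ab),
    inv_source_abundance = pair$invader$abundance,
    inv_task_count = task_count(inv_mask),
    inv_task_complexity = task_complexity_max(inv_mask),
    inv_generalism_source = generalism_src,
    inv_generalism_post = stats::median(gen_post),
    inv_phylo_distance = mean_pd,
    time_gap = t_man - pair$t_sample,
    inv_age = pair$t_sample,
    community_age = t_man,
    persistence = inv_row$persistence,
    signed_change = change$signed_change,
    abs_change = change$abs_change
  )
  attr(out, "modelling") <- setdiff(
    names(out)[1:21],
    c("world_size", "net_resources", "resource_types", "inv_generalism_post")
  )
  out
}

#' Feature table of a campaign
#'
#' One row per included pair with an injected genotype, combining
#' [extract_features()] across the campaign.
#'
#' @param campaign A `sim_campaign` of time-travel or contemporary pairs.
#' @return A `data.frame`; the `modelling` attribute names the 17-feature
#'   modelling subset.
#' @export
feature_table <- function(campaign) {
  rows <- lapply(campaign$pairs, function(p) {
    if (!p$included || is.null(p$invader)) return(NULL)
    extract_features(p)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) stop("campaign contains no included pairs with an invader")
  out <- do.call(rbind, rows)
  attr(out, "modelling") <- attr(rows[[1]], "modelling")
  out
}
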