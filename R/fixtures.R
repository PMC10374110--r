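# Assemble a minimal trajectory object from plain tables (used by the
# fixture recipes and by tests that need hand-constructed communities).
.toy_trajectory <- function(census, infections, phylogeny, config = NULL) {
  structure(list(
    census = census,
    infections = infections,
    phylogeny = phylogeny,
    snapshots = unique(census$update),
    config = config,
    final_world = NULL
  ), class = "sim_trajectory")
}

.toy_phylogeny <- function(id, parent_id, kind, birth_update, mutations, mask) {
  data.frame(
    id = as.integer(id),
    parent_id = as.integer(parent_id),
    kind = kind,
    birth_update = as.integer(birth_update),
    mutations_from_parent = as.integer(mutations),
    task_bits = .mask_string(as.integer(mask))
  )
}

#' Deterministic test-pair fixtures with known ground truth
#'
#' Builds small, fully constructed experiment pairs whose metric values are
#' known by design, for testing the analysis layer independently of the
#' simulator:
#'
#' * `"identical_pair"`: control and treated trajectories are identical;
#'   every relative change is exactly 0.
#' * `"invader_takeover"`: after the manipulation the invader lineage is the
#'   only pathogen lineage; prevalence reaches (100%, 100%).
#' * `"loss_05pct"`: treated host richness is uniformly 19 versus 20 in the
#'   control over the window; the signed change is exactly +5%.
#'
#' The ground truth of each recipe is stored in the pair's `manifest`
#' element, computed by direct construction.
#'
#' @param name Recipe name.
#' @param seed Seed for the randomised parts of the censuses.
#' @return A `sim_pair` with a `manifest` list.
#' @export
make_fixture <- function(name = c("identical_pair", "invader_takeover", "loss_05pct"),
                         seed = 1L) {
  name <- match.arg(name)
  t_man <- 50L
  step <- 10L
  ups <- seq(0L, 100L, by = step)
  cfg <- list(persistence_cap = 40L, auc_window = 40L, auc_resolution = step,
              total_updates = 100L, n_cells = 100L,
              sample_window = c(20L, 60L), manipulate_window = c(60L, 80L),
              inflow_max = rep(1, 9), scale = 1)

  ## shared phylogeny: host root 1 with children 2,3; pathogen root 4 with
  ## native child 5, invader 6 (child of 4), invader descendant 7
  phylo <- .toy_phylogeny(
    id = 1:7,
    parent_id = c(NA, 1, 1, NA, 4, 4, 6),
    kind = c("host", "host", "host", "pathogen", "pathogen", "pathogen", "pathogen"),
    birth_update = c(0, 10, 10, 0, 20, 20, 60),
    mutations = c(0, 1, 2, 0, 1, 1, 1),
    mask = c(1, 3, 5, 1, 3, 7, 7)
  )

  host_census <- function(rich) {
    do.call(rbind, lapply(ups, function(u) {
      data.frame(update = u, genotype_id = seq_len(rich), kind = "host",
                 abundance = rep(5L, rich))
    }))
  }

  if (name == "identical_pair") {
    set.seed(seed)
    ab <- matrix(sample(1:50, 3 * length(ups), replace = TRUE), ncol = 3)
    cen <- do.call(rbind, lapply(seq_along(ups), function(i) {
      rbind(
        data.frame(update = ups[i], genotype_id = 1:3, kind = "host", abundance = ab[i, ]),
        data.frame(update = ups[i], genotype_id = 4:5, kind = "pathogen", abundance = c(4L, 2L))
      )
    }))
    inf <- data.frame(update = integer(0), pathogen_genotype = integer(0),
                      host_genotype = integer(0), count = integer(0))
    control <- .toy_trajectory(cen, inf, phylo, cfg)
    pair <- list(kind = "control_control", config = cfg, pair_seed = seed,
                 t_sample = NA_integer_, t_manipulate = t_man, invader = NULL,
                 n_injected = NA_integer_, reference = "control",
                 control = control, treated = control,
                 included = TRUE, exclusion_reason = NA_character_,
                 manifest = list(signed_change = 0, abs_change = 0))
    return(structure(pair, class = "sim_pair"))
  }

  if (name == "invader_takeover") {
    ## pathogens: natives 4,5 before t_man; invader 6 (+ descendant 7) alone after
    cen <- do.call(rbind, lapply(ups, function(u) {
      paths <- if (u < t_man) {
        data.frame(update = u, genotype_id = 4:5, kind = "pathogen", abundance = c(6L, 4L))
      } else if (u == t_man) {
        data.frame(update = u, genotype_id = c(4L, 5L, 6L), kind = "pathogen",
                   abundance = c(6L, 4L, 5L))
      } else {
        data.frame(update = u, genotype_id = c(6L, 7L), kind = "pathogen",
                   abundance = c(3L, 9L))[if (u >= 70L) 1:2 else 1L, , drop = FALSE]
      }
      rbind(data.frame(update = u, genotype_id = 1:2, kind = "host",
                       abundance = c(30L, 20L)), paths)
    }))
    inf <- data.frame(update = t_man, pathogen_genotype = 6L, host_genotype = 1:2,
                      count = c(3L, 2L))
    control_cen <- cen[!(cen$genotype_id %in% c(6L, 7L)), , drop = FALSE]
    control <- .toy_trajectory(control_cen, inf[0, ], phylo, cfg)
    treated <- .toy_trajectory(cen, inf, phylo, cfg)
    pair <- list(kind = "time_travel", config = cfg, pair_seed = seed,
                 t_sample = 30L, t_manipulate = t_man,
                 invader = list(genotype_id = 6L, t_sample = 30L, abundance = 5L),
                 n_injected = 5L, reference = "control",
                 control = control, treated = treated,
                 included = TRUE, exclusion_reason = NA_character_,
                 manifest = list(final_species_share = 100, final_individual_share = 100,
                                 invader_persistence = 40L))
    return(structure(pair, class = "sim_pair"))
  }

  ## loss_05pct: 20 vs 19 equally-abundant host genotypes at every snapshot
  ## in the window; by construction the AUC ratio gives a +5% signed change.
  pathogen_rows <- function(u) {
    data.frame(update = u, genotype_id = 4:5, kind = "pathogen", abundance = c(2L, 2L))
  }
  phylo20 <- .toy_phylogeny(
    id = 1:25,
    parent_id = c(NA, rep(1L, 19), NA, 21, 21, 22, 22),
    kind = c(rep("host", 20), rep("pathogen", 5)),
    birth_update = c(0, rep(5, 19), 0, rep(10, 4)),
    mutations = c(0, rep(1, 19), 0, rep(1, 4)),
    mask = c(rep(1, 20), rep(3, 5))
  )
  mk <- function(rich) {
    cen <- do.call(rbind, lapply(ups, function(u) {
      rbind(
        data.frame(update = u, genotype_id = seq_len(rich), kind = "host",
                   abundance = rep(5L, rich)),
        data.frame(update = u, genotype_id = c(21L, 22L), kind = "pathogen",
                   abundance = c(2L, 2L))
      )
    }))
    .toy_trajectory(cen, data.frame(update = integer(0), pathogen_genotype = integer(0),
                                    host_genotype = integer(0), count = integer(0)),
                    phylo20, cfg)
  }
  pair <- list(kind = "time_travel", config = cfg, pair_seed = seed,
               t_sample = 30L, t_manipulate = t_man,
               invader = list(genotype_id = 22L, t_sample = 30L, abundance = 2L),
               n_injected = 2L, reference = "control",
               control = mk(20L), treated = mk(19L),
               included = TRUE, exclusion_reason = NA_character_,
               manifest = list(signed_change = 100 * (20 - 19) / 20))
  structure(pair, class = "sim_pair")
}
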