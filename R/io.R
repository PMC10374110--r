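# Versioned tab-separated tables with a one-line `#schema=` comment. A
# clean, explicit schema beats ad-hoc dumps: anyone importing genuine
# digital-evolution detail dumps can map columns onto these.
.SCHEMAS <- c(census = "invasim-census-1",
              infections = "invasim-infections-1",
              phylogeny = "invasim-phylogeny-1")

.write_tsv <- function(df, path, schema) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#schema=", schema), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_tsv <- function(path, schema) {
  first <- readLines(path, n = 1L)
  if (!identical(first, paste0("#schema=", schema))) {
    stop(path, ": expected schema '", schema, "', found '", first, "'")
  }
  utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                    stringsAsFactors = FALSE, colClasses = NA)
}

#' Write a trajectory to a directory
#'
#' Writes the census, infection and phylogeny tables as tab-separated files
#' with schema headers, plus Newick exports of the host and pathogen
#' genotype trees.
#'
#' @param traj A `sim_trajectory`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_trajectory <- function(traj, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_tsv(traj$census, file.path(dir, "census.tsv"), .SCHEMAS["census"])
  .write_tsv(traj$infections, file.path(dir, "infections.tsv"), .SCHEMAS["infections"])
  .write_tsv(traj$phylogeny, file.path(dir, "phylogeny.tsv"), .SCHEMAS["phylogeny"])
  nwk <- export_newick(traj$phylogeny)
  writeLines(nwk, file.path(dir, "phylogeny.nwk"))
  invisible(dir)
}

#' Read a trajectory from a directory
#'
#' Reads and schema-validates the tables written by [write_trajectory()]:
#' abundances and counts must be positive, snapshot updates non-decreasing
#' in file order, every parent link must resolve, and every census genotype
#' must exist in the phylogeny.
#'
#' @param dir Directory holding `census.tsv`, `infections.tsv`,
#'   `phylogeny.tsv`.
#' @return A `sim_trajectory` (without a live final world).
#' @export
read_trajectory <- function(dir) {
  census <- .read_tsv(file.path(dir, "census.tsv"), .SCHEMAS["census"])
  infections <- .read_tsv(file.path(dir, "infections.tsv"), .SCHEMAS["infections"])
  phylogeny <- .read_tsv(file.path(dir, "phylogeny.tsv"), .SCHEMAS["phylogeny"])

  if (nrow(census)) {
    bad <- which(census$abundance <= 0)
    if (length(bad)) stop("census.tsv line ", bad[1] + 2L, ": non-positive abundance")
    if (is.unsorted(census$update)) {
      stop("census.tsv: snapshot updates must be non-decreasing")
    }
    if (!all(census$kind %in% c("host", "pathogen"))) stop("census.tsv: unknown kind")
  }
  if (nrow(infections)) {
    bad <- which(infections$count <= 0)
    if (length(bad)) stop("infections.tsv line ", bad[1] + 2L, ": non-positive count")
  }
  if (nrow(phylogeny)) {
    known <- phylogeny$parent_id %in% phylogeny$id | is.na(phylogeny$parent_id)
    if (!all(known)) {
      stop("phylogeny.tsv line ", which(!known)[1] + 2L, ": unknown parent id")
    }
    phylogeny$task_bits <- formatC(phylogeny$task_bits, width = 9, flag = "0")
  }
  miss <- setdiff(census$genotype_id, phylogeny$id)
  if (length(miss)) stop("census references genotypes absent from the phylogeny: ",
                         paste(utils::head(miss), collapse = ", "))
  structure(list(
    census = census,
    infections = infections,
    phylogeny = phylogeny,
    snapshots = unique(census$update),
    config = NULL,
    final_world = NULL
  ), class = "sim_trajectory")
}

#' Write / read a configuration file
#'
#' Configurations are stored as YAML, one field per entry, so a pair is
#' fully regenerable from its directory.
#'
#' @param cfg A `sim_config`.
#' @param path File path.
#' @return `write_config`: `path` invisibly; `read_config`: a `sim_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 17L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- .normalize_config(yaml::read_yaml(path))
  validate_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Write / read a pair directory
#'
#' A pair directory holds the configuration, a provenance record (seeds,
#' times, injected genotype, inclusion state) and the control and treated
#' trajectories; it suffices to regenerate both trajectories bit-identically
#' via [run_pair()].
#'
#' @param pair A `sim_pair`.
#' @param dir Output directory.
#' @return `write_pair_dir`: `dir` invisibly; `read_pair_dir`: a `sim_pair`
#'   (trajectories reloaded from the tables).
#' @export
write_pair_dir <- function(pair, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_config(pair$config, file.path(dir, "config.yml"))
  prov <- list(
    kind = pair$kind,
    pair_seed = pair$pair_seed,
    t_sample = pair$t_sample,
    t_manipulate = pair$t_manipulate,
    invader_genotype = if (is.null(pair$invader)) NA else pair$invader$genotype_id,
    invader_source_abundance = if (is.null(pair$invader)) NA else pair$invader$abundance,
    n_injected = pair$n_injected,
    reference = pair$reference,
    included = pair$included,
    exclusion_reason = pair$exclusion_reason
  )
  yaml::write_yaml(prov, file.path(dir, "provenance.yml"))
  write_trajectory(pair$control, file.path(dir, "control"))
  if (!is.null(pair$treated)) write_trajectory(pair$treated, file.path(dir, "treated"))
  invisible(dir)
}

#' @rdname write_pair_dir
#' @export
read_pair_dir <- function(dir) {
  cfg <- read_config(file.path(dir, "config.yml"))
  prov <- yaml::read_yaml(file.path(dir, "provenance.yml"))
  control <- read_trajectory(file.path(dir, "control"))
  control$config <- cfg
  treated <- NULL
  if (dir.exists(file.path(dir, "treated"))) {
    treated <- read_trajectory(file.path(dir, "treated"))
    treated$config <- cfg
  }
  invader <- NULL
  if (!is.null(prov$invader_genotype) && !is.na(prov$invader_genotype)) {
    invader <- list(genotype_id = prov$invader_genotype,
                    t_sample = prov$t_sample,
                    abundance = prov$invader_source_abundance)
  }
  structure(list(
    kind = prov$kind,
    config = cfg,
    pair_seed = prov$pair_seed,
    t_sample = if (is.null(prov$t_sample) || is.na(prov$t_sample)) NA_integer_ else prov$t_sample,
    t_manipulate = prov$t_manipulate,
    invader = invader,
    n_injected = prov$n_injected,
    reference = prov$reference,
    control = control,
    treated = treated,
    included = isTRUE(prov$included),
    exclusion_reason = if (is.null(prov$exclusion_reason) || is.na(prov$exclusion_reason))
      NA_character_ else prov$exclusion_reason
  ), class = "sim_pair")
}

#' Export a genotype phylogeny as Newick
#'
#' The genotype phylogeny is a forest with at most one host and one
#' pathogen root. Every genotype appears as a labelled node (`g<id>`);
#' genotypes with descendants become internal nodes. Branch lengths are
#' task substitutions from the parent (default) or update-time differences.
#'
#' @param phylo Phylogeny table.
#' @param branch_unit `"mutations"` or `"updates"`.
#' @return Character vector of Newick strings, one per root.
#' @export
export_newick <- function(phylo, branch_unit = c("mutations", "updates")) {
  branch_unit <- match.arg(branch_unit)
  n <- nrow(phylo)
  if (n == 0L) return(character(0))
  idx_of <- match(seq_len(max(phylo$id)), phylo$id)
  pidx <- idx_of[ifelse(is.na(phylo$parent_id), NA_integer_, phylo$parent_id)]
  if (any(!is.na(pidx) & pidx >= seq_len(n))) {
    stop("cyclic or forward parent links: parents must precede children")
  }
  blen <- if (branch_unit == "mutations") {
    phylo$mutations_from_parent
  } else {
    phylo$birth_update - ifelse(is.na(pidx), 0L, phylo$birth_update[pmax(pidx, 1L)])
  }
  children <- vector("list", n)
  for (i in seq_len(n)) {
    p <- pidx[i]
    if (!is.na(p)) children[[p]] <- c(children[[p]], i)
  }
  node_str <- character(n)
  for (i in n:1) {   # children have larger row indices, so they are ready
    label <- paste0("g", phylo$id[i])
    inner <- if (length(children[[i]])) {
      paste0("(", paste(node_str[children[[i]]], collapse = ","), ")")
    } else {
      ""
    }
    node_str[i] <- if (is.na(pidx[i])) {
      paste0(inner, label, ";")
    } else {
      paste0(inner, label, ":", format(blen[i], scientific = FALSE))
    }
  }
  node_str[is.na(pidx)]
}
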