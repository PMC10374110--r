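# Independent brute-force oracles. Each recomputes a quantity from first
# principles, by explicit enumeration or summation, deliberately avoiding
# the code paths (and the library calls) used by the implementation.

shannon_oracle <- function(ab) {
  n <- sum(ab)
  h <- 0
  for (a in ab) h <- h - (a / n) * log(a / n)
  h
}

# Faith's PD: union of root paths, edge by edge.
pd_oracle <- function(phylo, ids, unit = "mutations") {
  edges <- character(0)
  total <- 0
  for (id in unique(ids)) {
    cur <- id
    repeat {
      row <- which(phylo$id == cur)
      p <- phylo$parent_id[row]
      if (is.na(p)) break
      key <- as.character(cur)
      if (!key %in% edges) {
        edges <- c(edges, key)
        len <- if (unit == "mutations") {
          phylo$mutations_from_parent[row]
        } else {
          phylo$birth_update[row] - phylo$birth_update[phylo$id == p]
        }
        total <- total + len
      }
      cur <- p
    }
  }
  total
}

# All descendants of `root` (plus root), by repeated scanning.
descendants_oracle <- function(phylo, root) {
  members <- root
  repeat {
    more <- phylo$id[!is.na(phylo$parent_id) & phylo$parent_id %in% members &
                       !phylo$id %in% members]
    if (!length(more)) return(sort(members))
    members <- c(members, more)
  }
}

# Lineage persistence by exhaustive scan of the census table.
persistence_oracle <- function(census, phylo, root, t_man, cap) {
  members <- descendants_oracle(phylo, root)
  last <- NA_integer_
  for (u in sort(unique(census$update))) {
    if (u <= t_man || u > t_man + cap) next
    rows <- census[census$update == u & census$kind == "pathogen", ]
    if (any(rows$genotype_id %in% members)) last <- u
  }
  if (is.na(last)) 0L else min(last - t_man, cap)
}

# Trapezoidal AUC by explicit summation.
auc_oracle <- function(x, y) {
  a <- 0
  for (i in seq_len(length(x) - 1)) {
    a <- a + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  }
  a
}

# Spearman as the Pearson correlation of midranks, computed by hand.
spearman_oracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  mx <- mean(rx)
  my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Exact two-sided rank-sum p by complete enumeration of group assignments.
ranksum_oracle <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  obs <- sum(r[seq_len(na)])
  mu <- na * (length(pooled) + 1) / 2
  combos <- utils::combn(length(pooled), na)
  stat <- apply(combos, 2, function(idx) sum(r[idx]))
  mean(abs(stat - mu) >= abs(obs - mu))
}

# Upper-tail binomial probability by direct pmf summation.
binom_tail_oracle <- function(k, n, q) {
  total <- 0
  for (i in k:n) total <- total + choose(n, i) * q^i * (1 - q)^(n - i)
  total
}

# Patristic distance by exhaustive root-path comparison.
phylo_distance_oracle <- function(phylo, a, b) {
  path_up <- function(id) {
    ids <- id
    while (!is.na(phylo$parent_id[phylo$id == ids[length(ids)]])) {
      ids <- c(ids, phylo$parent_id[phylo$id == ids[length(ids)]])
    }
    ids
  }
  pa <- path_up(a)
  pb <- path_up(b)
  common <- intersect(pa, pb)
  if (!length(common)) return(Inf)
  lca <- common[1]
  dist_to <- function(path, stop_at) {
    d <- 0
    for (id in path) {
      if (id == stop_at) break
      d <- d + phylo$mutations_from_parent[phylo$id == id]
    }
    d
  }
  dist_to(pa, lca) + dist_to(pb, lca)
}
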