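# Small, fast configurations for simulator tests.
tiny_config <- function(seed = 1L, ...) {
  build_config(seed, scale = 0.02, ...)   # ~50-300 cells, 5000 updates
}

# A random phylogeny table: chain/tree of n genotypes with random parents
# among earlier ids, random branch lengths.
random_phylo <- function(n, seed) {
  set.seed(seed)
  parent <- c(NA_integer_, vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L))
  data.frame(
    id = seq_len(n),
    parent_id = parent,
    kind = "pathogen",
    birth_update = cumsum(c(0L, sample(0:5, n - 1L, replace = TRUE))),
    mutations_from_parent = c(0L, sample(1:4, n - 1L, replace = TRUE)),
    task_bits = invasim:::.mask_string(sample(1:511, n, replace = TRUE))
  )
}
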