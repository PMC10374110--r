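test_that("lineage persistence matches the exhaustive census scan", {
  ## randomized small communities: persistence of every root equals a
  ## brute-force scan of the census table
  for (s in 1:20) {
    ph <- random_phylo(12, seed = s)
    set.seed(s + 100)
    ups <- seq(0L, 100L, by = 10L)
    cen <- do.call(rbind, lapply(ups, function(u) {
      alive <- sample(ph$id, sample(1:6, 1))
      data.frame(update = u, genotype_id = alive, kind = "pathogen",
                 abundance = sample(1:20, length(alive), replace = TRUE))
    }))
    traj <- invasim:::.toy_trajectory(cen, NULL, ph, list(persistence_cap = 50L))
    for (root in sample(ph$id, 4)) {
      expect_equal(
        lineage_persistence(traj, root, t_manipulate = 40L, cap = 50L),
        persistence_oracle(cen, ph, root, 40L, 50L),
        info = sprintf("seed %d root %d", s, root)
      )
    }
  }
})

test_that("persistence is 0 for vanished lineages and capped for immortal ones", {
  ph <- random_phylo(5, seed = 1)
  ups <- seq(0L, 200L, by = 10L)
  cen <- do.call(rbind, lapply(ups, function(u) {
    data.frame(update = u, genotype_id = 1L, kind = "pathogen", abundance = 5L)
  }))
  traj <- invasim:::.toy_trajectory(cen, NULL, ph, list(persistence_cap = 100L))
  expect_equal(lineage_persistence(traj, 1L, 0L, cap = 100L), 100L)
  ## a leaf genotype that never appears in the census
  leaf <- setdiff(ph$id, c(1L, ph$parent_id))[1]
  expect_equal(lineage_persistence(traj, leaf, 0L, cap = 100L), 0L)
  expect_error(lineage_persistence(traj, 999L, 0L), "unknown root")
})

test_that("increasing the cap never decreases persistence", {
  ph <- random_phylo(10, seed = 3)
  set.seed(33)
  ups <- seq(0L, 150L, by = 10L)
  cen <- do.call(rbind, lapply(ups, function(u) {
    alive <- sample(ph$id, 3)
    data.frame(update = u, genotype_id = alive, kind = "pathogen",
               abundance = rep(2L, 3))
  }))
  traj <- invasim:::.toy_trajectory(cen, NULL, ph, list())
  for (root in ph$id) {
    p <- vapply(c(20L, 50L, 100L, 150L),
                function(cap) lineage_persistence(traj, root, 10L, cap), 1L)
    expect_true(all(diff(p) >= 0))
  }
})

test_that("native comparison counts qualifying natives only", {
  tab <- data.frame(
    genotype_id = 1:7,
    persistence = c(50L, 10L, 60L, 40L, 80L, 5L, 2L),
    n_at_manipulation = c(10L, 20L, 15L, 9L, 12L, 3L, 1L),
    is_invader = c(TRUE, rep(FALSE, 6))
  )
  ## qualifying natives: N >= 10 -> ids 2 (10 < 50), 3 (60 > 50), 5 (80 > 50)
  expect_equal(native_comparison(tab), 1 / 3)

  tab$persistence[1] <- 100L
  expect_equal(native_comparison(tab), 1.0)
  tab$persistence[1] <- 0L
  expect_equal(native_comparison(tab), 0.0)

  ## no native as large as the invader -> statistic undefined
  tab$n_at_manipulation <- c(100L, rep(1L, 6))
  expect_error(native_comparison(tab), "no qualifying natives")
})

test_that("prevalence shares match hand-computed ratios", {
  pair <- make_fixture("invader_takeover")
  prev <- prevalence_series(pair$treated, pair$invader$genotype_id, pair$t_manipulate)
  expect_equal(prev$species_share[nrow(prev)], 100)
  expect_equal(prev$individual_share[nrow(prev)], 100)

  ## three-lineage toy census: shares equal hand-computed ratios
  ph <- data.frame(id = 1:3, parent_id = c(NA, NA, 2L), kind = "pathogen",
                   birth_update = c(0L, 0L, 5L), mutations_from_parent = c(0L, 0L, 1L),
                   task_bits = rep("100000000", 3))
  cen <- data.frame(update = 10L, genotype_id = 1:3, kind = "pathogen",
                    abundance = c(6L, 3L, 1L))
  traj <- invasim:::.toy_trajectory(cen, NULL, ph, list())
  prev2 <- prevalence_series(traj, 2L, 0L)
  expect_equal(prev2$species_share, 100 * 2 / 3)
  expect_equal(prev2$individual_share, 100 * 4 / 10)

  ## extinct invader: zero shares at the recorded updates where pathogens exist
  prev3 <- prevalence_series(traj, 1L, 0L)
  expect_equal(prev3$species_share, 100 / 3)
})

test_that("the excess-persistence test equals the enumerated binomial tail", {
  expect_equal(excess_persistence_test(0, 10, 0.3), 1)
  expect_equal(excess_persistence_test(10, 10, 0.5), 2^-10)
  for (s in 1:20) {
    set.seed(s)
    n <- sample(5:20, 1)
    k <- sample(0:n, 1)
    q <- runif(1, 0.01, 0.99)
    expect_equal(excess_persistence_test(k, n, q), binom_tail_oracle(k, n, q),
                 tolerance = 1e-12)
  }
  ## non-increasing in k
  p <- vapply(0:12, function(k) excess_persistence_test(k, 12, 0.054), 1)
  expect_true(all(diff(p) <= 0))
  expect_error(excess_persistence_test(3, 10, 0), "q must be")
  expect_error(excess_persistence_test(11, 10, 0.5), "k must be")
})
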