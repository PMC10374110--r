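test_that("identical config and seed give bit-identical trajectories", {
  cfg <- tiny_config(11)
  a <- run_simulation(cfg, until = 1500)
  b <- run_simulation(cfg, until = 1500)
  expect_identical(trajectory_hash(a), trajectory_hash(b))
  expect_identical(snapshot_hashes(a), snapshot_hashes(b))
})

test_that("the recorder controls which updates are recorded", {
  cfg <- tiny_config(12)
  rec <- data.frame(from = c(0L, 1000L), to = c(1000L, 2000L), step = c(100L, 500L))
  traj <- run_simulation(cfg, until = 2000, recorder = rec)
  expect_setequal(traj$snapshots, c(seq(0, 1000, 100), seq(1000, 2000, 500)))
})

test_that("a zero-length run records only the initial census", {
  cfg <- tiny_config(13)
  traj <- run_simulation(cfg, until = 0)
  expect_equal(traj$snapshots, 0L)
  expect_equal(sum(traj$census$abundance), 1L)  # the single ancestor
})

test_that("census abundances sum to the incrementally maintained counts", {
  cfg <- tiny_config(14)
  traj <- run_simulation(cfg, until = 2000, audit_every = 10)
  w <- traj$final_world
  last <- max(traj$snapshots)
  expect_equal(sum(census_at(traj, last, "host")$abundance), w$n_hosts)
  expect_equal(sum(census_at(traj, last, "pathogen")$abundance), w$n_paths)
})

test_that("every census genotype exists in the phylogeny with consistent ancestry", {
  cfg <- tiny_config(15)
  traj <- run_simulation(cfg, until = 2000)
  ph <- traj$phylogeny
  expect_true(all(traj$census$genotype_id %in% ph$id))
  ## parent links form a forest rooted at the two ancestors
  expect_equal(sum(is.na(ph$parent_id)), 2L)
  nonroot <- !is.na(ph$parent_id)
  expect_true(all(ph$parent_id[nonroot] < ph$id[nonroot]))
  ## birth ordering along lineages
  pb <- ph$birth_update[match(ph$parent_id[nonroot], ph$id)]
  expect_true(all(ph$birth_update[nonroot] >= pb))
  ## kinds never interconvert along descent
  pk <- ph$kind[match(ph$parent_id[nonroot], ph$id)]
  expect_equal(ph$kind[nonroot], pk)
})

test_that("arms race: host task complexity does not systematically decay", {
  ## over many seeded small runs, mean maximal host complexity at the end
  ## must be at least its ancestral value (1, the NOT task)
  final_max <- vapply(1:20, function(s) {
    cfg <- build_config(s + 400, scale = 0.01)
    traj <- run_simulation(cfg)
    hosts <- census_at(traj, max(traj$snapshots), "host")
    masks <- invasim:::.string_mask(
      traj$phylogeny$task_bits[match(hosts$genotype_id, traj$phylogeny$id)]
    )
    max(task_complexity_sum(masks))
  }, 1)
  expect_gte(mean(final_max), 1)
  expect_gt(mean(final_max), 1.5)  # and in fact complexity grows
})
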