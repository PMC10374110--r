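test_that("scheduled times fall in the protocol windows and keep their order", {
  cfg <- build_config(21, scale = 0.04)
  snaps <- recorder_updates(default_recorder(cfg), cfg$total_updates)
  set.seed(1)
  for (i in 1:200) {
    ts <- schedule_times(cfg, snaps)
    expect_gte(ts$t_sample, 2000L)
    expect_lte(ts$t_sample, 6000L)
    expect_gt(ts$t_manipulate, 6000L)
    expect_lte(ts$t_manipulate, 8000L)
    expect_lt(ts$t_sample, ts$t_manipulate)
  }
})

test_that("invader sampling is abundance-weighted within the window", {
  ## single-snapshot window with two genotypes at 90/10: the sampling
  ## frequency must match the binomial expectation within 3 sigma
  cen <- data.frame(
    update = 100L, genotype_id = c(31L, 32L), kind = "pathogen",
    abundance = c(90L, 10L)
  )
  ph <- data.frame(id = c(31L, 32L), parent_id = c(NA, 31L), kind = "pathogen",
                   birth_update = c(0L, 10L), mutations_from_parent = c(0L, 1L),
                   task_bits = c("100000000", "110000000"))
  traj <- invasim:::.toy_trajectory(cen, NULL, ph,
                                    list(sample_window = c(0L, 200L)))
  set.seed(7)
  draws <- replicate(10000, sample_invader(traj)$genotype_id)
  p_hat <- mean(draws == 31L)
  expect_lt(abs(p_hat - 0.9), 3 * sqrt(0.9 * 0.1 / 10000))

  ## single pathogen genotype: chosen with certainty
  cen1 <- cen[1, ]
  traj1 <- invasim:::.toy_trajectory(cen1, NULL, ph, list(sample_window = c(0L, 200L)))
  expect_equal(sample_invader(traj1)$genotype_id, 31L)

  ## window beyond pathogen extinction
  expect_error(sample_invader(traj, window = c(150L, 200L)), "empty-window")
})

test_that("injection targets the configured fraction and honours susceptibility", {
  cfg <- tiny_config(22)
  set.seed(cfg$seed)
  w <- init_world(cfg)
  for (i in 1:(cfg$pathogen_intro_update + 50)) step_world(w)
  ## exactly ceiling(fraction * n_cells) distinct cells are targeted, so the
  ## number of new infections never exceeds that
  before <- w$n_paths
  n <- inject_invader(w, w$path_ancestor, fraction = 0.05, seed = 99)
  expect_lte(n, ceiling(0.05 * cfg$n_cells))
  expect_equal(w$n_paths, before + n)
  expect_silent(audit_world(w))
  expect_error(inject_invader(w, w$host_ancestor, 0.05, seed = 1), "host genotype")
  expect_error(inject_invader(w, w$path_ancestor, 1.5, seed = 1), "fraction")
})

test_that("paired runs replay identically before the manipulation and diverge after", {
  found_divergence <- FALSE
  n_checked <- 0
  for (s in 1:4) {
    cfg <- build_config(s + 30, scale = 0.02)
    pair <- run_pair(cfg, "time_travel", pair_seed = s + 900)
    if (!pair$included) next
    n_checked <- n_checked + 1
    hc <- snapshot_hashes(pair$control)
    ht <- snapshot_hashes(pair$treated)
    pre <- names(hc)[as.integer(names(hc)) < pair$t_manipulate]
    expect_identical(hc[pre], ht[pre])
    post <- names(hc)[as.integer(names(hc)) >= pair$t_manipulate]
    if (any(hc[post] != ht[post])) found_divergence <- TRUE
  }
  expect_gt(n_checked, 0)
  expect_true(found_divergence)
})

test_that("a time-travel invader's lineage is extinct in the recipient at manipulation", {
  for (s in 5:8) {
    cfg <- build_config(s + 30, scale = 0.02)
    pair <- run_pair(cfg, "time_travel", pair_seed = s + 900)
    if (!pair$included) next
    alive <- census_at(pair$control, pair$t_manipulate, "pathogen")$genotype_id
    members <- descendants_oracle(pair$control$phylogeny, pair$invader$genotype_id)
    expect_length(intersect(alive, members), 0)
    expect_lt(pair$t_sample, pair$t_manipulate)
  }
})

test_that("control-control pairs inject nothing and still diverge", {
  cfg <- build_config(43, scale = 0.02)
  pair <- run_pair(cfg, "control_control", pair_seed = 1234)
  expect_true(pair$included)
  expect_null(pair$invader)
  expect_true(is.na(pair$t_sample))
  hc <- snapshot_hashes(pair$control)
  ht <- snapshot_hashes(pair$treated)
  pre <- names(hc)[as.integer(names(hc)) < pair$t_manipulate]
  expect_identical(hc[pre], ht[pre])
})

test_that("contemporary pairs inject an extant pathogen", {
  cfg <- build_config(43, scale = 0.02)
  pair <- run_pair(cfg, "contemporary", pair_seed = 77)
  expect_true(pair$included)
  alive <- census_at(pair$control, pair$t_manipulate, "pathogen")$genotype_id
  expect_true(pair$invader$genotype_id %in% alive)
  expect_equal(pair$t_sample, pair$t_manipulate)
})

test_that("campaigns are deterministic, count correctly, and flag exclusions", {
  a <- run_campaign(4, 3, "time_travel", master_seed = 17, scale = 0.01)
  b <- run_campaign(4, 3, "time_travel", master_seed = 17, scale = 0.01)
  expect_length(a$pairs, 12L)
  expect_equal(a$included, b$included)
  for (k in seq_along(a$pairs)) {
    expect_identical(trajectory_hash(a$pairs[[k]]$control),
                     trajectory_hash(b$pairs[[k]]$control))
  }
  ## exclusion flag matches pathogen survival at the manipulation update
  for (p in a$pairs) {
    alive <- nrow(census_at(p$control, p$t_manipulate, "pathogen")) > 0
    if (!alive) {
      expect_false(p$included)
      expect_equal(p$exclusion_reason, "pathogen_extinct_pre_invasion")
    }
  }
})
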