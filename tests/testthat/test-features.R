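test_that("features of a constructed pair match hand computation", {
  pair <- make_fixture("invader_takeover")
  f <- extract_features(pair)

  ## environment: 100 cells; expected inflow = sum(1)/2 per resource
  expect_equal(f$world_size, 100L)
  expect_equal(f$net_resources, 4.5)
  expect_equal(f$resource_types, 9L)
  ## recipient community at manipulation (control snapshot at update 50)
  expect_equal(f$host_richness, 2L)
  expect_equal(f$path_richness, 2L)
  expect_equal(f$host_abundance, 50L)
  expect_equal(f$path_abundance, 10L)
  expect_equal(f$host_density, 0.5)
  expect_equal(f$path_density, 0.1)
  ## the invader never existed in the control history of this fixture
  expect_equal(f$inv_pre_persistence, 0L)
  expect_equal(f$inv_pre_mean_abundance, 0)
  expect_equal(f$inv_pre_total_abundance, 0L)
  expect_equal(f$inv_source_abundance, 5L)
  ## task profile 111000000: NOT, NAND, AND
  expect_equal(f$inv_task_count, 3L)
  expect_equal(f$inv_task_complexity, 2)
  expect_equal(f$inv_generalism_source, 0L)
  expect_equal(f$inv_generalism_post, 0)
  ## mean patristic distance to natives 4 and 5: (1 + 2) / 2
  expect_equal(f$inv_phylo_distance, 1.5)
  expect_equal(f$time_gap, 20L)
  expect_equal(f$inv_age, 30L)
  expect_equal(f$community_age, 50L)
  ## outcomes
  expect_equal(f$persistence, pair$manifest$invader_persistence)
  expect_equal(f$signed_change, 0)

  ## the modelling subset drops the environment features and post generalism
  mod <- attr(f, "modelling")
  expect_length(mod, 17L)
  expect_false(any(c("world_size", "net_resources", "resource_types",
                     "inv_generalism_post") %in% mod))
})

test_that("patristic distances agree with the exhaustive root-path oracle", {
  for (s in 1:10) {
    ph <- random_phylo(20, seed = s + 200)
    set.seed(s)
    a <- sample(ph$id, 1)
    bs <- sample(ph$id, 5)
    expect_equal(phylo_distance(ph, a, bs),
                 vapply(bs, function(b) phylo_distance_oracle(ph, a, b), 1))
  }
})

test_that("features from a simulated pair are complete and internally consistent", {
  found <- FALSE
  for (s in 1:4) {
    cfg <- build_config(s + 50, scale = 0.02)
    pair <- run_pair(cfg, "time_travel", pair_seed = s)
    if (!pair$included) next
    found <- TRUE
    f <- extract_features(pair)
    expect_false(anyNA(f))
    expect_equal(f$host_density, f$host_abundance / cfg$n_cells)
    expect_equal(f$path_density, f$path_abundance / cfg$n_cells)
    expect_equal(f$time_gap, f$community_age - f$inv_age)
    expect_gte(f$inv_task_count, 1L)   # it must share a task to have lived
    break
  }
  expect_true(found)
})
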