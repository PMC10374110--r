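test_that("Shannon diversity matches direct summation", {
  expect_equal(shannon(rep(10, 4)), log(4))
  expect_equal(shannon(42), 0)
  expect_equal(shannon(c(50, 30, 20)), shannon_oracle(c(50, 30, 20)))
  expect_error(shannon(numeric(0)), "empty")
  expect_error(shannon(c(3, 0)), "positive")
  for (s in 1:20) {
    set.seed(s)
    ab <- sample(1:100, sample(2:20, 1), replace = TRUE)
    expect_equal(shannon(ab), shannon_oracle(ab))
  }
  ## agreement with the community-ecology reference implementation
  skip_if_not_installed("vegan")
  set.seed(5)
  ab <- sample(1:50, 12)
  expect_equal(shannon(ab), unname(vegan::diversity(ab, index = "shannon")))
})

test_that("Faith's PD equals the brute-force path-union oracle", {
  ## star tree: three tips of unit length
  star <- data.frame(id = 1:4, parent_id = c(NA, 1L, 1L, 1L), kind = "host",
                     birth_update = c(0L, 1L, 1L, 1L),
                     mutations_from_parent = c(0L, 1L, 1L, 1L),
                     task_bits = rep("100000000", 4))
  expect_equal(faith_pd(star, 2:4), 3)
  expect_equal(faith_pd(star, 2L), 1)

  ## caterpillar chain
  cat6 <- data.frame(id = 1:6, parent_id = c(NA, 1:5), kind = "host",
                     birth_update = 0:5, mutations_from_parent = c(0L, 2L, 1L, 4L, 1L, 3L),
                     task_bits = rep("100000000", 6))
  expect_equal(faith_pd(cat6, 6L), 2 + 1 + 4 + 1 + 3)
  expect_equal(faith_pd(cat6, c(3L, 6L)), pd_oracle(cat6, c(3L, 6L)))

  ## randomized trees and tip sets, both branch-length units
  for (s in 1:20) {
    ph <- random_phylo(15, seed = s + 50)
    set.seed(s)
    tips <- sample(ph$id, sample(1:8, 1))
    expect_equal(faith_pd(ph, tips), pd_oracle(ph, tips))
    expect_equal(faith_pd(ph, tips, branch_unit = "updates"),
                 pd_oracle(ph, tips, unit = "updates"))
  }
  expect_error(faith_pd(star, 99L), "unknown genotype")
})

test_that("identical series give exactly zero change", {
  pair <- make_fixture("identical_pair")
  ch <- pair_change(pair)
  expect_equal(ch$signed_change, 0)
  expect_equal(ch$abs_change, 0)
  expect_true(all(ch$timepoints$change == 0))
})

test_that("the signed change follows the loss-positive sign convention", {
  pair <- make_fixture("loss_05pct")
  ch <- pair_change(pair)
  expect_equal(ch$signed_change, pair$manifest$signed_change)
  expect_equal(ch$signed_change, 5)
  expect_true(all(ch$timepoints$change == 5))
  ## constant 10 versus 9: +10% regardless of window
  con <- data.frame(update = seq(0, 40, 10), richness = 10)
  trt <- data.frame(update = seq(0, 40, 10), richness = 9)
  ch2 <- auc_change(con, trt, 0, 40, 10)
  expect_equal(ch2$signed_change, 10)
})

test_that("AUC change agrees with explicit trapezoid summation", {
  for (s in 1:20) {
    set.seed(s + 10)
    grid <- seq(0, 100, 10)
    yc <- sample(5:30, length(grid), replace = TRUE)
    yt <- sample(5:30, length(grid), replace = TRUE)
    con <- data.frame(update = grid, richness = yc)
    trt <- data.frame(update = grid, richness = yt)
    ch <- auc_change(con, trt, 0, 100, 10)
    a_con <- auc_oracle(grid, yc)
    a_trt <- auc_oracle(grid, yt)
    expect_equal(ch$signed_change, 100 * (a_con - a_trt) / a_con)
    expect_equal(ch$abs_change, abs(ch$signed_change))
  }
  ## scale invariance: common rescaling leaves relative change unchanged
  grid <- seq(0, 100, 10)
  set.seed(3)
  yc <- runif(11, 5, 20)
  yt <- runif(11, 5, 20)
  ch1 <- auc_change(data.frame(update = grid, richness = yc),
                    data.frame(update = grid, richness = yt), 0, 100, 10)
  ch2 <- auc_change(data.frame(update = grid, richness = 7 * yc),
                    data.frame(update = grid, richness = 7 * yt), 0, 100, 10)
  expect_equal(ch1$signed_change, ch2$signed_change)
})

test_that("window sensitivity echoes the window grid and flags divergence timing", {
  pair <- make_fixture("identical_pair")
  ws <- window_sensitivity(pair, windows = c(10L, 20L, 30L, 40L))
  expect_equal(ws$window, c(10L, 20L, 30L, 40L))
  expect_equal(ws$signed_change, rep(0, 4))

  ## a pair diverging only after the first window
  ups <- seq(0L, 100L, 10L)
  mk <- function(rich_fun) {
    cen <- do.call(rbind, lapply(ups, function(u) {
      data.frame(update = u, genotype_id = seq_len(rich_fun(u)), kind = "host",
                 abundance = 5L)
    }))
    invasim:::.toy_trajectory(cen, NULL, make_fixture("loss_05pct")$control$phylogeny,
                              list(auc_window = 40L, auc_resolution = 10L))
  }
  pair2 <- make_fixture("identical_pair")
  pair2$t_manipulate <- 0L
  pair2$control <- mk(function(u) 10L)
  pair2$treated <- mk(function(u) if (u <= 20L) 10L else 8L)
  ws2 <- window_sensitivity(pair2, windows = c(10L, 20L, 60L))
  expect_equal(ws2$signed_change[1:2], c(0, 0))
  expect_gt(ws2$signed_change[3], 0)
})

test_that("diversity series recomputes each metric from the raw census", {
  cfg <- tiny_config(61)
  traj <- run_simulation(cfg, until = 1500)
  ds <- diversity_series(traj, "host", include_pd = TRUE)
  for (i in sample(nrow(ds), 5)) {
    u <- ds$update[i]
    rows <- census_at(traj, u, "host")
    expect_equal(ds$richness[i], nrow(rows))
    expect_equal(ds$abundance[i], sum(rows$abundance))
    expect_equal(ds$shannon[i], shannon_oracle(rows$abundance))
    expect_equal(ds$pd[i], pd_oracle(traj$phylogeny, rows$genotype_id))
    if (nrow(rows) > 1) {
      expect_equal(ds$evenness[i], ds$shannon[i] / log(ds$richness[i]))
    }
  }
  expect_true(all(ds$shannon <= log(ds$richness) + 1e-12))
  expect_true(all(ds$abundance >= ds$richness))
})

test_that("exceedance against a null distribution counts threshold crossings", {
  set.seed(8)
  null <- rnorm(20)
  treated <- rnorm(20)
  thr <- quantile(null, 0.95, names = FALSE)
  expect_equal(exceedance_vs_null(treated, null), mean(treated > thr))
  expect_equal(exceedance_vs_null(c(-10, -20), null), 0)
  ## self-exceedance sits near the nominal 5%
  many <- rnorm(5000)
  expect_lt(abs(exceedance_vs_null(many, many) - 0.05), 0.02)
})
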