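test_that("spearman matches the midrank oracle and its invariances", {
  expect_equal(spearman(1:10, (1:10)^3), 1)
  expect_equal(spearman(1:10, -(1:10)), -1)
  ## 8-point data with a tie, against Pearson-of-midranks computed by hand
  x <- c(1, 2, 2, 3, 5, 6, 7, 9)
  y <- c(2, 1, 4, 3, 7, 6, 9, 8)
  expect_equal(spearman(x, y), spearman_oracle(x, y))
  for (s in 1:20) {
    set.seed(s)
    a <- sample(1:15, 10, replace = TRUE)
    b <- sample(1:15, 10, replace = TRUE)
    if (sd(a) == 0 || sd(b) == 0) next
    expect_equal(spearman(a, b), spearman_oracle(a, b))
  }
  ## invariance under strictly monotone transforms
  set.seed(4)
  a <- runif(30)
  b <- runif(30)
  expect_equal(spearman(exp(a), b), spearman(a, b))
  expect_equal(spearman(a, a), 1)
  expect_error(spearman(rep(1, 10), 1:10), "constant")
  expect_error(spearman(1:3, 1:4), "equal length")
})

test_that("the exact rank-sum path equals complete enumeration", {
  expect_equal(ranksum_two_sided(c(1, 2), c(3, 4)), 2 / 6)
  for (s in 1:20) {
    set.seed(s)
    na <- sample(2:6, 1)
    nb <- sample(2:6, 1)
    vals <- sample(1:1000, na + nb)   # distinct -> no ties
    a <- vals[seq_len(na)]
    b <- vals[-seq_len(na)]
    expect_equal(ranksum_two_sided(a, b), ranksum_oracle(a, b),
                 info = sprintf("seed %d (%d,%d)", s, na, nb))
  }
})

test_that("the tied/approximate rank-sum path behaves sensibly", {
  a <- c(1, 1, 2, 2, 3, 3, 4)
  expect_gte(suppressWarnings(ranksum_two_sided(a, a)), 0.99)
  set.seed(2)
  x <- rnorm(30)
  y <- rnorm(30) + 5
  expect_lt(ranksum_two_sided(x, y), 1e-6)
  expect_error(ranksum_two_sided(numeric(0), 1:3), "non-empty")
})

test_that("random forest recovers a planted monotone predictor", {
  ## planted signal at 3:1 signal-to-noise, n = 300: the planted feature
  ## must rank top-1 in importance in at least 9 of 10 seeded repeats
  hits <- 0L
  for (s in 1:10) {
    set.seed(s)
    n <- 300L
    x <- as.data.frame(matrix(rnorm(n * 8), n, 8))
    names(x) <- paste0("f", 1:8)
    y <- 3 * x$f1 + rnorm(n)
    rep <- rf_model(x, y, n_trees = 300L, seed = s)
    if (names(which.max(rep$importance)) == "f1") hits <- hits + 1L
    expect_length(rep$importance, 8L)
  }
  expect_gte(hits, 9L)
})

test_that("random forest explains nothing on pure noise", {
  low <- 0L
  for (s in 1:10) {
    set.seed(s + 100)
    n <- 200L
    x <- as.data.frame(matrix(rnorm(n * 8), n, 8))
    y <- rnorm(n)
    rep <- rf_model(x, y, n_trees = 300L, seed = s)
    if (rep$explained_variance <= 0.05) low <- low + 1L
  }
  expect_gte(low, 9L)
})

test_that("random forest reports are deterministic given data and seed", {
  set.seed(1)
  x <- as.data.frame(matrix(rnorm(600), 100, 6))
  y <- x[[1]] + rnorm(100)
  a <- rf_model(x, y, n_trees = 200L, seed = 42)
  b <- rf_model(x, y, n_trees = 200L, seed = 42)
  expect_equal(a$explained_variance, b$explained_variance)
  expect_equal(a$importance, b$importance)
  expect_error(rf_model(x[1:10, ], y[1:10]), "at least 20")
})

test_that("the loss/gain contrast splits at the 5% threshold", {
  feats <- data.frame(
    persistence = c(10, 20, 30, 1, 2, 3, 50),
    signed_change = c(6, 8, 12, -7, -9, -6, 2)
  )
  lg <- loss_gain_test(feats)
  expect_equal(lg$n_loss, 3L)
  expect_equal(lg$n_gain, 3L)
  expect_equal(lg$p_value, ranksum_oracle(c(10, 20, 30), c(1, 2, 3)))
})
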