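#' Spearman rank correlation
#'
#' Rank correlation with midranks for ties; the screening statistic of the
#' feature analysis.
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @return `r_s` in `[-1, 1]`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input: r_s undefined")
  stats::cor(x, y, method = "spearman")
}

#' Two-sided rank-sum test
#'
#' Wilcoxon-Mann-Whitney comparison of two independent groups: exact (by
#' complete enumeration of rank assignments) when the pooled sample size is
#' at most 12 and there are no ties, the normal approximation with tie
#' correction and continuity correction otherwise.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @return Two-sided p-value.
#' @export
ranksum_two_sided <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b)) <= 12L && !ties
  stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value
}

#' Spearman screen of features against outcomes
#'
#' Pairwise Spearman correlations between every feature column and every
#' outcome column of a feature table. No multiple-testing correction is
#' applied to the screen.
#'
#' @param features Feature table from [feature_table()].
#' @param outcomes Outcome column names.
#' @return Matrix of `r_s` values, features x outcomes; `NA` where a column
#'   is constant.
#' @export
screen_features <- function(features,
                            outcomes = c("persistence", "signed_change", "abs_change")) {
  feat_cols <- setdiff(names(features), outcomes)
  m <- matrix(NA_real_, length(feat_cols), length(outcomes),
              dimnames = list(feat_cols, outcomes))
  for (f in feat_cols) {
    for (o in outcomes) {
      m[f, o] <- tryCatch(spearman(features[[f]], features[[o]]),
                          error = function(e) NA_real_)
    }
  }
  m
}

#' Compare invader persistence between diversity-loss and -gain pairs
#'
#' Splits pairs into substantial losses (`signed_change > threshold`) and
#' substantial gains (`signed_change < -threshold`) and compares a feature
#' (invader persistence by default) between the two groups with the
#' two-sided rank-sum test.
#'
#' @param features Feature table.
#' @param feature Column to compare.
#' @param threshold Absolute percent change defining "substantial" (5, as in
#'   the loss/gain contrast).
#' @return List with group sizes, group values and the p-value (`NA` if a
#'   group is empty).
#' @export
loss_gain_test <- function(features, feature = "persistence", threshold = 5) {
  loss <- features[[feature]][features$signed_change > threshold]
  gain <- features[[feature]][features$signed_change < -threshold]
  p <- if (length(loss) && length(gain)) ranksum_two_sided(loss, gain) else NA_real_
  list(n_loss = length(loss), n_gain = length(gain),
       loss = loss, gain = gain, p_value = p)
}

#' Random-forest prediction of invasion outcomes
#'
#' Fits a random-forest regression (1,000 trees) of an outcome on the
#' feature columns and reports out-of-bag explained variance and permutation
#' importances (percent increase in mean squared error).
#'
#' @param features Data frame of predictor columns (complete rows only are
#'   used; at least 20 required).
#' @param outcome Numeric response vector.
#' @param n_trees Number of trees.
#' @param seed Integer seed (the fit is deterministic given data and seed).
#' @return An `rf_report`: list with `explained_variance` (OOB, fraction),
#'   `importance` (named %IncMSE vector covering every feature), `n` and the
#'   fitted model.
#' @export
rf_model <- function(features, outcome, n_trees = 1000L, seed = 1L) {
  stopifnot(is.data.frame(features), length(outcome) == nrow(features))
  keep <- stats::complete.cases(features) & !is.na(outcome)
  x <- features[keep, , drop = FALSE]
  y <- outcome[keep]
  if (nrow(x) < 20L) stop("need at least 20 complete rows")
  fit <- .with_seed(seed, randomForest::randomForest(
    x = x, y = y, ntree = n_trees, importance = TRUE
  ))
  imp <- randomForest::importance(fit, type = 1L, scale = TRUE)[, 1L]
  structure(list(
    explained_variance = fit$rsq[length(fit$rsq)],
    importance = imp,
    n = nrow(x),
    n_trees = n_trees,
    model = fit
  ), class = "rf_report")
}

#' @export
print.rf_report <- function(x, ...) {
  cat(sprintf("<rf_report> n=%d, %d trees, OOB explained variance %.1f%%\n",
              x$n, x$n_trees, 100 * x$explained_variance))
  top <- sort(x$importance, decreasing = TRUE)
  top <- utils::head(top, 5L)
  cat("  top importance (%IncMSE):",
      paste(sprintf("%s %.1f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Full outcome analysis of a campaign
#'
#' Combines the campaign-level analytics: the feature table, the Spearman
#' screen, the loss/gain rank-sum contrast, the persistence distribution
#' with the excess-persistence test, and (when enough pairs are available)
#' the random-forest models for persistence and for signed/absolute
#' diversity change (the change models additionally include invader
#' persistence as a predictor).
#'
#' @param campaign A time-travel `sim_campaign`.
#' @param rf_seed Seed for the random-forest fits.
#' @param min_rf_rows Minimum complete rows to attempt the forests.
#' @return A list with elements `features`, `screen`, `loss_gain`,
#'   `persistence`, `native_fraction`, `excess_test`, and `rf` (possibly
#'   `NULL`).
#' @export
analyze_campaign <- function(campaign, rf_seed = 1L, min_rf_rows = 20L) {
  feats <- feature_table(campaign)
  screen <- screen_features(feats)
  lg <- loss_gain_test(feats)

  included <- campaign$pairs[campaign$included &
                               !vapply(campaign$pairs, function(p) is.null(p$invader), TRUE)]
  ptabs <- lapply(included, persistence_table)
  cap <- included[[1]]$config$persistence_cap
  native_pers <- unlist(lapply(ptabs, function(t) t$persistence[!t$is_invader]))
  inv_pers <- vapply(ptabs, function(t) t$persistence[t$is_invader][1], 1)
  q_native <- mean(native_pers >= cap)
  k <- sum(inv_pers >= cap)
  excess <- if (q_native > 0 && q_native < 1) {
    excess_persistence_test(k, length(inv_pers), q_native)
  } else {
    NA_real_
  }
  native_fraction <- vapply(ptabs, function(t) {
    tryCatch(native_comparison(t), error = function(e) NA_real_)
  }, 1)

  mod_cols <- attr(feats, "modelling")
  rf <- NULL
  if (sum(stats::complete.cases(feats[mod_cols])) >= min_rf_rows) {
    rf <- list(
      persistence = rf_model(feats[mod_cols], feats$persistence, seed = rf_seed),
      signed_change = rf_model(cbind(feats[mod_cols], persistence = feats$persistence),
                               feats$signed_change, seed = rf_seed),
      abs_change = rf_model(cbind(feats[mod_cols], persistence = feats$persistence),
                            feats$abs_change, seed = rf_seed)
    )
  }
  list(
    features = feats,
    screen = screen,
    loss_gain = lg,
    persistence = data.frame(invader = inv_pers),
    native_persistence = native_pers,
    native_fraction = native_fraction,
    q_native = q_native,
    k_persistent = k,
    excess_test = excess,
    rf = rf
  )
}
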